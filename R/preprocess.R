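#' Centred log-ratio transform
#'
#' clr_j = ln(x_j) - mean_k ln(x_k), applied row-wise. Input must be strictly
#' positive (impute zeros first, e.g. via [dirichlet_clr()]). Rows sum to zero
#' by construction and the transform is invariant to rescaling a row.
#'
#' @param x strictly positive matrix (samples x genera) or vector.
#' @return matrix (or vector) of clr values.
#' @export
clr_transform <- function(x) {
  if (is.null(dim(x))) {
    if (any(x <= 0)) stop("clr requires strictly positive values")
    lx <- log(x)
    return(lx - mean(lx))
  }
  if (any(x <= 0)) stop("clr requires strictly positive values")
  lx <- log(x)
  lx - rowMeans(lx)
}

#' Mean-relative-abundance filter
#'
#' Removes genera whose relative abundance, averaged over all samples, is
#' strictly lower than `min_mean_rel_abund`. The boundary is kept: a genus with
#' mean exactly at the threshold is retained.
#'
#' @param table a [genus_count_table()].
#' @param min_mean_rel_abund threshold on the mean relative abundance
#'   (default 0.001).
#' @return list with `table` (filtered) and `dropped` (character vector of
#'   removed genus ids).
#' @export
abundance_filter <- function(table, min_mean_rel_abund = 0.001) {
  stopifnot(inherits(table, "genus_count_table"))
  rel <- relative_abundance(table$counts)
  keep <- colMeans(rel) >= min_mean_rel_abund
  if (!any(keep))
    stop("abundance filter removed every genus; review the threshold (",
         min_mean_rel_abund, ")")
  filtered <- genus_count_table(table$counts[, keep, drop = FALSE],
                                site = table$site,
                                lineage = if (!is.null(table$lineage)) table$lineage[keep])
  list(table = filtered, dropped = colnames(table$counts)[!keep])
}

# ---- bagged shallow trees (no external tree package available) --------------

# Best gini split of a single node over all features; returns NULL if no
# impurity-reducing split exists.
best_split <- function(X, y) {
  n <- length(y)
  n1 <- sum(y)
  parent_gini <- 2 * (n1 / n) * (1 - n1 / n)
  best <- NULL
  best_gain <- 1e-12
  for (j in seq_len(ncol(X))) {
    xj <- X[, j]
    o <- order(xj)
    xs <- xj[o]; ys <- y[o]
    cum1 <- cumsum(ys)
    k <- seq_len(n - 1L)
    valid <- xs[k] < xs[k + 1L]
    if (!any(valid)) next
    nl <- k
    nr <- n - k
    l1 <- cum1[k]
    r1 <- n1 - l1
    gl <- 2 * (l1 / nl) * (1 - l1 / nl)
    gr <- 2 * (r1 / nr) * (1 - r1 / nr)
    gain <- parent_gini - (nl * gl + nr * gr) / n
    gain[!valid] <- -Inf
    i <- which.max(gain)
    if (gain[i] > best_gain) {
      best_gain <- gain[i]
      best <- list(feature = j, cut = (xs[i] + xs[i + 1L]) / 2)
    }
  }
  best
}

fit_tree <- function(X, y, depth, min_n = 5L) {
  n1 <- sum(y)
  prob <- n1 / length(y)
  if (depth == 0L || length(y) < min_n || n1 == 0L || n1 == length(y))
    return(list(leaf = TRUE, prob = prob))
  sp <- best_split(X, y)
  if (is.null(sp)) return(list(leaf = TRUE, prob = prob))
  left <- X[, sp$feature] <= sp$cut
  list(leaf = FALSE, feature = sp$feature, cut = sp$cut,
       left = fit_tree(X[left, , drop = FALSE], y[left], depth - 1L, min_n),
       right = fit_tree(X[!left, , drop = FALSE], y[!left], depth - 1L, min_n))
}

predict_tree <- function(tree, X) {
  if (tree$leaf) return(rep(tree$prob, nrow(X)))
  out <- numeric(nrow(X))
  left <- X[, tree$feature] <= tree$cut
  if (any(left)) out[left] <- predict_tree(tree$left, X[left, , drop = FALSE])
  if (any(!left)) out[!left] <- predict_tree(tree$right, X[!left, , drop = FALSE])
  out
}

#' Out-of-bag error of a bagged shallow-tree ensemble
#'
#' Fits `n_trees` depth-limited CART-style trees (gini splits) on bootstrap
#' resamples and scores each sample by majority vote over the trees whose
#' bootstrap excluded it.
#'
#' @param X numeric matrix (samples x features).
#' @param y binary labels (0/1 or a 2-level factor).
#' @param n_trees number of bagged trees (default 200).
#' @param max_depth tree depth (default 2).
#' @return OOB misclassification rate (NA if some sample was never out of bag).
#' @export
bagged_oob_error <- function(X, y, n_trees = 200L, max_depth = 2L) {
  if (is.factor(y)) y <- as.integer(y) - 1L
  y <- as.integer(y)
  stopifnot(all(y %in% c(0L, 1L)))
  n <- nrow(X)
  votes1 <- numeric(n)
  votes0 <- numeric(n)
  for (b in seq_len(n_trees)) {
    idx <- sample.int(n, n, replace = TRUE)
    oob <- setdiff(seq_len(n), idx)
    if (!length(oob)) next
    tree <- fit_tree(X[idx, , drop = FALSE], y[idx], depth = max_depth)
    pr <- predict_tree(tree, X[oob, , drop = FALSE])
    cls <- as.integer(pr >= 0.5)
    votes1[oob] <- votes1[oob] + cls
    votes0[oob] <- votes0[oob] + (1L - cls)
  }
  seen <- votes1 + votes0 > 0
  pred <- as.integer(votes1 >= votes0)  # ties -> class 1 (majority-ish)
  mean(pred[seen] != y[seen])
}

#' Prevalence-threshold search (PIME-style)
#'
#' For each candidate prevalence fraction, keeps the genera present
#' (count > 0) in at least that fraction of samples within at least one
#' treatment group, fits a bagged-tree ensemble on the relative abundances of
#' the retained genera, and records its out-of-bag misclassification error.
#' Returns the threshold minimising OOB error (ties broken towards the
#' smallest threshold).
#'
#' @param table a [genus_count_table()].
#' @param labels 2-level factor (treatment) aligned with the table rows.
#' @param grid candidate prevalence fractions (default 0.05 to 0.95 by 0.05).
#' @param n_trees trees per ensemble (default 500).
#' @param max_depth tree depth (default 2).
#' @param seed RNG seed for the bootstrap resamples.
#' @return list: `threshold` (chosen), `errors` (data.frame threshold /
#'   n_genera / oob_error), `retained` (genus ids at the chosen threshold).
#' @export
prevalence_threshold_search <- function(table, labels,
                                        grid = seq(0.05, 0.95, by = 0.05),
                                        n_trees = 500L, max_depth = 2L,
                                        seed = 1L) {
  stopifnot(inherits(table, "genus_count_table"))
  labels <- factor(labels)
  stopifnot(nlevels(labels) == 2L, length(labels) == nrow(table$counts))
  rel <- relative_abundance(table$counts)
  pres <- table$counts > 0
  prev_by_group <- vapply(levels(labels), function(g)
    colMeans(pres[labels == g, , drop = FALSE]), numeric(ncol(pres)))
  max_prev <- apply(prev_by_group, 1, max)
  set.seed(seed)
  rows <- lapply(grid, function(th) {
    keep <- max_prev >= th
    if (!any(keep)) {
      warning(sprintf("threshold %.2f retains no genus; skipped", th))
      return(data.frame(threshold = th, n_genera = 0L, oob_error = NA_real_))
    }
    err <- bagged_oob_error(rel[, keep, drop = FALSE], labels,
                            n_trees = n_trees, max_depth = max_depth)
    data.frame(threshold = th, n_genera = sum(keep), oob_error = err)
  })
  errors <- do.call(rbind, rows)
  ok <- which(!is.na(errors$oob_error))
  if (!length(ok)) stop("no threshold retained any genus")
  best <- ok[which.min(errors$oob_error[ok])]  # which.min -> first = smallest
  th <- errors$threshold[best]
  list(threshold = th, errors = errors,
       retained = colnames(table$counts)[max_prev >= th])
}

#' Apply a prevalence threshold to a count table
#'
#' @param table a [genus_count_table()].
#' @param labels 2-level treatment factor.
#' @param threshold prevalence fraction; genera present in at least this
#'   fraction of samples within at least one group are kept.
#' @return filtered [genus_count_table()].
#' @export
apply_prevalence_filter <- function(table, labels, threshold) {
  labels <- factor(labels)
  pres <- table$counts > 0
  prev_by_group <- vapply(levels(labels), function(g)
    colMeans(pres[labels == g, , drop = FALSE]), numeric(ncol(pres)))
  keep <- apply(prev_by_group, 1, max) >= threshold
  if (!any(keep)) stop("prevalence filter retains no genus")
  genus_count_table(table$counts[, keep, drop = FALSE], site = table$site,
                    lineage = if (!is.null(table$lineage)) table$lineage[keep])
}

#' Monte-Carlo Dirichlet zero replacement + clr ensemble
#'
#' For every sample, draws K proportion vectors from
#' Dirichlet(counts + prior) — replacing zeros with posterior mass — and clr-
#' transforms each draw. The ensemble mean instance (element-wise mean of the
#' K clr matrices) is what point-estimate consumers (PLS-DA, ordination) use;
#' per-instance statistics (Welch's t) use all K instances.
#'
#' @param table a [genus_count_table()] (already filtered).
#' @param K number of Monte-Carlo instances (default 128).
#' @param prior Dirichlet prior mass added to every cell (default 0.5).
#' @param seed RNG seed.
#' @return object of class `clr_ensemble`: list with `instances`
#'   (array samples x genera x K), `mean` (samples x genera matrix), `K`,
#'   `prior`.
#' @export
dirichlet_clr <- function(table, K = 128L, prior = 0.5, seed = 1L) {
  if (inherits(table, "genus_count_table")) counts <- table$counts
  else counts <- as.matrix(table)
  if (K < 1L) stop("K must be >= 1")
  if (any(rowSums(counts) == 0))
    stop("all-zero sample row(s): ",
         paste(rownames(counts)[rowSums(counts) == 0], collapse = ", "))
  n <- nrow(counts); p <- ncol(counts)
  set.seed(seed)
  shape <- counts + prior
  inst <- array(NA_real_, dim = c(n, p, K),
                dimnames = list(rownames(counts), colnames(counts), NULL))
  for (k in seq_len(K)) {
    g <- matrix(stats::rgamma(n * p, shape = shape), n, p)
    # gamma draws can underflow to 0 for tiny shapes; clamp before log
    g[g < .Machine$double.xmin] <- .Machine$double.xmin
    lx <- log(g) - log(rowSums(g))
    inst[, , k] <- lx - rowMeans(lx)
  }
  structure(list(instances = inst, mean = apply(inst, c(1, 2), mean),
                 K = K, prior = prior),
            class = "clr_ensemble")
}

#' @export
print.clr_ensemble <- function(x, ...) {
  cat(sprintf("clr_ensemble: %d samples x %d genera, K = %d (prior %.2f)\n",
              nrow(x$mean), ncol(x$mean), x$K, x$prior))
  invisible(x)
}

#' Full preprocessing for one site
#'
#' Prevalence search, then mean-abundance filter, then Dirichlet/clr — the
#' narrative order of the source workflow.
#'
#' @inheritParams prevalence_threshold_search
#' @inheritParams dirichlet_clr
#' @param min_mean_rel_abund abundance-filter threshold.
#' @return list: `ensemble`, `table` (filtered counts), `prevalence` (search
#'   result), `dropped_low_abundance`.
#' @export
preprocess_site <- function(table, labels, grid = seq(0.05, 0.95, by = 0.05),
                            n_trees = 500L, min_mean_rel_abund = 0.001,
                            K = 128L, prior = 0.5, seed = 1L) {
  srch <- prevalence_threshold_search(table, labels, grid = grid,
                                      n_trees = n_trees, seed = seed)
  tab <- apply_prevalence_filter(table, labels, srch$threshold)
  ab <- abundance_filter(tab, min_mean_rel_abund)
  ens <- dirichlet_clr(ab$table, K = K, prior = prior, seed = seed + 1L)
  list(ensemble = ens, table = ab$table, prevalence = srch,
       dropped_low_abundance = ab$dropped)
}
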