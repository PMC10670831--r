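#' Per-sample alpha diversity
#'
#' Richness G_obs is the number of genera with non-zero count. The adjusted
#' Shannon index is Pielou-type evenness H / ln(G_obs) with
#' H = -sum p_i ln p_i over the present genera; it is defined as 0 when
#' G_obs <= 1, and lies in [0, 1].
#'
#' Computed on the raw (unfiltered) counts: richness is meaningless after
#' prevalence/abundance filtering.
#'
#' @param counts matrix samples x genera, or a [genus_count_table()].
#' @return data.frame: sample_id, observed_genera, adjusted_shannon.
#' @export
alpha_diversity <- function(counts) {
  if (inherits(counts, "genus_count_table")) counts <- counts$counts
  if (any(rowSums(counts) == 0))
    stop("empty sample(s): ",
         paste(rownames(counts)[rowSums(counts) == 0], collapse = ", "))
  g_obs <- rowSums(counts > 0)
  p <- relative_abundance(counts)
  h <- apply(p, 1, function(pi) { pi <- pi[pi > 0]; -sum(pi * log(pi)) })
  adj <- ifelse(g_obs <= 1, 0, h / log(g_obs))
  data.frame(sample_id = rownames(counts), observed_genera = as.integer(g_obs),
             adjusted_shannon = adj, row.names = NULL)
}

#' Treatment contrast from a one-random-intercept mixed model
#'
#' Fits `y ~ treatment + (1 | litter)` by REML and reports the Wald t test of
#' the group contrast with residual degrees of freedom n - #litters - 1. If
#' the litter variance estimate is singular (zero) the model collapses to OLS
#' with a logged notice, as does a design with a single litter.
#'
#' @param y numeric response.
#' @param treatment 2-level factor.
#' @param litter grouping factor for the random intercept.
#' @param contrast length-2 character: the estimate reported is
#'   mean(contrast[1]) - mean(contrast[2]). Default is the factor's levels in
#'   order.
#' @return list: estimate, se, df, t, p, group_means, group_se, method
#'   ("reml" or "ols").
#' @export
mixed_contrast <- function(y, treatment, litter, contrast = NULL) {
  treatment <- factor(treatment)
  litter <- factor(litter)
  stopifnot(nlevels(treatment) == 2L, length(y) == length(treatment),
            length(y) == length(litter))
  if (is.null(contrast)) contrast <- levels(treatment)
  stopifnot(all(contrast %in% levels(treatment)))
  # code treatment so the slope is mean(contrast[1]) - mean(contrast[2])
  tr <- factor(treatment, levels = rev(contrast))
  method <- "reml"
  fit <- NULL
  if (nlevels(litter) >= 2L) {
    fit <- tryCatch(
      suppressMessages(lme4::lmer(y ~ tr + (1 | litter), REML = TRUE,
                                  control = lme4::lmerControl(
                                    check.conv.singular = "ignore"))),
      error = function(e) NULL)
    if (!is.null(fit) && lme4::isSingular(fit, tol = 1e-5)) fit <- NULL
  }
  if (is.null(fit)) {
    method <- "ols"
    fit <- stats::lm(y ~ tr)
    sm <- summary(fit)$coefficients
    est <- sm[2, 1]; se <- sm[2, 2]
  } else {
    sm <- summary(fit)$coefficients
    est <- sm[2, 1]; se <- sm[2, 2]
  }
  df <- max(1L, length(y) - nlevels(litter) - 1L)
  tval <- est / se
  p <- 2 * stats::pt(-abs(tval), df = df)
  gm <- tapply(y, treatment, mean)
  gse <- tapply(y, treatment, function(v) stats::sd(v) / sqrt(length(v)))
  list(estimate = unname(est), se = unname(se), df = df, t = unname(tval),
       p = unname(p), group_means = gm, group_se = gse, method = method)
}

#' Bray-Curtis dissimilarity matrix
#'
#' BC(x, y) = sum |x_i - y_i| / sum (x_i + y_i); 0 for identical profiles,
#' 1 for disjoint supports. Computed on relative abundances by convention but
#' the formula accepts any non-negative profiles.
#'
#' @param rel_abund matrix samples x genera.
#' @return symmetric dissimilarity matrix (base `matrix`) with zero diagonal.
#' @export
bray_curtis <- function(rel_abund) {
  rel_abund <- as.matrix(rel_abund)
  if (requireNamespace("vegan", quietly = TRUE)) {
    d <- as.matrix(vegan::vegdist(rel_abund, method = "bray"))
  } else {
    n <- nrow(rel_abund)
    d <- matrix(0, n, n, dimnames = list(rownames(rel_abund), rownames(rel_abund)))
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      num <- sum(abs(rel_abund[i, ] - rel_abund[j, ]))
      den <- sum(rel_abund[i, ] + rel_abund[j, ])
      d[i, j] <- d[j, i] <- if (den > 0) num / den else 0
    }
  }
  d
}

#' PERMANOVA with sequential sums of squares
#'
#' Partitions the Gower-centred inner-product matrix G = -1/2 J D^2 J of a
#' distance matrix into sequential factor (litter entered first, then
#' treatment) and residual sums of squares via projection matrices
#' (McArdle-Anderson). Pseudo-F per factor; p-values by free permutation of
#' the sample labels with the (1 + #{F_perm >= F_obs}) / (n_perm + 1)
#' convention.
#'
#' @param dist square symmetric distance matrix.
#' @param treatment factor of interest (tested after litter).
#' @param litter nuisance factor entered first; NULL for a one-factor test.
#' @param n_perm number of Monte-Carlo permutations (default 999).
#' @param seed RNG seed for the permutations.
#' @return data.frame with one row per factor: df, SS, pseudo_F, p; residual
#'   and total rows appended (attribute "SS_total" also set).
#' @export
permanova <- function(dist, treatment, litter = NULL, n_perm = 999L, seed = 1L) {
  dist <- as.matrix(dist)
  n <- nrow(dist)
  if (ncol(dist) != n || max(abs(dist - t(dist))) > 1e-8)
    stop("distance matrix must be square and symmetric")
  treatment <- factor(treatment)
  stopifnot(length(treatment) == n)
  if (!is.null(litter)) { litter <- factor(litter); stopifnot(length(litter) == n) }

  J <- diag(n) - matrix(1 / n, n, n)
  G <- -0.5 * J %*% (dist^2) %*% J

  hat <- function(X) { X %*% solve(crossprod(X), t(X)) }
  X0 <- matrix(1, n, 1)
  facs <- list()
  if (!is.null(litter)) facs$litter <- stats::model.matrix(~litter)[, -1, drop = FALSE]
  facs$treatment <- stats::model.matrix(~treatment)[, -1, drop = FALSE]

  Hs <- list(); X <- X0
  for (nm in names(facs)) {
    X <- cbind(X, facs[[nm]])
    Hs[[nm]] <- hat(X)
  }
  ss_seq <- function(Gm) {
    tot <- sum(diag(Gm))
    prev <- 0
    ss <- numeric(length(Hs)); names(ss) <- names(Hs)
    for (i in seq_along(Hs)) {
      ex <- sum(Hs[[i]] * Gm)  # tr(H G), H symmetric
      ss[i] <- ex - prev
      prev <- ex
    }
    c(ss, residual = tot - prev, total = tot)
  }
  dfs <- vapply(facs, ncol, integer(1))
  df_res <- n - 1L - sum(dfs)
  obs <- ss_seq(G)
  f_obs <- (obs[names(facs)] / dfs) / (obs["residual"] / df_res)

  set.seed(seed)
  exceed <- setNames(numeric(length(facs)), names(facs))
  for (b in seq_len(n_perm)) {
    prm <- sample.int(n)
    ssp <- ss_seq(G[prm, prm])
    fp <- (ssp[names(facs)] / dfs) / (ssp["residual"] / df_res)
    exceed <- exceed + (fp >= f_obs - 1e-12)
  }
  pvals <- (1 + exceed) / (n_perm + 1)
  out <- data.frame(
    term = c(names(facs), "residual", "total"),
    df = c(dfs, df_res, n - 1L),
    SS = unname(obs[c(names(facs), "residual", "total")]),
    pseudo_F = c(unname(f_obs), NA, NA),
    p = c(unname(pvals), NA, NA),
    row.names = NULL)
  attr(out, "SS_total") <- unname(obs["total"])
  out
}

#' Mean within-group dissimilarity
#'
#' @param dist square symmetric dissimilarity matrix.
#' @param groups factor aligned with the matrix rows.
#' @return named numeric: mean over all within-group pairs, per group.
#' @export
within_group_dissimilarity <- function(dist, groups) {
  dist <- as.matrix(dist)
  groups <- factor(groups)
  stopifnot(length(groups) == nrow(dist))
  sapply(levels(groups), function(g) {
    idx <- which(groups == g)
    if (length(idx) < 2) stop("group '", g, "' has fewer than 2 members")
    sub <- dist[idx, idx]
    mean(sub[upper.tri(sub)])
  })
}

#' Site-level diversity report
#'
#' Alpha diversity with mixed-model treatment contrasts, Bray-Curtis
#' dissimilarities, within-group means, and PERMANOVA — the full
#' diversity-analysis layer for one sampling site.
#'
#' @param table raw (unfiltered) [genus_count_table()].
#' @param metadata metadata data.frame covering the table's samples.
#' @param n_perm PERMANOVA permutations.
#' @param seed RNG seed.
#' @return list: `alpha` (per-sample data.frame), `alpha_contrasts`,
#'   `within_group_bc`, `permanova`.
#' @export
diversity_report <- function(table, metadata, n_perm = 999L, seed = 1L) {
  j <- join_metadata(table, metadata)
  alpha <- alpha_diversity(table)
  contrasts <- lapply(c(observed_genera = "observed_genera",
                        adjusted_shannon = "adjusted_shannon"),
                      function(v) mixed_contrast(alpha[[v]], j$treatment,
                                                 j$litter,
                                                 contrast = c("stress", "control")))
  rel <- relative_abundance(table$counts)
  bc <- bray_curtis(rel)
  list(alpha = alpha,
       alpha_contrasts = contrasts,
       within_group_bc = within_group_dissimilarity(bc, j$treatment),
       permanova = permanova(bc, j$treatment, j$litter,
                             n_perm = n_perm, seed = seed))
}
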