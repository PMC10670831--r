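#' Fit a PLS1 discriminant model (NIPALS)
#'
#' Partial least squares regression of a centred binary class indicator
#' (stress = 1, control = 0) on a column-centred predictor matrix, computed by
#' NIPALS with X-deflation per component. For a single response, each
#' component's weight vector is w_a = X_a' y / ||X_a' y||, the score
#' t_a = X_a w_a, the X-loading p_a = X_a' t_a / (t_a' t_a) and the y-loading
#' q_a = y' t_a / (t_a' t_a). Class prediction thresholds the decentred fitted
#' response at 0.5.
#'
#' @param X numeric matrix samples x predictors (e.g. the clr mean instance).
#' @param y binary response (0/1 numeric or 2-level factor; second level = 1).
#' @param A number of latent components.
#' @return object of class `plsda`: weights W (p x A), scores Tt (n x A),
#'   loadings P (p x A), y-loadings q (length A), coefficients `b` (on centred
#'   X), centres, fitted response, training error, kept predictor names.
#' @export
fit_plsda <- function(X, y, A = 1L) {
  X <- as.matrix(X)
  if (is.factor(y)) y <- as.integer(y) - 1L
  y <- as.numeric(y)
  stopifnot(all(y %in% c(0, 1)), nrow(X) == length(y), nrow(X) >= 4L)
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  sdev <- apply(X, 2, stats::sd)
  if (any(sdev == 0)) {
    warning("dropping zero-variance column(s): ",
            paste(colnames(X)[sdev == 0], collapse = ", "))
    X <- X[, sdev > 0, drop = FALSE]
  }
  p <- ncol(X)
  A <- min(A, p, nrow(X) - 1L)
  x_center <- colMeans(X)
  y_center <- mean(y)
  Xc <- sweep(X, 2, x_center)
  yc <- y - y_center

  W <- matrix(0, p, A); P <- matrix(0, p, A); Tt <- matrix(0, nrow(X), A)
  q <- numeric(A)
  Xa <- Xc
  for (a in seq_len(A)) {
    w <- crossprod(Xa, yc)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) { A <- a - 1L; break }  # nothing left to extract
    w <- w / nw
    t_a <- Xa %*% w
    tt <- sum(t_a^2)
    p_a <- crossprod(Xa, t_a) / tt
    q_a <- sum(yc * t_a) / tt
    W[, a] <- w; P[, a] <- p_a; Tt[, a] <- t_a; q[a] <- q_a
    Xa <- Xa - t_a %*% t(p_a)
  }
  if (A < 1L) stop("no usable PLS component (response orthogonal to X)")
  W <- W[, seq_len(A), drop = FALSE]; P <- P[, seq_len(A), drop = FALSE]
  Tt <- Tt[, seq_len(A), drop = FALSE]; q <- q[seq_len(A)]
  # regression coefficients on centred X: b = W (P'W)^-1 q
  b <- W %*% solve(crossprod(P, W), q)
  fitted <- drop(Tt %*% q) + y_center
  model <- structure(list(
    W = W, P = P, Tt = Tt, q = q, A = A, b = drop(b),
    x_center = x_center, y_center = y_center,
    predictors = colnames(X), fitted = fitted,
    train_error = mean(as.integer(fitted >= 0.5) != y)),
    class = "plsda")
  model
}

#' @export
print.plsda <- function(x, ...) {
  cat(sprintf("plsda: %d component(s), %d predictors, training error %.3f\n",
              x$A, length(x$b), x$train_error))
  invisible(x)
}

#' Predict from a fitted PLS-DA model
#'
#' @param object a `plsda` model.
#' @param newdata matrix with the model's predictor columns.
#' @param type "class" (0/1 at the 0.5 threshold) or "response" (continuous).
#' @param ... unused.
#' @export
predict.plsda <- function(object, newdata, type = c("class", "response"), ...) {
  type <- match.arg(type)
  newdata <- as.matrix(newdata)
  if (!is.null(object$predictors) && !is.null(colnames(newdata)))
    newdata <- newdata[, object$predictors, drop = FALSE]
  yhat <- drop(sweep(newdata, 2, object$x_center) %*% object$b) + object$y_center
  if (type == "response") yhat else as.integer(yhat >= 0.5)
}

#' Variable importance in projection
#'
#' VIP_j = sqrt( p * sum_a SSY_a (w_aj / ||w_a||)^2 / sum_a SSY_a ) with
#' SSY_a = q_a^2 t_a' t_a, so that sum_j VIP_j^2 = p.
#'
#' @param model a fitted `plsda` model.
#' @return named numeric vector of VIP scores, one per retained predictor.
#' @export
vip_scores <- function(model) {
  stopifnot(inherits(model, "plsda"))
  p <- nrow(model$W)
  ssy <- model$q^2 * colSums(model$Tt^2)
  wn <- sweep(model$W, 2, sqrt(colSums(model$W^2)), "/")
  vip <- sqrt(p * drop(wn^2 %*% ssy) / sum(ssy))
  names(vip) <- model$predictors
  vip
}

#' Leave-one-out selection of the number of components
#'
#' For each A up to `A_max`, refits the model on n-1 samples and classifies
#' the held-out sample; returns the A minimising LOO classification error
#' (ties towards the smallest A).
#'
#' @inheritParams fit_plsda
#' @param A_max largest number of components considered (default 5).
#' @return list: `A` (selected), `errors` (LOO error per candidate A).
#' @export
loo_select_components <- function(X, y, A_max = 5L) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  if (is.factor(y)) y <- as.integer(y) - 1L
  n <- nrow(X)
  A_max <- min(A_max, ncol(X), n - 2L)
  wrong <- matrix(0L, n, A_max)
  for (i in seq_len(n)) {
    for (a in seq_len(A_max)) {
      m <- tryCatch(fit_plsda(X[-i, , drop = FALSE], y[-i], A = a),
                    error = function(e) NULL)
      pred <- if (is.null(m)) NA_integer_
              else predict(m, X[i, , drop = FALSE], type = "class")
      wrong[i, a] <- as.integer(!identical(pred, as.integer(y[i])))
    }
  }
  errors <- colMeans(wrong)
  list(A = which.min(errors), errors = errors)
}

#' LOO classification error at a fixed number of components
#' @inheritParams fit_plsda
#' @return misclassification rate.
#' @export
loo_error <- function(X, y, A) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  if (is.factor(y)) y <- as.integer(y) - 1L
  n <- nrow(X)
  wrong <- logical(n)
  for (i in seq_len(n)) {
    m <- fit_plsda(X[-i, , drop = FALSE], y[-i], A = A)
    wrong[i] <- predict(m, X[i, , drop = FALSE], type = "class") != y[i]
  }
  mean(wrong)
}

#' Sequential PLS-DA / VIP feature elimination
#'
#' Round 0 fits with the LOO-selected number of components and removes all
#' predictors with VIP < `vip_cut`; subsequent rounds refit (components again
#' LOO-selected, in practice collapsing to 1) and remove again. The loop
#' stops when (a) the candidate round's LOO error exceeds the previous
#' round's — discrimination is being lost, keep the previous round — or
#' (b) no predictor falls below the cut, or (c) fewer than `min_genera`
#' predictors would remain. It always terminates: the retained set strictly
#' shrinks or a stop condition fires.
#'
#' @inheritParams fit_plsda
#' @param vip_cut VIP retention threshold (default 0.8).
#' @param A_max components considered by LOO selection (default 5).
#' @param min_genera smallest admissible retained-set size (default 3).
#' @return list: `rounds` (data.frame round / n_genera / A / loo_error /
#'   stop_reason on the last row), `final_genera`, `final_model`,
#'   `final_loo_error`, `classification_rate` (1 - final LOO error).
#' @export
sequential_elimination <- function(X, y, vip_cut = 0.8, A_max = 5L,
                                   min_genera = 3L) {
  X <- as.matrix(X)
  if (is.factor(y)) y <- as.integer(y) - 1L
  stopifnot(ncol(X) >= 2L)
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))

  keep <- colnames(X)
  sel <- loo_select_components(X[, keep, drop = FALSE], y, A_max = A_max)
  model <- fit_plsda(X[, keep, drop = FALSE], y, A = sel$A)
  err <- sel$errors[sel$A]
  rounds <- data.frame(round = 0L, n_genera = length(keep), A = sel$A,
                       loo_error = err, stop_reason = NA_character_)
  stop_reason <- NULL
  r <- 0L
  while (is.null(stop_reason)) {
    vip <- vip_scores(model)
    cand <- model$predictors[vip >= vip_cut]
    if (length(cand) == length(model$predictors)) {
      stop_reason <- "no genus below VIP cut"
    } else if (length(cand) < min_genera) {
      stop_reason <- sprintf("fewer than %d genera would remain", min_genera)
    } else {
      sel_c <- loo_select_components(X[, cand, drop = FALSE], y, A_max = A_max)
      err_c <- sel_c$errors[sel_c$A]
      if (err_c > err + 1e-12) {
        stop_reason <- "candidate round lost discrimination (LOO error rose)"
      } else {
        r <- r + 1L
        keep <- cand
        model <- fit_plsda(X[, keep, drop = FALSE], y, A = sel_c$A)
        err <- err_c
        rounds <- rbind(rounds, data.frame(round = r, n_genera = length(keep),
                                           A = sel_c$A, loo_error = err,
                                           stop_reason = NA_character_))
      }
    }
  }
  rounds$stop_reason[nrow(rounds)] <- stop_reason
  list(rounds = rounds, final_genera = keep, final_model = model,
       final_loo_error = unname(err), classification_rate = 1 - unname(err))
}

#' Welch's t-test on a single pair of groups
#'
#' Unequal-variance t with Welch-Satterthwaite degrees of freedom. Kept
#' separate from `stats::t.test` so the ensemble version can be vectorised;
#' `stats::t.test` is its oracle in the test-suite.
#'
#' @param x,y numeric vectors (each of length >= 2).
#' @return list: t, df, p.
#' @export
welch_t <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  stopifnot(n1 >= 2L, n2 >= 2L)
  v1 <- stats::var(x) / n1; v2 <- stats::var(y) / n2
  tval <- (mean(x) - mean(y)) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  list(t = tval, df = df, p = 2 * stats::pt(-abs(tval), df))
}

#' Welch enrichment calls over a clr ensemble
#'
#' For each genus in `genus_set`, Welch's t is computed on every Monte-Carlo
#' clr instance and the reported p-value is the arithmetic mean over instances
#' (the "expected p" convention). Benjamini-Hochberg adjustment is applied
#' across the genus set. Effect sizes are the stress - control difference of
#' the ensemble mean instance, expressed in pooled-SD units; the direction is
#' "enriched"/"depleted" in the stress group, or "none" at exactly zero
#' difference.
#'
#' @param ensemble a `clr_ensemble` (or a plain matrix, treated as K = 1).
#' @param labels 2-level factor; the level named "stress" (or the first
#'   level) is the enriched-direction reference.
#' @param genus_set genus ids to test (default: all columns).
#' @return data.frame: genus, effect_sd, direction, vip-ready ordering columns
#'   p (expected over instances) and q (BH).
#' @export
welch_enrichment <- function(ensemble, labels, genus_set = NULL) {
  if (inherits(ensemble, "clr_ensemble")) {
    inst <- ensemble$instances
    mean_inst <- ensemble$mean
  } else {
    mean_inst <- as.matrix(ensemble)
    inst <- array(mean_inst, dim = c(dim(mean_inst), 1L),
                  dimnames = c(dimnames(mean_inst), list(NULL)))
  }
  labels <- factor(labels)
  stopifnot(nlevels(labels) == 2L)
  stress_lev <- if ("stress" %in% levels(labels)) "stress" else levels(labels)[1]
  other_lev <- setdiff(levels(labels), stress_lev)
  i1 <- which(labels == stress_lev); i2 <- which(labels == other_lev)
  if (length(i1) < 2L || length(i2) < 2L)
    stop("each group needs at least 2 samples")
  if (is.null(genus_set)) genus_set <- colnames(mean_inst)
  stopifnot(all(genus_set %in% colnames(mean_inst)))

  K <- dim(inst)[3]
  n1 <- length(i1); n2 <- length(i2)
  res <- lapply(genus_set, function(g) {
    pk <- numeric(K)
    for (k in seq_len(K)) {
      w <- welch_t(inst[i1, g, k], inst[i2, g, k])
      pk[k] <- w$p
    }
    m1 <- mean(mean_inst[i1, g]); m2 <- mean(mean_inst[i2, g])
    s1 <- stats::var(mean_inst[i1, g]); s2 <- stats::var(mean_inst[i2, g])
    pooled <- sqrt(((n1 - 1) * s1 + (n2 - 1) * s2) / (n1 + n2 - 2))
    diff <- m1 - m2
    data.frame(genus = g,
               effect_sd = if (pooled > 0) diff / pooled else 0,
               clr_difference = diff,
               direction = if (diff > 0) "enriched"
                           else if (diff < 0) "depleted" else "none",
               p = mean(pk))
  })
  out <- do.call(rbind, res)
  out$q <- stats::p.adjust(out$p, method = "BH")
  rownames(out) <- NULL
  out
}

#' Full biomarker discovery for one site
#'
#' Sequential PLS-DA/VIP elimination on the ensemble mean instance followed by
#' Welch enrichment calls on the final genus set.
#'
#' @param ensemble a `clr_ensemble`.
#' @param labels 2-level treatment factor.
#' @inheritParams sequential_elimination
#' @return list: `report` (enrichment table with VIPs merged in),
#'   `elimination`, `classification_rate`, `scores`, `loadings` (biplot
#'   coordinates).
#' @export
biomarker_discovery <- function(ensemble, labels, vip_cut = 0.8, A_max = 5L) {
  labels <- factor(labels)
  y <- as.integer(labels == if ("stress" %in% levels(labels)) "stress"
                            else levels(labels)[1])
  elim <- sequential_elimination(ensemble$mean, y, vip_cut = vip_cut,
                                 A_max = A_max)
  rep <- welch_enrichment(ensemble, labels, genus_set = elim$final_genera)
  vip <- vip_scores(elim$final_model)
  rep$vip <- unname(vip[rep$genus])
  rep <- rep[order(-rep$vip), ]
  rownames(rep) <- NULL
  list(report = rep, elimination = elim,
       classification_rate = elim$classification_rate,
       scores = elim$final_model$Tt, loadings = elim$final_model$P)
}
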