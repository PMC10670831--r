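#' Default pathogen genera
#'
#' Opportunistic pathogens tracked by the susceptibility layer; configurable
#' everywhere they are consumed.
#' @export
default_pathogens <- function() c("Clostridium", "Treponema",
                                  "Streptococcus", "Campylobacter")

#' One-sided normal tail probability behind the susceptibility factor
#'
#' Under a normal model, an observation `factor` standard deviations above the
#' centre is exceeded with probability `1 - pnorm(factor)`; at the default 2.5
#' this is ~0.006, the significance level that motivates the cut-off.
#'
#' @param factor number of standard deviations (default 2.5).
#' @return upper-tail probability.
#' @export
susceptibility_tail_prob <- function(factor = 2.5) {
  stats::pnorm(factor, lower.tail = FALSE)
}

#' Median-ratio susceptibility classifier
#'
#' An animal is called susceptible to a pathogen at a site when its relative
#' abundance of that genus is at least `factor` times (inclusive) the median
#' relative abundance within its treatment group. If a group's median is zero
#' the ratio is undefined and every member is called resistant with a warning.
#' The rule is ratio-based, hence invariant to rescaling all abundances.
#'
#' @param rel_abund matrix samples x genera of relative abundances (one site).
#' @param treatment 2-level factor aligned with rows.
#' @param pathogen_list genus ids to classify (default [default_pathogens()]).
#' @param factor ratio threshold (default 2.5).
#' @param site site label carried into the output.
#' @param animal_id optional ids (default row names).
#' @return data.frame: animal_id, pathogen, site, abundance, group_median,
#'   ratio, label ("susceptible"/"resistant").
#' @export
classify_susceptibility <- function(rel_abund, treatment,
                                    pathogen_list = default_pathogens(),
                                    factor = 2.5, site = "unknown",
                                    animal_id = NULL) {
  rel_abund <- as.matrix(rel_abund)
  treatment <- droplevels(base::factor(treatment))  # `factor` arg shadows base
  stopifnot(length(treatment) == nrow(rel_abund))
  if (min(table(treatment)) < 3L)
    stop("each treatment group needs at least 3 animals")
  absent <- setdiff(pathogen_list, colnames(rel_abund))
  if (length(absent))
    stop("pathogen genus absent from table: ", paste(absent, collapse = ", "))
  if (is.null(animal_id)) animal_id <- rownames(rel_abund)
  out <- list()
  for (pg in pathogen_list) {
    x <- rel_abund[, pg]
    med <- tapply(x, treatment, stats::median)
    gm <- med[as.character(treatment)]
    ratio <- ifelse(gm > 0, x / gm, NA_real_)
    if (any(gm == 0)) {
      warning(sprintf(
        "all-zero group median for '%s' (%s); affected animals set resistant",
        pg, paste(names(med)[med == 0], collapse = ", ")))
    }
    label <- ifelse(!is.na(ratio) & ratio >= factor, "susceptible", "resistant")
    out[[pg]] <- data.frame(animal_id = animal_id, pathogen = pg, site = site,
                            abundance = unname(x), group_median = unname(gm),
                            ratio = unname(ratio), label = label,
                            row.names = NULL)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Bayesian mixed-model contrast with posterior sign probabilities
#'
#' Gaussian linear mixed model y = X beta + Z u + e with treatment and
#' susceptibility as fixed effects and a litter random intercept, sampled by
#' Gibbs with fully conjugate updates. Priors: beta ~ N(0, (10 sd(y))^2),
#' half-Student-t(3, scale 2.5 sd(y)) on both sigma_litter and sigma_e via
#' the inverse-gamma parameter-expansion representation. Pr0 is the fraction
#' of post-warm-up draws in which an effect is positive; split-chain R-hat
#' above 1.1 flags (but does not abort) the fit.
#'
#' @param y numeric response (clr abundance of one pathogen at one site).
#' @param treatment 2-level factor; effect reported for the "stress" level
#'   (or the second level) versus the other.
#' @param susceptibility optional 2-level factor ("susceptible" vs
#'   "resistant"); effect reported for "susceptible". NULL omits the term.
#' @param litter grouping factor for the random intercept.
#' @param n_iter iterations per chain, half discarded as warm-up
#'   (default 2000).
#' @param n_chains number of chains (default 4).
#' @param seed RNG seed.
#' @return list with per-effect posterior mean, 95% credible interval, Pr0,
#'   R-hat; plus sigma summaries, draws kept per effect, and a `converged`
#'   flag.
#' @export
bayes_mixed_contrast <- function(y, treatment, susceptibility = NULL, litter,
                                 n_iter = 2000L, n_chains = 4L, seed = 1L) {
  treatment <- droplevels(factor(treatment))
  litter <- droplevels(factor(litter))
  stopifnot(nlevels(treatment) == 2L, nlevels(litter) >= 2L,
            length(y) == length(treatment), length(y) == length(litter))
  ref <- if ("stress" %in% levels(treatment)) "stress" else levels(treatment)[2]
  xt <- as.numeric(treatment == ref)
  X <- cbind(intercept = 1, treatment = xt)
  eff_names <- "treatment"
  if (!is.null(susceptibility)) {
    susceptibility <- droplevels(factor(susceptibility))
    sref <- if ("susceptible" %in% levels(susceptibility)) "susceptible"
            else levels(susceptibility)[2]
    if (nlevels(susceptibility) == 2L) {
      X <- cbind(X, susceptibility = as.numeric(susceptibility == sref))
      eff_names <- c(eff_names, "susceptibility")
    }
  }
  if (qr(X)$rank < ncol(X)) stop("fixed-effect design matrix is rank deficient")
  Z <- stats::model.matrix(~ 0 + litter)
  n <- length(y); pfix <- ncol(X); q <- ncol(Z)
  C <- cbind(X, Z)
  CtC <- crossprod(C)
  Cty <- crossprod(C, y)

  sdy <- stats::sd(y); if (sdy == 0) sdy <- 1
  prior_beta_prec <- 1 / (10 * sdy)^2
  A_scale <- 2.5 * sdy   # half-t scale
  nu <- 3

  keep <- floor(n_iter / 2)
  draws <- array(NA_real_, dim = c(keep, n_chains, pfix + q + 2))
  for (ch in seq_len(n_chains)) {
    set.seed(seed + 1000L * ch)
    sig2_e <- sdy^2; sig2_l <- sdy^2 / 4
    a_e <- a_l <- 1
    for (it in seq_len(n_iter)) {
      # coefficients: joint conjugate normal update
      prec <- CtC / sig2_e
      diag(prec)[seq_len(pfix)] <- diag(prec)[seq_len(pfix)] + prior_beta_prec
      diag(prec)[pfix + seq_len(q)] <- diag(prec)[pfix + seq_len(q)] + 1 / sig2_l
      R <- chol(prec)
      mu <- backsolve(R, forwardsolve(t(R), Cty / sig2_e))
      theta <- mu + backsolve(R, stats::rnorm(pfix + q))
      u <- theta[pfix + seq_len(q)]
      resid <- y - C %*% theta
      # variances: inverse-gamma updates (half-t via parameter expansion)
      sig2_e <- 1 / stats::rgamma(1, (nu + n) / 2,
                                  nu / a_e + sum(resid^2) / 2)
      sig2_l <- 1 / stats::rgamma(1, (nu + q) / 2,
                                  nu / a_l + sum(u^2) / 2)
      a_e <- 1 / stats::rgamma(1, (nu + 1) / 2, nu / sig2_e + 1 / A_scale^2)
      a_l <- 1 / stats::rgamma(1, (nu + 1) / 2, nu / sig2_l + 1 / A_scale^2)
      if (it > n_iter - keep)
        draws[it - (n_iter - keep), ch, ] <- c(theta, sig2_l, sig2_e)
    }
  }

  rhat <- function(mat) {  # mat: iterations x chains, split-chain R-hat
    half <- floor(nrow(mat) / 2)
    sp <- cbind(mat[seq_len(half), , drop = FALSE],
                mat[half + seq_len(half), , drop = FALSE])
    m <- ncol(sp); nn <- nrow(sp)
    means <- colMeans(sp); vars <- apply(sp, 2, stats::var)
    B <- nn * stats::var(means); W <- mean(vars)
    if (W == 0) return(1)
    sqrt(((nn - 1) / nn * W + B / nn) / W)
  }

  effects <- list()
  idx <- setNames(1 + seq_along(eff_names), eff_names)
  for (nm in eff_names) {
    d <- draws[, , idx[[nm]], drop = FALSE]
    v <- as.vector(d)
    effects[[nm]] <- list(
      mean = mean(v),
      ci95 = unname(stats::quantile(v, c(0.025, 0.975))),
      pr0 = mean(v > 0),
      rhat = rhat(matrix(d, nrow = dim(d)[1])))
  }
  sig_l <- sqrt(as.vector(draws[, , pfix + q + 1]))
  sig_e <- sqrt(as.vector(draws[, , pfix + q + 2]))
  rhats <- vapply(effects, function(e) e$rhat, numeric(1))
  list(effects = effects,
       sigma_litter = c(mean = mean(sig_l), sd = stats::sd(sig_l)),
       sigma_e = c(mean = mean(sig_e), sd = stats::sd(sig_e)),
       n_draws = keep * n_chains, n_chains = n_chains,
       converged = all(rhats < 1.1))
}

#' Susceptibility layer for one site
#'
#' Classifies every animal against every pathogen and fits the Bayesian
#' treatment + susceptibility model on each pathogen's clr abundance.
#'
#' @param table raw [genus_count_table()] for the site.
#' @param metadata metadata covering the samples.
#' @param pathogen_list pathogens to analyse.
#' @param factor median-ratio threshold.
#' @param clr_matrix optional precomputed clr matrix (defaults to the clr of
#'   prior-smoothed proportions, prior 0.5).
#' @inheritParams bayes_mixed_contrast
#' @return list: `calls` (classifier output), `posteriors` (per pathogen).
#' @export
resistance_analysis <- function(table, metadata,
                                pathogen_list = default_pathogens(),
                                factor = 2.5, clr_matrix = NULL,
                                n_iter = 2000L, n_chains = 4L, seed = 1L) {
  j <- join_metadata(table, metadata)
  rel <- relative_abundance(table$counts)
  calls <- classify_susceptibility(rel, j$treatment, pathogen_list,
                                   factor = factor, site = table$site,
                                   animal_id = j$animal_id)
  if (is.null(clr_matrix))
    clr_matrix <- clr_transform(sweep(table$counts + 0.5, 1,
                                      rowSums(table$counts + 0.5), "/"))
  posteriors <- lapply(setNames(pathogen_list, pathogen_list), function(pg) {
    lab <- calls$label[calls$pathogen == pg][match(j$animal_id,
                                                   calls$animal_id[calls$pathogen == pg])]
    susc <- base::factor(lab, levels = c("resistant", "susceptible"))
    if (nlevels(droplevels(susc)) < 2L) susc <- NULL
    bayes_mixed_contrast(clr_matrix[, pg], j$treatment, susc, j$litter,
                         n_iter = n_iter, n_chains = n_chains, seed = seed)
  })
  list(calls = calls, posteriors = posteriors)
}
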