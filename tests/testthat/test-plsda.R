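test_that("a perfect predictor yields zero error and one component", {
  set.seed(1)
  n <- 20
  y <- rep(c(0, 1), n / 2)
  X <- cbind(y, matrix(rnorm(n * 4, sd = 0.1), n, 4))
  colnames(X) <- paste0("g", 1:5)
  m <- fit_plsda(X, y, A = 1)
  expect_equal(m$train_error, 0)
  sel <- loo_select_components(X, y, A_max = 3)
  expect_equal(sel$A, 1L)          # monotone tie -> smallest A
  expect_equal(sel$errors[1], 0)
})

test_that("one-component weights match the closed form w = X'y / ||X'y||", {
  set.seed(2)
  X <- matrix(rnorm(40), 20, 2); colnames(X) <- c("a", "b")
  y <- rep(c(0, 1), 10)
  m <- fit_plsda(X, y, A = 1)
  Xc <- scale(X, scale = FALSE); yc <- y - mean(y)
  w <- crossprod(Xc, yc); w <- w / sqrt(sum(w^2))
  expect_equal(unname(m$W[, 1]), unname(drop(w)), tolerance = 1e-8)
})

test_that("scores are orthogonal and VIP identities hold", {
  set.seed(3)
  X <- matrix(rnorm(38 * 12), 38, 12)
  y <- rep(c(0, 1), 19)
  for (A in c(1, 3, 5)) {
    m <- fit_plsda(X, y, A = A)
    G <- crossprod(m$Tt)
    expect_lt(max(abs(G[upper.tri(G)])), 1e-6)
    vip <- vip_scores(m)
    expect_equal(sum(vip^2), ncol(X), tolerance = 1e-6)  # sum VIP^2 = p
  }
  # symmetric 2-predictor, 1-component: equal |weights| -> VIP = (1, 1)
  Xs <- cbind(a = y + rnorm(38, sd = 0.1))
  Xs <- cbind(Xs, b = Xs[, "a"])
  ms <- fit_plsda(Xs, y, A = 1)
  expect_equal(unname(vip_scores(ms)), c(1, 1), tolerance = 1e-10)
  # hand computation: weights (0.6, 0.8) -> VIP = sqrt(2) * (0.6, 0.8)
  mh <- ms; mh$W <- matrix(c(0.6, 0.8), 2, 1)
  expect_equal(unname(vip_scores(mh)), c(0.8485, 1.1314), tolerance = 1e-4)
})

test_that("null models show chance-level LOO error", {
  set.seed(4)
  errs <- replicate(200, {
    X <- matrix(rnorm(38 * 10), 38, 10)
    y <- rep(c(0, 1), 19)
    loo_error(X, y, A = 1)
  })
  expect_gt(mean(errs), 0.35)
  expect_lt(mean(errs), 0.65)
})

test_that("sequential elimination terminates and obeys its stop rules", {
  set.seed(5)
  y <- rep(c(0, 1), 19)
  # all predictors informative & symmetric -> all VIP >= 0.8, loop stops with
  # the full set
  sig <- y + rnorm(38, sd = 0.4)
  X2 <- cbind(a = sig, b = sig + rnorm(38, sd = 0.05),
              c = -sig + rnorm(38, sd = 0.05))
  se2 <- sequential_elimination(X2, y)
  expect_setequal(se2$final_genera, c("a", "b", "c"))
  expect_match(se2$rounds$stop_reason[nrow(se2$rounds)], "no genus below")

  # pure noise: terminates within p rounds; round-0 LOO error is at chance
  # (the post-selection error is optimistically biased -- see ledger/vignette)
  Xn <- matrix(rnorm(38 * 30), 38, 30)
  sen <- suppressWarnings(sequential_elimination(Xn, y))
  expect_lte(nrow(sen$rounds), 30)
  expect_gte(sen$rounds$loo_error[1], 0.35)
  expect_equal(sen$classification_rate, 1 - sen$final_loo_error)
})

test_that("planted biomarkers are recovered by the elimination loop", {
  set.seed(6)
  hits <- 0L
  reps <- 10L
  for (r in seq_len(reps)) {
    n <- 38; p <- 50
    y <- rep(c(0, 1), n / 2)
    X <- matrix(rnorm(n * p), n, p)
    colnames(X) <- paste0("g", seq_len(p))
    planted <- paste0("g", 1:5)
    X[, planted] <- X[, planted] + outer(y - mean(y), rep(1.5, 5))
    se <- suppressWarnings(sequential_elimination(X, y))
    hits <- hits + (sum(planted %in% se$final_genera) >= 4)
  }
  expect_gte(hits / reps, 0.8)
})

test_that("welch_t matches stats::t.test and enrichment conventions hold", {
  w <- welch_t(c(1, 2, 3), c(4, 5, 6))
  expect_equal(w$t, -3.674, tolerance = 1e-3)
  expect_equal(w$df, 4, tolerance = 1e-10)
  expect_equal(w$p, 0.0214, tolerance = 1e-2)  # exact value 0.021312
  tt <- t.test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(w$t, unname(tt$statistic), tolerance = 1e-10)
  expect_equal(w$p, tt$p.value, tolerance = 1e-10)

  # zero difference -> effect 0, direction "none"
  m <- matrix(rnorm(8 * 3), 8, 3, dimnames = list(paste0("s", 1:8), paste0("g", 1:3)))
  m[, "g2"] <- rep(c(1, 1, 2, 2), 2)  # identical group distributions
  lab <- factor(rep(c("stress", "control"), 4))
  rep_tab <- welch_enrichment(m, lab)
  expect_equal(rep_tab$direction[rep_tab$genus == "g2"], "none")
  expect_equal(rep_tab$effect_sd[rep_tab$genus == "g2"], 0)

  # direction is consistent with the sign of the clr difference
  co <- quick_cohort(seed = 61)
  ens <- dirichlet_clr(abundance_filter(co$table)$table, K = 6, seed = 2)
  out <- welch_enrichment(ens, co$join$treatment)
  d <- colMeans(ens$mean[co$join$treatment == "stress", out$genus]) -
       colMeans(ens$mean[co$join$treatment == "control", out$genus])
  expect_true(all(out$direction[d > 0] == "enriched"))
  expect_true(all(out$direction[d < 0] == "depleted"))
  expect_error(welch_enrichment(m[1:3, ], factor(c("stress", "control", "stress"))),
               "at least 2")
})
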