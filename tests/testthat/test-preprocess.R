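test_that("clr transform: hand values, zero row sums, scale invariance", {
  v <- clr_transform(c(0.5, 0.25, 0.25))
  expect_equal(v, c(0.4621, -0.2310, -0.2310), tolerance = 1e-3)
  expect_equal(sum(v), 0, tolerance = 1e-12)
  expect_equal(clr_transform(rep(1 / 5, 5)), rep(0, 5))
  x <- matrix(rexp(40) + 0.01, 8, 5)
  expect_equal(clr_transform(x), clr_transform(17.3 * x), tolerance = 1e-12)
  expect_error(clr_transform(c(1, 0, 2)), "positive")
})

test_that("abundance filter is strict 'lower than' with boundary retained", {
  # 4 samples x 3 genera; g2 constant at 0.0005, g3 at exactly 0.001
  tot <- 10000
  cnt <- cbind(g1 = rep(tot - 15, 4), g2 = rep(5, 4), g3 = rep(10, 4))
  rownames(cnt) <- paste0("s", 1:4)
  tab <- genus_count_table(cnt)
  out <- abundance_filter(tab)
  expect_identical(out$dropped, "g2")
  expect_true("g3" %in% colnames(out$table$counts))  # mean exactly 0.001 kept
  expect_error(abundance_filter(tab, min_mean_rel_abund = 0.9999),
               "review the threshold")
})

test_that("prevalence rule and tie-breaking follow the contract", {
  set.seed(1)
  n <- 20
  labels <- factor(rep(c("stress", "control"), each = n / 2))
  # two perfectly separating genera present in all samples + one rare genus
  g1 <- ifelse(labels == "stress", 400L, 100L)
  g2 <- ifelse(labels == "stress", 100L, 400L)
  rare <- integer(n); rare[sample.int(n, 8)] <- 5L  # 40% prevalence
  cnt <- cbind(sep1 = g1, sep2 = g2, rare = rare,
               fill = rep(500L, n))
  rownames(cnt) <- paste0("s", 1:n)
  tab <- genus_count_table(cnt)

  sr <- prevalence_threshold_search(tab, labels, grid = c(0.1, 0.5, 0.9),
                                    n_trees = 60, seed = 1)
  expect_true(all(sr$errors$oob_error == 0))   # perfect separators everywhere
  expect_equal(sr$threshold, 0.1)              # tie -> smallest threshold

  # genus at 40% prevalence is excluded at threshold 0.50
  kept <- apply_prevalence_filter(tab, labels, 0.50)
  expect_false("rare" %in% colnames(kept$counts))
  expect_true("rare" %in% colnames(apply_prevalence_filter(tab, labels, 0.20)$counts))
})

test_that("null labels give high minimum out-of-bag error", {
  # spec null band: min OOB over the grid >= 0.25 in >= 90% of replicates
  co <- quick_cohort(seed = 31, truth_fn = null_truth)
  ok <- 0L
  reps <- 20L
  for (r in seq_len(reps)) {
    set.seed(r)
    perm <- sample(co$join$treatment)
    sr <- suppressWarnings(
      prevalence_threshold_search(co$table, perm,
                                  grid = seq(0.1, 0.9, by = 0.2),
                                  n_trees = 40, seed = r))
    ok <- ok + (min(sr$errors$oob_error, na.rm = TRUE) >= 0.25)
  }
  expect_gte(ok / reps, 0.9)
})

test_that("Dirichlet-clr ensemble: geometry, determinism, degenerate input", {
  co <- quick_cohort(seed = 41)
  tab <- abundance_filter(co$table)$table
  ens <- dirichlet_clr(tab, K = 8, seed = 7)
  # every row of every instance sums to 0 (machine precision)
  sums <- apply(ens$instances, c(1, 3), sum)
  expect_lt(max(abs(sums)), 1e-8)
  expect_lt(max(abs(rowSums(ens$mean))), 1e-8)
  # imputation leaves no zero/negative before the log: clr values all finite
  expect_true(all(is.finite(ens$instances)))
  # fixed seed -> identical ensemble
  ens2 <- dirichlet_clr(tab, K = 8, seed = 7)
  expect_identical(ens$instances, ens2$instances)
  # all-zero row -> error
  bad <- rbind(a = c(0L, 0L), b = c(1L, 2L))
  colnames(bad) <- c("g1", "g2")
  expect_error(dirichlet_clr(genus_count_table(bad), K = 2, seed = 1),
               "all-zero")
})

test_that("preprocess_site runs the full filter chain in order", {
  co <- quick_cohort(seed = 51)
  pp <- suppressWarnings(
    preprocess_site(co$table, co$join$treatment,
                    grid = seq(0.2, 0.8, by = 0.2), n_trees = 40,
                    K = 8, seed = 3))
  expect_s3_class(pp$ensemble, "clr_ensemble")
  expect_lte(ncol(pp$table$counts), ncol(co$table$counts))
  expect_true(all(colnames(pp$ensemble$mean) %in% colnames(pp$table$counts)))
})
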