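test_that("alpha diversity: richness and adjusted Shannon (evenness)", {
  cnt <- rbind(u = rep(3L, 10), s = c(9L, rep(0L, 9)), h = c(2L, 2L, 4L, rep(0L, 7)))
  colnames(cnt) <- paste0("g", 1:10)
  a <- alpha_diversity(genus_count_table(cnt))
  expect_equal(a$observed_genera, c(10L, 1L, 3L))
  expect_equal(a$adjusted_shannon[1], 1.0)                 # uniform -> 1
  expect_equal(a$adjusted_shannon[2], 0)                   # single genus -> 0
  expect_equal(a$adjusted_shannon[3], 1.03972 / log(3), tolerance = 1e-4)
  expect_true(all(a$adjusted_shannon >= 0 & a$adjusted_shannon <= 1))
  cnt0 <- rbind(a = c(0L, 0L), b = c(1L, 1L)); colnames(cnt0) <- c("g1", "g2")
  expect_error(alpha_diversity(cnt0), "empty")
})

test_that("mixed_contrast collapses to OLS and recovers planted effects", {
  # no litter variance, balanced design -> estimate = difference of group means
  set.seed(1)
  n <- 24
  tr <- factor(rep(c("stress", "control"), n / 2))
  lt <- factor(rep(1:6, each = 4))
  y <- rnorm(n) + 0.7 * (tr == "stress")
  mc <- mixed_contrast(y, tr, lt, contrast = c("stress", "control"))
  expect_equal(mc$estimate,
               mean(y[tr == "stress"]) - mean(y[tr == "control"]),
               tolerance = 1e-6)

  # parameter recovery: sigma_l = sigma_e = 1, effect 1.0, n = 38
  est <- replicate(200, {
    lt38 <- factor(rep(1:9, length.out = 38))
    tr38 <- factor(rep(c("stress", "control"), length.out = 38))
    y38 <- rnorm(9)[as.integer(lt38)] + rnorm(38) + 1.0 * (tr38 == "stress")
    mixed_contrast(y38, tr38, lt38, contrast = c("stress", "control"))$estimate
  })
  expect_lt(abs(mean(est) - 1.0), 0.15)
})

test_that("Bray-Curtis: hand values, range, symmetry, vegan agreement", {
  expect_equal(bray_curtis(rbind(a = c(1, 0), b = c(0, 1)))["a", "b"], 1)
  expect_equal(bray_curtis(rbind(a = c(2, 3), b = c(2, 3)))["a", "b"], 0)
  expect_equal(bray_curtis(rbind(a = c(6, 2), b = c(2, 2)))["a", "b"],
               1 / 3, tolerance = 1e-10)
  set.seed(2)
  x <- matrix(rexp(60), 10, 6)
  d <- bray_curtis(x)
  expect_equal(d, t(d))
  expect_true(all(d >= 0 & d <= 1))
  expect_equal(unname(diag(d)), rep(0, 10))
})

test_that("PERMANOVA partitions SS exactly and matches vegan::adonis2", {
  skip_if_not_installed("vegan")
  set.seed(3)
  x <- matrix(rexp(80), 16, 5); x <- x / rowSums(x)
  tr <- factor(rep(c("a", "b"), 8))
  lt <- factor(rep(1:4, each = 4))
  d <- bray_curtis(x)
  pv <- permanova(d, tr, lt, n_perm = 499, seed = 1)
  # total SS = sum of parts (machine precision)
  expect_equal(sum(pv$SS[pv$term %in% c("litter", "treatment", "residual")]),
               pv$SS[pv$term == "total"], tolerance = 1e-10)
  av <- vegan::adonis2(stats::as.dist(d) ~ lt + tr, permutations = 499,
                       by = "terms")
  expect_equal(pv$SS[1:2], av$SumOfSqs[1:2], tolerance = 1e-8)
  expect_equal(pv$pseudo_F[1:2], av$F[1:2], tolerance = 1e-8)
  # fixed seed -> identical permutation p
  pv2 <- permanova(d, tr, lt, n_perm = 499, seed = 1)
  expect_identical(pv$p, pv2$p)
  expect_error(permanova(d[, -1], tr, lt), "square")
})

test_that("PERMANOVA has power against a strongly planted treatment shift", {
  hits <- 0L
  for (s in 1:10) {
    co <- quick_cohort(seed = 2100 + s, truth_fn = function(d)
      planted_truth(d, n_enriched = 5, n_depleted = 3, effect_size = 3))
    rel <- relative_abundance(co$table)
    pv <- permanova(bray_curtis(rel), co$join$treatment, co$join$litter,
                    n_perm = 199, seed = s)
    hits <- hits + (pv$p[pv$term == "treatment"] <= 0.05)
  }
  expect_gte(hits / 10, 0.9)
})

test_that("within-group dissimilarity means and degenerate groups", {
  d <- matrix(0, 4, 4, dimnames = list(paste0("s", 1:4), paste0("s", 1:4)))
  d["s1", "s2"] <- d["s2", "s1"] <- 0.2
  d["s1", "s3"] <- d["s3", "s1"] <- 0.4
  d["s2", "s3"] <- d["s3", "s2"] <- 0.6
  g <- factor(c("a", "a", "a", "b"))
  expect_error(within_group_dissimilarity(d, g), "fewer than 2")
  g2 <- factor(c("a", "a", "a", "a"))
  expect_equal(unname(within_group_dissimilarity(d, g2)["a"]),
               mean(c(0.2, 0.4, 0.6, 0, 0, 0)))
  # identical points -> 0
  expect_equal(unname(within_group_dissimilarity(matrix(0, 3, 3),
                                                 factor(rep("a", 3)))["a"]), 0)
})
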