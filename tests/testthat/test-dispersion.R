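test_that("IQRNL matches the interpolated-quantile definition", {
  expect_equal(iqrnl(rep(2.5, 6)), 0)
  # ln k = 0,1,2,3: Q1 = 0.75, Q3 = 2.25 under type-7 quantiles
  expect_equal(iqrnl(exp(0:3)), 1.5)
  set.seed(601)
  ks <- rlnorm(50, 0, 1)
  expect_equal(iqrnl(10 * ks), iqrnl(ks)) # scale invariance
  expect_error(iqrnl(3), "at least 2")
  expect_error(iqrnl(c(1, -2)), "positive")
})

test_that("small-sample IQRNL systematically underestimates the population", {
  set.seed(602)
  sigma <- 1
  pop_value <- 2 * qnorm(0.75) * sigma # 1.349 sigma
  small <- replicate(2000, iqrnl(rlnorm(3, 0, sigma)))
  expect_lt(mean(small), pop_value)
})

test_that("fit sub-population selection ranks by score with stable ties", {
  rec <- data.frame(dataset = "D", sample_id = sprintf("s%02d", 1:5),
                    k = 1:5, dO = c(30, 10, 20, 10, 50))
  top <- select_fit_subpop(rec, "dO", 3)
  expect_equal(top$sample_id, c("s02", "s04", "s03"))
  expect_error(select_fit_subpop(rec, "dO", 9), "exceeds")
  # scoring from sequences when no precomputed column exists
  rec2 <- data.frame(dataset = "D", sample_id = c("a", "b"), k = c(1, 2),
                     sequences = c("GGGGAAAACCCC", "GAGAGAGAGAGA"))
  top2 <- select_fit_subpop(rec2, "dO", 1)
  expect_equal(top2$sample_id, "b") # no G/C hairpin available
})

test_that("large weights make dW selection coincide with dO selection", {
  set.seed(603)
  tab <- synthetic_rate_table(seed = 603)
  sub <- tab[tab$dataset == "H22F", ]
  # records need dN too for dW; score from sequences for both
  sub2 <- sub[, c("dataset", "sample_id", "k", "sequences")]
  by_dO <- select_fit_subpop(sub2, "dO", 3)$sample_id
  by_dW <- select_fit_subpop(sub2, "dW", 3, x = 1e6)$sample_id
  expect_setequal(by_dO, by_dW)
})

test_that("bootstrap estimates are ordered, reproducible, and degenerate-safe", {
  rec <- data.frame(dataset = "D", sample_id = sprintf("s%d", 1:10),
                    k = rep(3, 10), dO = 1:10)
  est <- bootstrap_dispersion_fit(rec, "dO", 4, B = 200, seed = 1)
  expect_equal(c(est$p25, est$p50, est$p75), c(0, 0, 0))
  set.seed(604)
  rec$k <- rlnorm(10, 0, 1)
  e1 <- bootstrap_dispersion_fit(rec, "dO", 4, B = 500, seed = 9)
  e2 <- bootstrap_dispersion_fit(rec, "dO", 4, B = 500, seed = 9)
  expect_identical(c(e1$p25, e1$p50, e1$p75), c(e2$p25, e2$p50, e2$p75))
  expect_true(e1$p25 <= e1$p50 && e1$p50 <= e1$p75)
  r1 <- bootstrap_dispersion_random(rec, 4, B = 100, R = 100, seed = 3)
  expect_true(r1$p25 <= r1$p50 && r1$p50 <= r1$p75)
})

test_that("random-draw bootstrap recovers the lognormal closed form", {
  set.seed(605)
  sigma <- 0.8
  rec <- data.frame(dataset = "D", sample_id = sprintf("s%04d", 1:3000),
                    k = rlnorm(3000, 0, sigma))
  est <- bootstrap_dispersion_random(rec, n = 1000, B = 150, R = 120)
  expect_equal(est$p50, 2 * qnorm(0.75) * sigma, tolerance = 0.08)
  # monotone in the population spread
  rec2 <- rec
  set.seed(606)
  rec2$k <- rlnorm(3000, 0, 2 * sigma)
  est2 <- bootstrap_dispersion_random(rec2, n = 1000, B = 150, R = 120)
  expect_gt(est2$p50, est$p50)
})

test_that("relative dispersion arithmetic and edge cases", {
  mk <- function(p50, p25 = p50, p75 = p50) {
    structure(list(p25 = p25, p50 = p50, p75 = p75, n = 3),
              class = "dispersion_estimate")
  }
  expect_equal(relative_dispersion(mk(1), mk(1))$reduction, 0)
  expect_equal(relative_dispersion(mk(0.16), mk(1))$reduction, 84)
  expect_lt(relative_dispersion(mk(2), mk(1))$reduction, 0)
  expect_error(relative_dispersion(mk(1), mk(0)), "zero")
})

test_that("two-component populations show strong dispersion reduction", {
  set.seed(607)
  n <- 40
  clean <- 1:3
  lnk <- rnorm(n, 14, 1.5)
  lnk[clean] <- rnorm(3, 14, 0.1)
  rec <- data.frame(dataset = "D", sample_id = sprintf("s%02d", 1:n),
                    k = exp(lnk), dO = seq_len(n) * 100)
  fit <- bootstrap_dispersion_fit(rec, "dO", 3, B = 1000, seed = 11)
  rnd <- bootstrap_dispersion_random(rec, 3, B = 500, R = 500, seed = 12)
  rel <- relative_dispersion(fit, rnd)
  expect_lt(rel$normalized, 0.5)
  expect_gt(rel$reduction, 50)
})

test_that("distribution tests separate distinct groups and not identical ones", {
  set.seed(608)
  same <- rlnorm(20, 0, 1)
  expect_gt(distribution_test(same, same, "KS"), 0.99)
  lo <- exp(rnorm(10, 0, 0.1))
  hi <- exp(rnorm(10, 5, 0.1)) # disjoint support on the log scale
  expect_lt(distribution_test(lo, hi, "KS"), 0.05)
  expect_lt(distribution_test(lo, hi, "Wilcoxon"), 0.05)
  expect_lt(distribution_test(lo, hi, "AD", n_perm = 499, seed = 1), 0.05)
  # AD permutation p-value is seed-stable
  p1 <- distribution_test(lo, hi, "AD", n_perm = 199, seed = 5)
  p2 <- distribution_test(lo, hi, "AD", n_perm = 199, seed = 5)
  expect_identical(p1, p2)
  expect_error(distribution_test(numeric(0), hi), "non-empty")
})

test_that("rate tables round-trip through delimited text", {
  tab <- data.frame(dataset = "Z37F", sample_id = c("a", "b"),
                    k = c(1e5, 2e6), temperature = 37,
                    reaction = "formation",
                    sequences = c("ACGT", "GGTT"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_rate_table(tab, path)
  back <- read_rate_table(path)
  expect_equal(back$k, tab$k)
  expect_equal(back$sequences, tab$sequences)
  bad <- tab
  bad$k[1] <- -1
  write_rate_table(bad, path)
  expect_error(read_rate_table(path), "positive")
})
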