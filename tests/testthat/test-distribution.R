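test_that("kde peak finds the mode and averages twin subpeaks", {
  expect_error(kde_peak(rep(3, 50)), "variance")
  expect_error(kde_peak(1:5), "at least 8")

  # symmetric bimodal sample: two equal-height modes near 2 and 4
  x <- c(rep(c(1.9, 2, 2.1), 20), rep(c(3.9, 4, 4.1), 20))
  pk <- kde_peak(x)
  expect_true(pk$subpeaks_averaged)
  expect_equal(pk$peak, 3, tolerance = 0.05)
  expect_gte(nrow(pk$subpeaks), 2)

  # unimodal lognormal: peak near the analytic mode exp(mu - sigma^2)
  set.seed(21)
  y <- rlnorm(2000, 0.5, 0.5)
  pk2 <- kde_peak(y)
  expect_false(pk2$subpeaks_averaged)
  expect_equal(pk2$peak, exp(0.5 - 0.25), tolerance = 0.15)
})

test_that("kde peak shifts with the data", {
  set.seed(33)
  x <- rnorm(300)
  p0 <- kde_peak(x)$peak
  expect_equal(kde_peak(x + 5)$peak, p0 + 5, tolerance = 1e-9)
})

test_that("moment skewness matches direct computation and the z-test calibrates", {
  s <- skewness_test(c(1, 1, 1, 10, 10, 1, 1, 1))
  # symmetric enough? no: direct check on the documented 4-point moment case
  x <- c(1, 1, 1, 10)
  m2 <- mean((x - mean(x))^2); m3 <- mean((x - mean(x))^3)
  expect_equal(m3 / m2^1.5, 1.1547, tolerance = 1e-4)

  sym <- c(-3, -1, 0, 1, 3, -2, 2, 0)
  expect_equal(skewness_test(sym)$b1, 0, tolerance = 1e-12)

  set.seed(8)
  big <- rnorm(10000)
  st <- skewness_test(big)
  expect_lt(abs(st$z), 4)
  expect_lt(abs(st$b1), 0.1)

  skewed <- rlnorm(500, 0, 0.8)
  expect_gt(skewness_test(skewed)$b1, 1)
  expect_lt(skewness_test(skewed)$p_value, 1e-6)
})

test_that("Geary's metric hits its normal limit and flags heavy tails", {
  expect_equal(kurtosis_test(rep(c(-1, 1), 10))$geary, 1)
  set.seed(13)
  g <- kurtosis_test(rnorm(1e5))
  expect_equal(g$geary, sqrt(2 / pi), tolerance = 0.01)
  heavy <- kurtosis_test(rt(5000, df = 3))
  expect_lt(heavy$geary, sqrt(2 / pi))
  expect_lt(heavy$p_value, 1e-4)
  expect_error(kurtosis_test(rep(1, 20)), "variance")
})

test_that("randomization null is degenerate when physiology is shared", {
  ph <- toy_phys(12)
  ph$t_b <- 38; ph$t_lc <- 28
  t_min <- runif(12, -20, 20)
  rn <- randomization_null(ph, t_min, "median", n_reps = 100, seed = 4)
  # permuting temperatures among identical (t_lc, t_b) leaves the ME multiset
  expect_equal(rn$lower, rn$upper, tolerance = 1e-12)
  expect_equal(rn$lower, rn$observed, tolerance = 1e-12)
})

test_that("two-species randomization equals exhaustive enumeration", {
  ph <- toy_phys(2)
  t_min <- c(-10, 5)
  cond <- estimate_conductance(ph$bmr, ph$t_b, ph$t_lc)
  me_of <- function(tm) metabolic_expansibility(
    as.numeric(mr_at_cold_boundary(tm, ph$t_lc, cond, ph$bmr)), ph$bmr)
  support <- c(mean(me_of(t_min)), mean(me_of(rev(t_min))))
  rn <- randomization_null(ph, t_min, "mean", n_reps = 400, seed = 2)
  # every replicate lies on the 2-permutation support, and both points occur
  expect_true(all(apply(abs(outer(rn$stats, support, "-")), 1, min) < 1e-12))
  expect_true(all(apply(abs(outer(rn$stats, support, "-")), 2, min) < 1e-12))
})

test_that("isocline-tracking cohorts fall outside the randomization null", {
  # species whose boundary temperatures sit exactly on their own thermal
  # isocline for a common target ME: shuffling temperatures across species
  # decouples boundary from physiology and inflates the null mean
  ph <- toy_phys(40, seed = 6)
  t_min <- ph$t_lc - 2 * (ph$t_b - ph$t_lc)   # every species at ME = 3
  rn <- randomization_null(ph, t_min, "mean", n_reps = 500, seed = 3)
  expect_equal(rn$observed, 3, tolerance = 1e-12)
  expect_true(rn$observed > rn$upper || rn$observed < rn$lower)
})

test_that("distribution summary bundles all statistics", {
  set.seed(17)
  s <- me_distribution_summary(1 + rlnorm(80, 1, 0.4), seed = 5)
  expect_s3_class(s, "me_distribution_summary")
  expect_gt(s$skewness, 0)
  expect_true(s$dip_p >= 0 && s$dip_p <= 1)
  expect_equal(s$n, 80)
  expect_output(print(s), "ME distribution")
})
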