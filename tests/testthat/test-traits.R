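# normal-equations oracle for least squares
ols_oracle <- function(X, y) drop(solve(crossprod(X), crossprod(X, y)))

test_that("trait OLS matches the normal-equations oracle", {
  set.seed(14)
  n <- 60
  d <- data.frame(
    log10_mass = runif(n, 1, 3),
    diet = sample(c("granivore", "herbivore", "carnivore"), n, replace = TRUE),
    nocturnal = rbinom(n, 1, 0.5),
    torpor = rbinom(n, 1, 0.3))
  d$me_crb <- 3 - 0.6 * d$log10_mass + 1.2 * d$torpor + rnorm(n, 0, 0.4)
  fit <- fit_trait_model(d)
  X <- model.matrix(~ log10_mass + diet + nocturnal + torpor, d)
  beta <- ols_oracle(X, d$me_crb)
  expect_equal(unname(fit$coefficients$estimate),
               unname(beta[fit$coefficients$term]), tolerance = 1e-8)
  expect_equal(fit$r_squared,
               1 - sum(fit$residuals^2) / sum((d$me_crb - mean(d$me_crb))^2))
})

test_that("noise-free linear response is recovered exactly", {
  d <- data.frame(log10_mass = seq(1, 3, length.out = 30))
  d$me_crb <- 5 - 1.5 * d$log10_mass
  # the perfect fit is the point here; R warns about unreliable summaries
  fit <- suppressWarnings(fit_trait_model(d, predictors = "log10_mass"))
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_equal(fit$coefficients$estimate[2], -1.5, tolerance = 1e-12)
})

test_that("null predictors give near-zero r-squared and small t-statistics", {
  set.seed(23)
  n <- 500
  d <- data.frame(
    log10_mass = runif(n, 1, 3),
    torpor = rbinom(n, 1, 0.4),
    nocturnal = rbinom(n, 1, 0.5))
  d$me_crb <- rnorm(n)
  fit <- fit_trait_model(d, predictors = c("log10_mass", "torpor", "nocturnal"))
  expect_lt(fit$r_squared, 0.03)
  expect_true(all(abs(fit$coefficients$t[-1]) < 4))
})

test_that("rank-deficient designs are reported with the offending columns", {
  d <- data.frame(log10_mass = runif(20, 1, 3))
  d$dup <- d$log10_mass
  d$me_crb <- rnorm(20)
  expect_error(fit_trait_model(d, predictors = c("log10_mass", "dup")),
               "rank-deficient")
})

test_that("AICc follows its formula and converges to AIC", {
  expect_equal(aicc(0, 0, 10), 0)
  expect_equal(aicc(-10, 2, 10), 20 + 4 + 12 / 7)
  expect_error(aicc(-10, 9, 10), "n > k")
  expect_lt(abs(aicc(-50, 3, 1e6) - (2 * 50 + 6)), 0.01)
})

test_that("subset enumeration respects marginality", {
  expect_length(coldrange:::model_subsets(c("a", "b")), 4)
  expect_length(coldrange:::model_subsets(c("a", "b", "a:b")), 5)
  subs <- coldrange:::model_subsets(c("a", "b", "a:b"))
  with_int <- Filter(function(s) "a:b" %in% s, subs)
  expect_true(all(vapply(with_int, function(s)
    all(c("a", "b") %in% s), logical(1))))
})

test_that("Akaike weights normalise and are invariant to AICc shifts", {
  set.seed(2)
  d <- data.frame(log10_mass = runif(40, 1, 3), torpor = rbinom(40, 1, 0.5))
  d$me_crb <- 2 + d$torpor + rnorm(40, 0, 0.5)
  dr <- dredge_and_average(d, c("log10_mass", "torpor"))
  expect_equal(nrow(dr$models), 4)
  expect_equal(sum(dr$models$weight), 1, tolerance = 1e-12)
  # shift invariance: weights depend only on deltas
  w2 <- exp(-(dr$models$AICc + 100 - min(dr$models$AICc + 100)) / 2)
  expect_equal(dr$models$weight, w2 / sum(w2), tolerance = 1e-12)
})

test_that("model averaging zeros absent terms and the guard trips", {
  set.seed(3)
  d <- data.frame(log10_mass = runif(50, 1, 3), torpor = rbinom(50, 1, 0.5))
  d$me_crb <- 4 - 1 * d$log10_mass + rnorm(50, 0, 0.3)
  dr <- dredge_and_average(d, c("log10_mass", "torpor"), delta_max = 1e6)
  # averaged torpor coefficient shrunk relative to its full-model estimate
  full <- lm(me_crb ~ log10_mass + torpor, d)
  expect_lt(abs(dr$coefficients["torpor"]), abs(coef(full)["torpor"]) + 1e-12)
  expect_error(dredge_and_average(d, paste0("x", 1:20), max_models = 100),
               "exceed")
})

test_that("a strong single effect is selected on top in nearly all replicates", {
  set.seed(44)
  hits <- 0
  for (i in 1:200) {
    n <- 80
    d <- data.frame(log10_mass = runif(n, 1, 3),
                    torpor = rbinom(n, 1, 0.5),
                    nocturnal = rbinom(n, 1, 0.5))
    d$me_crb <- 2 + 1.5 * d$torpor + rnorm(n, 0, 0.5)
    dr <- dredge_and_average(d, c("log10_mass", "torpor", "nocturnal"))
    if (grepl("torpor", dr$models$terms[1])) hits <- hits + 1
  }
  expect_gte(hits, 190)  # >= 95% of 200 replicates
})
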