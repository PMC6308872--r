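test_that("synthetic climate follows the gradient and warming contract", {
  spec <- synthetic_world_spec(sigma_clim = 0, warming = 0, seed = 2)
  cl <- make_climate(spec)
  # sigma_clim = 0: constant along each latitude row, a - b|lat| exactly
  expect_true(all(apply(cl$current$values, 1, function(r) diff(range(r))) == 0))
  i40 <- which.min(abs(cl$current$lat - 40.25))
  expect_equal(cl$current$values[i40, 1],
               25 - 0.5 * abs(cl$current$lat[i40]))
  # warming 0: future identical
  expect_identical(cl$future$values, cl$current$values)

  spec2 <- synthetic_world_spec(warming = 3, seed = 2)
  cl2 <- make_climate(spec2)
  expect_equal(cl2$future$values - cl2$current$values,
               matrix(3, nrow(cl2$current$values), ncol(cl2$current$values)))
})

test_that("generation is deterministic under a fixed seed", {
  w1 <- make_world(synthetic_world_spec(n_species = 10, seed = 9))
  w2 <- make_world(synthetic_world_spec(n_species = 10, seed = 9))
  expect_identical(w1$climate$current$values, w2$climate$current$values)
  expect_identical(w1$physiology, w2$physiology)
  expect_identical(w1$truth, w2$truth)
  expect_identical(lapply(w1$masks, `[[`, "presence"),
                   lapply(w2$masks, `[[`, "presence"))
  w3 <- make_world(synthetic_world_spec(n_species = 10, seed = 10))
  expect_false(identical(w1$truth$me_true, w3$truth$me_true))
})

test_that("written worlds are byte-identical across runs", {
  w <- make_world(synthetic_world_spec(n_species = 4, seed = 5))
  d1 <- file.path(tempdir(), "wA"); d2 <- file.path(tempdir(), "wB")
  write_world(w, d1); write_world(w, d2)
  f1 <- list.files(d1, recursive = TRUE)
  expect_true(length(f1) >= 7)
  for (f in f1)
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))))
})

test_that("noise-free worlds are recovered exactly by the pipeline arithmetic", {
  spec <- synthetic_world_spec(n_species = 25, sigma_clim = 0, sigma_edge = 0,
                               seed = 12)
  w <- make_world(spec)
  res <- analyze_cohort(normalize_physiology(w$physiology), NULL, w$masks,
                        w$climate$current, NULL, quiet = TRUE)
  tr <- merge(res$species[, c("species_id", "me_crb", "t_b", "t_lc")],
              w$truth[, c("species_id", "me_true")])
  # within one cell's temperature step on the thermal-limit scale
  step <- spec$lapse * spec$res
  err_T <- abs(tr$me_crb - tr$me_true) * (tr$t_b - tr$t_lc)
  expect_true(all(err_T <= step + 1e-9))
})

test_that("edge jitter degrades recovery monotonically", {
  errs <- vapply(c(0, 2, 6), function(sj) {
    spec <- synthetic_world_spec(n_species = 30, sigma_clim = 0,
                                 sigma_edge = sj, seed = 8)
    w <- make_world(spec)
    res <- analyze_cohort(normalize_physiology(w$physiology), NULL, w$masks,
                          w$climate$current, NULL, quiet = TRUE)
    tr <- merge(res$species[, c("species_id", "me_crb")],
                w$truth[, c("species_id", "me_true")])
    median(abs(tr$me_crb - tr$me_true))
  }, numeric(1))
  expect_true(all(diff(errs) > 0))
})

test_that("cohort-level torpor contrast reflects the built-in effect", {
  spec <- synthetic_world_spec(n_species = 150, delta_torpor = 1.5, seed = 16)
  w <- make_world(spec)
  d <- w$truth
  # raw group contrast on the truth table (mass effects add noise around 1.5)
  contrast <- mean(d$me_true[d$torpor == 1]) - mean(d$me_true[d$torpor == 0])
  expect_equal(contrast, 1.5, tolerance = 0.5)
})

test_that("lognormal cohorts give right-skewed pipeline ME distributions", {
  pos <- vapply(1:10, function(s) {
    w <- make_world(synthetic_world_spec(n_species = 60, seed = 100 + s))
    res <- analyze_cohort(normalize_physiology(w$physiology), NULL, w$masks,
                          w$climate$current, NULL, quiet = TRUE)
    skewness_test(res$species$me_crb)$b1 > 0
  }, logical(1))
  expect_gte(sum(pos), 10 * 0.95)
})

test_that("hand-written fixtures enumerate stably", {
  fx1 <- make_fixtures(); fx2 <- make_fixtures()
  expect_identical(names(fx1), names(fx2))
  expect_identical(fx1$clump_grid, fx2$clump_grid)
  expect_equal(sort(tabulate(label_clumps(fx1$clump_grid))), sort(fx1$clump_sizes))
  expect_equal(nrow(fx1$physiology), 2)
  expect_equal(nrow(validate_physiology(fx1$physiology)), 0)
})
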