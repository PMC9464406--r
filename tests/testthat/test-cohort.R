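# Cohort generator: calibration, determinism, observer replicates.

test_that("residual SD derivation follows total_sd * sqrt(1 - R2)", {
  expect_equal(deriveResidualSd(10.8, 0.507), 7.58, tolerance = 0.005)
  expect_equal(deriveResidualSd(5, 0), 5)
  expect_equal(deriveResidualSd(5, 0.999999), 0, tolerance = 0.01)
  expect_error(deriveResidualSd(5, 1))
})

test_that("cohorts are reproducible under a fixed seed", {
  a <- simulateCohort(cohortParams(n_hips = 50, seed = 9))
  b <- simulateCohort(cohortParams(n_hips = 50, seed = 9))
  expect_identical(a, b)
  c2 <- simulateCohort(cohortParams(n_hips = 50, seed = 10))
  expect_false(identical(a$aw, c2$aw))
})

test_that("large-sample marginals match the sex-specific calibration", {
  co <- simulateCohort(cohortParams(n_hips = 1e5, seed = 2))
  male <- co$sex == "male"
  expect_equal(mean(co$aw[male]), 14.6, tolerance = 0.1)
  expect_equal(mean(co$aw[!male]), 20.8, tolerance = 0.1)
  expect_equal(sd(co$aw[male]), 6.6, tolerance = 0.1)
  expect_equal(sd(co$aw[!male]), 8.2, tolerance = 0.1)
  expect_equal(mean(co$aw), 0.53 * 14.6 + 0.47 * 20.8, tolerance = 0.1)
  expect_equal(mean(co$nsa), 127.3, tolerance = 0.1)
  # anteversion and neck-shaft angle are generated independent
  expect_lt(abs(cor(co$fa, co$nsa)), 0.02)
})

test_that("zero residual SD makes anteversion exactly linear", {
  co <- simulateCohort(cohortParams(n_hips = 200, residual_sd = 0, seed = 3))
  # lm warns about the (intended) perfect fit
  fit <- suppressWarnings(olsForced(co$fa, co$aw, co$sex_code))
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_equal(unname(fit$coef), c(4.330, 0.744, -4.998), tolerance = 1e-9)
})

test_that("observer replicates hit the target reliability at n = 2000", {
  co <- simulateCohort(cohortParams(n_hips = 2000, seed = 4))
  obs <- simulateObservers(co, target_icc_intra = 0.96,
                           target_icc_inter = 0.94, seed = 5)
  rel <- observerReliability(obs)
  expect_equal(rel$intra$icc_value, 0.96, tolerance = 0.01)
  expect_equal(rel$inter$icc_value, 0.94, tolerance = 0.01)
})

test_that("degenerate reliability targets are rejected or saturate", {
  co <- simulateCohort(cohortParams(n_hips = 100, seed = 6))
  expect_error(simulateObservers(co, 1.0, 0.9), "strictly inside")
  expect_error(simulateObservers(co, 0.9, 1.0), "strictly inside")
  # an interobserver target above what the session noise allows is impossible
  expect_error(simulateObservers(co, 0.5, 0.99), "incompatible")
  # near-zero session noise drives the intraobserver ICC to 1
  obs <- simulateObservers(co, 0.999999, 0.95, seed = 7)
  rel <- observerReliability(obs)
  expect_gt(rel$intra$icc_value, 0.999)
})

test_that("explained variance and calibrated residual SD are consistent", {
  p <- cohortParams()
  v <- explainedVariance(p)
  sd_cal <- calibrateResidualSd(p, 0.507)
  expect_equal(v / (v + sd_cal^2), 0.507, tolerance = 1e-12)
  # empirical check of the closed form at large n
  co <- simulateCohort(cohortParams(n_hips = 2e5, seed = 8))
  lin <- co$fa - (4.330 + 0.744 * co$aw - 4.998 * co$sex_code)
  expect_equal(var(co$fa) - var(lin), v, tolerance = 0.02 * v)
})
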