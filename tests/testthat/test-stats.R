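# Statistical layer: correlation, chi-square, normality, group comparison,
# the forced-entry regression with diagnostics, and prediction equations.

test_that("pearson correlation matches hand-computed cases", {
  expect_equal(pearsonR(1:10, 1:10)$r, 1)
  expect_equal(pearsonR(1:10, -(1:10))$r, -1)
  expect_equal(pearsonR(1:5, c(2, 1, 4, 3, 5))$r, 0.8)
  expect_error(pearsonR(1:5, rep(3, 5)), "zero variance")
})

test_that("chi-square on 2x2 counts matches the hand formula", {
  expect_equal(chiSquareCounts(matrix(c(10, 10, 20, 20), 2))$statistic, 0)
  expect_equal(chiSquareCounts(matrix(c(10, 0, 0, 10), 2))$statistic, 20)
  expect_equal(chiSquareCounts(matrix(c(53, 53, 47, 47), 2))$statistic, 0)
  expect_error(chiSquareCounts(matrix(c(0, 0, 5, 5), 2)), "marginal")
})

test_that("normality gate passes Gaussian and fails exponential samples", {
  set.seed(1)
  expect_true(normalityGate(rnorm(500))$pass_flag)
  expect_false(normalityGate(rexp(500))$pass_flag)
  expect_error(normalityGate(c(1, 2)), "3 <= n")
  expect_error(normalityGate(rep(1, 10)), "constant")
})

test_that("group comparison reports clinical-style summaries", {
  set.seed(2)
  a <- rnorm(50); b <- rnorm(50, 10)
  gc <- groupCompare(a, b)
  expect_lt(gc$p, 0.001)
  expect_equal(gc$p_display, "< 0.001")
  expect_match(gc$summary_a, "^-?[0-9.]+ ± [0-9.]+ \\(-?[0-9.]+–-?[0-9.]+\\)$")
  same <- groupCompare(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$p, 1)
  # formatting reproduces the printed style on matching input
  x <- c(116.6, 141.0, rep(127.3, 48))
  x <- (x - mean(x)) / sd(x) * 5.2 + 127.3  # mean 127.3, sd 5.2 exactly
  expect_match(groupCompare(x, x)$summary_a, "127.3 ± 5.2")
})

test_that("forced-entry regression equals the pseudoinverse oracle", {
  for (s in 1:20) {
    set.seed(200 + s)
    n <- 50 + s
    aw <- rnorm(n, 17, 8); sex <- rbinom(n, 1, 0.5)
    y <- 4 + 0.7 * aw - 5 * sex + rnorm(n, 0, 7)
    fit <- olsForced(y, aw, sex)
    oracle <- olsOracle(y, cbind(aw, sex))
    expect_equal(unname(fit$coef), oracle$coef, tolerance = 1e-8)
    expect_equal(unname(fit$se), oracle$se, tolerance = 1e-8)
    expect_equal(fit$r_squared, oracle$r2, tolerance = 1e-8)
    expect_equal(fit$f_stat, oracle$f, tolerance = 1e-6)
  }
})

test_that("noiseless data reproduce the generating coefficients exactly", {
  set.seed(3)
  aw <- rnorm(100, 17, 8); sex <- rbinom(100, 1, 0.5)
  y <- 4.330 + 0.744 * aw - 4.998 * sex
  fit <- suppressWarnings(olsForced(y, aw, sex))  # intended perfect fit
  expect_equal(unname(fit$coef), c(4.330, 0.744, -4.998), tolerance = 1e-10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
})

test_that("regression invariants and diagnostics hold", {
  set.seed(4)
  for (s in 1:10) {
    n <- 80
    aw <- rnorm(n, 17, 8); sex <- rbinom(n, 1, 0.5)
    y <- 4 + 0.7 * aw - 5 * sex + rnorm(n, 0, 7)
    fit <- olsForced(y, aw, sex)
    expect_lte(fit$adj_r_squared, fit$r_squared)
    expect_gte(fit$durbin_watson, 0)
    expect_lte(fit$durbin_watson, 4)
    expect_true(all(fit$ci95[, 1] <= fit$coef & fit$coef <= fit$ci95[, 2]))
  }
  expect_error(olsForced(rnorm(10), rnorm(10), rep(1, 10)), "collinear|constant")
})

test_that("Durbin-Watson matches lmtest and approaches 4 for alternating residuals", {
  set.seed(5)
  n <- 200
  aw <- rnorm(n, 17, 8); sex <- rbinom(n, 1, 0.5)
  y <- 4 + 0.7 * aw - 5 * sex + rnorm(n, 0, 7)
  fit <- olsForced(y, aw, sex)
  dw_ref <- unname(lmtest::dwtest(fit$lm)$statistic)
  expect_equal(fit$durbin_watson, dw_ref, tolerance = 1e-10)
  # alternating residual pattern: project alternating noise onto the
  # residual space so the fitted residuals alternate exactly
  e0 <- rep(c(1, -1), n / 2)
  e <- residuals(lm(e0 ~ aw + sex))
  fit2 <- olsForced(4 + 0.7 * aw - 5 * sex + e, aw, sex)
  expect_gt(fit2$durbin_watson, 3.8)
})

test_that("prediction model rounds to the published sex-specific equations", {
  pm <- makePredictionModel(list(coef = c(const = 4.330, aw = 0.744,
                                          sex = -4.998)))
  expect_equal(pm$rounded$slope, 0.7)
  expect_equal(pm$rounded$intercept_male, -0.7)
  expect_equal(pm$rounded$intercept_female, 4.3)
  pm0 <- makePredictionModel(list(coef = c(const = 4.330, aw = 0.744, sex = 0)))
  expect_equal(pm0$rounded$intercept_male, pm0$rounded$intercept_female)
})

test_that("predictions follow the full-precision and rounded equations", {
  pm <- makePredictionModel(list(coef = c(const = 4.330, aw = 0.744,
                                          sex = -4.998)))
  expect_equal(predictFa(0, "female", pm), 4.330)
  expect_equal(predictFa(17.5, "male", pm), 12.352)
  # display rounding can shift predictions by at most
  # |slope error| * max|aw| + |intercept error| over the clinical AW range
  aw <- seq(-5, 45, by = 0.1)
  for (sx in c("male", "female")) {
    gap <- abs(predictFa(aw, sx, pm) - predictFa(aw, sx, pm, rounded = TRUE))
    d_int <- if (sx == "male") abs(pm$coef_const + pm$coef_sex - pm$rounded$intercept_male)
             else abs(pm$coef_const - pm$rounded$intercept_female)
    bound <- abs(pm$coef_aw - pm$rounded$slope) * 45 + d_int
    expect_lte(max(gap), bound + 1e-12)
  }
})

test_that("error fraction uses a strict threshold and matches the tail law", {
  pm <- makePredictionModel(list(coef = c(const = 4.330, aw = 0.744,
                                          sex = -4.998)))
  co0 <- simulateCohort(cohortParams(n_hips = 100, residual_sd = 0, seed = 6))
  expect_equal(errorGt10Fraction(co0, pm), 0, tolerance = 0.05)
  # boundary: an error of exactly 10 does not count
  co1 <- data.frame(sex_code = 0, aw = 0, fa = 4.3 + 10)
  expect_equal(errorGt10Fraction(co1, pm), 0)
  co2 <- data.frame(sex_code = 0, aw = 0, fa = 4.3 + 10.0001)
  expect_equal(errorGt10Fraction(co2, pm), 1)
  # large-sample convergence to the Gaussian tail formula
  co <- simulateCohort(cohortParams(n_hips = 1e5, seed = 7))
  expect_equal(errorGt10Fraction(co, pm),
               errorFractionClosedForm(deriveResidualSd(10.8, 0.507)),
               tolerance = 0.02)
})

test_that("pooled means reproduce printed cohort summaries", {
  expect_equal(pooledMean(c(14.6, 20.8), c(53, 47)), 17.5)
  expect_equal(pooledMean(c(14.7, 15.0), c(67, 33)), 14.8)
  expect_equal(pooledMean(c(127.6, 126.7), c(67, 33)), 127.3)
  expect_equal(pooledMean(5, 10), 5)
  expect_error(pooledMean(c(1, 2), 3), "length")
})

test_that("ICC estimator behaves at the boundaries", {
  set.seed(8)
  x <- rnorm(100)
  expect_equal(iccEstimate(cbind(x, x, x))$icc_value, 1, tolerance = 1e-9)
  noise <- matrix(rnorm(4000), ncol = 2)
  expect_lt(abs(iccEstimate(noise)$icc_value), 0.05)
  expect_error(iccEstimate(cbind(rep(1, 10), rnorm(10))), "degenerate|constant")
})

test_that("half-up rounding differs from banker's rounding where it matters", {
  expect_equal(roundHalfUp(-0.668, 1), -0.7)
  expect_equal(roundHalfUp(4.330, 1), 4.3)
  expect_equal(roundHalfUp(0.25, 1), 0.3)  # round(0.25, 1) would give 0.2
  expect_equal(roundHalfUp(-0.25, 1), -0.3)
})

test_that("confidence intervals of the AW slope cover the truth at the nominal rate", {
  set.seed(9)
  cover <- vapply(1:300, function(i) {
    p <- cohortParams(n_hips = 100, seed = 10000 + i)
    co <- simulateCohort(p)
    fit <- olsForced(co$fa, co$aw, co$sex_code)
    fit$ci95["aw", 1] <= 0.744 && 0.744 <= fit$ci95["aw", 2]
  }, TRUE)
  expect_equal(mean(cover), 0.95, tolerance = 0.03)
})
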