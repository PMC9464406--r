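# Statistical layer: reliability, correlation, group comparison, the
# normality gate, the forced-entry multiple regression with diagnostics,
# and the sex-specific anteversion prediction equations.

#' Round half away from zero
#'
#' Display rounding for the prediction equations (R's `round()` uses
#' banker's rounding, which would not reproduce conventional half-up
#' reporting).
#'
#' @param x numeric.
#' @param digits decimal places.
#' @return Rounded numeric.
#' @export
roundHalfUp <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Format a p-value with the "< 0.001" convention
#'
#' @param p p-value.
#' @return Character, three decimals or `"< 0.001"`.
#' @export
formatPValue <- function(p) {
  if (p < 0.001) "< 0.001" else sprintf("%.3f", p)
}

#' Pearson correlation with two-sided t-based p-value
#'
#' @param x,y numeric vectors of equal length, n >= 3.
#' @return List with `r` and `p`.
#' @export
pearsonR <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3,
            all(is.finite(x)), all(is.finite(y)))
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance: correlation undefined")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' Intraclass correlation coefficient, two-way absolute agreement
#'
#' ANOVA-based single-measures ICC. The default flavor is the two-way
#' random-effects absolute-agreement single-measures coefficient (the
#' standard choice for a two-rater reliability design); a two-way
#' consistency flavor is available.
#'
#' @param replicate_matrix numeric matrix, subjects x raters (or sessions);
#'   >= 5 subjects, >= 2 columns.
#' @param flavor `"agreement"` (default) or `"consistency"`.
#' @return An `iccResult` list: `icc_value`, `model_label`, `ci95` (approx
#'   F-based interval), and the mean squares.
#' @export
iccEstimate <- function(replicate_matrix,
                        flavor = c("agreement", "consistency")) {
  flavor <- match.arg(flavor)
  M <- as.matrix(replicate_matrix)
  n <- nrow(M); k <- ncol(M)
  stopifnot(n >= 5, k >= 2, all(is.finite(M)))
  if (any(apply(M, 2, stats::sd) == 0))
    stop("degenerate variance: a rater column is constant")
  grand <- mean(M)
  row_m <- rowMeans(M); col_m <- colMeans(M)
  ss_rows <- k * sum((row_m - grand)^2)
  ss_cols <- n * sum((col_m - grand)^2)
  ss_err <- sum((M - outer(row_m, rep(1, k)) -
                   outer(rep(1, n), col_m) + grand)^2)
  msr <- ss_rows / (n - 1)
  msc <- ss_cols / (k - 1)
  mse <- ss_err / ((n - 1) * (k - 1))
  icc <- if (flavor == "agreement") {
    (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  } else {
    (msr - mse) / (msr + (k - 1) * mse)
  }
  # approximate CI via the F distribution on MSR/MSE (consistency bounds)
  f <- msr / mse
  fl <- f / stats::qf(0.975, n - 1, (n - 1) * (k - 1))
  fu <- f * stats::qf(0.975, (n - 1) * (k - 1), n - 1)
  ci <- c((fl - 1) / (fl + k - 1), (fu - 1) / (fu + k - 1))
  structure(list(icc_value = icc,
                 model_label = sprintf("two-way/%s/single-measures", flavor),
                 ci95 = ci, ms = c(rows = msr, cols = msc, error = mse)),
            class = "iccResult")
}

#' Intra- and interobserver reliability of simulated replicates
#'
#' Intraobserver: ICC across the two sessions of observer 1.
#' Interobserver: ICC across the two observers' session-averaged values.
#'
#' @param replicates an `observerReplicates` object.
#' @param flavor passed to [iccEstimate()].
#' @return List with `intra` and `inter` `iccResult`s.
#' @export
observerReliability <- function(replicates, flavor = "agreement") {
  v <- replicates$values
  list(intra = iccEstimate(cbind(v[, 1, 1], v[, 1, 2]), flavor),
       inter = iccEstimate(cbind((v[, 1, 1] + v[, 1, 2]) / 2,
                                 (v[, 2, 1] + v[, 2, 2]) / 2), flavor))
}

#' Pearson chi-square test on a 2x2 count table
#'
#' @param table 2x2 matrix of nonnegative integer counts.
#' @param correct apply the continuity correction (default FALSE).
#' @return List with `statistic` and `p`.
#' @export
chiSquareCounts <- function(table, correct = FALSE) {
  M <- as.matrix(table)
  stopifnot(all(dim(M) == c(2, 2)), all(M >= 0), all(M == round(M)))
  if (any(rowSums(M) == 0) || any(colSums(M) == 0))
    stop("zero marginal: chi-square undefined")
  ct <- suppressWarnings(stats::chisq.test(M, correct = correct))
  list(statistic = unname(ct$statistic), p = ct$p.value)
}

#' Shapiro-Wilk normality gate
#'
#' @param values numeric vector, 3 <= n <= 5000.
#' @return List with `w_statistic`, `p`, and `pass_flag` (p >= 0.05).
#' @export
normalityGate <- function(values) {
  stopifnot(all(is.finite(values)))
  if (length(values) < 3 || length(values) > 5000)
    stop("Shapiro-Wilk requires 3 <= n <= 5000")
  if (stats::sd(values) == 0) stop("constant input: normality test undefined")
  sw <- stats::shapiro.test(values)
  list(w_statistic = unname(sw$statistic), p = sw$p.value,
       pass_flag = sw$p.value >= 0.05)
}

#' Two-group comparison with formatted summaries
#'
#' Two-sided two-sample t-test (Welch by default) with group summaries in
#' the "mean +/- sd (range)" style of clinical tables.
#'
#' @param values_a,values_b numeric vectors, each n >= 2.
#' @param var_equal use the Student (pooled-variance) t-test.
#' @param digits decimals in the formatted summaries.
#' @return List with `mean_a`, `sd_a`, `mean_b`, `sd_b`, `summary_a`,
#'   `summary_b` (formatted strings), `p`, and `p_display`.
#' @export
groupCompare <- function(values_a, values_b, var_equal = FALSE, digits = 1) {
  if (length(values_a) < 2 || length(values_b) < 2)
    stop("each group needs at least 2 observations")
  fmt <- function(v) sprintf(paste0("%.", digits, "f ± %.", digits,
                                    "f (%.", digits, "f–%.", digits, "f)"),
                             mean(v), stats::sd(v), min(v), max(v))
  tt <- stats::t.test(values_a, values_b, var.equal = var_equal)
  list(mean_a = mean(values_a), sd_a = stats::sd(values_a),
       mean_b = mean(values_b), sd_b = stats::sd(values_b),
       summary_a = fmt(values_a), summary_b = fmt(values_b),
       p = tt$p.value, p_display = formatPValue(tt$p.value))
}

#' Forced-entry multiple regression of anteversion on AW angle and sex
#'
#' All prespecified predictors are entered simultaneously (no selection).
#' Reports unstandardized coefficients with their standard errors,
#' standardized betas, t-based p-values and 95% confidence intervals, the
#' overall F test with (k, n-k-1) degrees of freedom, R-squared and
#' adjusted R-squared, the Durbin-Watson ratio
#' \eqn{d = \sum (e_i - e_{i-1})^2 / \sum e_i^2}, and flags for
#' standardized residuals beyond +/- 3.
#'
#' @param y response, degrees.
#' @param aw anterior-wall angle predictor, degrees.
#' @param sex sex indicator, 0 = female, 1 = male.
#' @return An object of class `regressionFit`.
#' @export
olsForced <- function(y, aw, sex) {
  n <- length(y)
  stopifnot(length(aw) == n, length(sex) == n, all(is.finite(c(y, aw, sex))))
  if (n <= 3) stop("need n > k + 1 = 3 observations")
  X <- cbind(aw = aw, sex = sex)
  if (qr(cbind(1, X))$rank < 3)
    stop("rank-deficient design: aw and sex are collinear (or constant)")
  fit <- stats::lm(y ~ aw + sex)
  sm <- summary(fit)
  coefs <- sm$coefficients
  ci <- stats::confint(fit)
  e <- stats::residuals(fit)
  dw <- sum(diff(e)^2) / sum(e^2)
  std_beta <- c(NA,
                coefs["aw", 1] * stats::sd(aw) / stats::sd(y),
                coefs["sex", 1] * stats::sd(sex) / stats::sd(y))
  rstd <- stats::rstandard(fit)
  structure(list(
    coef = stats::setNames(coefs[, 1], c("const", "aw", "sex")),
    se = stats::setNames(coefs[, 2], c("const", "aw", "sex")),
    std_beta = stats::setNames(std_beta, c("const", "aw", "sex")),
    p_values = stats::setNames(coefs[, 4], c("const", "aw", "sex")),
    ci95 = matrix(ci, ncol = 2,
                  dimnames = list(c("const", "aw", "sex"),
                                  c("lower", "upper"))),
    r_squared = sm$r.squared, adj_r_squared = sm$adj.r.squared,
    f_stat = unname(sm$fstatistic[1]),
    f_df = unname(sm$fstatistic[2:3]),
    f_p = stats::pf(sm$fstatistic[1], sm$fstatistic[2], sm$fstatistic[3],
                    lower.tail = FALSE),
    durbin_watson = dw,
    residuals = unname(e),
    std_residuals = unname(rstd),
    outlier_flags = abs(rstd) > 3,
    n = n, lm = fit), class = "regressionFit")
}

#' @export
print.regressionFit <- function(x, ...) {
  cat("Forced-entry regression (n =", x$n, ")\n")
  tab <- data.frame(B = sprintf("%.3f", x$coef),
                    `SE B` = sprintf("%.3f", x$se),
                    beta = c("", sprintf("%.3f", x$std_beta[-1])),
                    `P value` = vapply(x$p_values, formatPValue, ""),
                    `CI lower` = sprintf("%.3f", x$ci95[, 1]),
                    `CI upper` = sprintf("%.3f", x$ci95[, 2]),
                    check.names = FALSE)
  rownames(tab) <- c("Constant", "Anterior wall angle", "Sex")
  print(tab)
  cat(sprintf("R2 = %.3f, adjusted R2 = %.3f, F(%d, %d) = %.3f (%s), Durbin-Watson = %.3f\n",
              x$r_squared, x$adj_r_squared, x$f_df[1], x$f_df[2], x$f_stat,
              formatPValue(x$f_p), x$durbin_watson))
  cat("Outliers (|standardized residual| > 3):", sum(x$outlier_flags), "\n")
  invisible(x)
}

#' Sex-specific prediction model from a regression fit
#'
#' The female equation keeps the constant; the male intercept adds the sex
#' coefficient. Display equations are rounded half-up at one decimal;
#' full-precision coefficients are retained for prediction.
#'
#' @param fit a `regressionFit` (or a list with `coef` named const/aw/sex).
#' @return An object of class `predictionModel`: full-precision
#'   `coef_const`, `coef_aw`, `coef_sex` and a `rounded` list with `slope`,
#'   `intercept_male`, `intercept_female`.
#' @export
makePredictionModel <- function(fit) {
  co <- fit$coef
  structure(list(
    coef_const = unname(co["const"]), coef_aw = unname(co["aw"]),
    coef_sex = unname(co["sex"]),
    rounded = list(slope = roundHalfUp(unname(co["aw"]), 1),
                   intercept_male = roundHalfUp(unname(co["const"] + co["sex"]), 1),
                   intercept_female = roundHalfUp(unname(co["const"]), 1))),
    class = "predictionModel")
}

#' @export
print.predictionModel <- function(x, ...) {
  cat(sprintf("male   FA = AW x %.1f %+.1f\n", x$rounded$slope, x$rounded$intercept_male))
  cat(sprintf("female FA = AW x %.1f %+.1f\n", x$rounded$slope, x$rounded$intercept_female))
  invisible(x)
}

#' Predict anteversion from the AW angle and sex
#'
#' @param aw anterior-wall angle, degrees.
#' @param sex `"male"`/`"female"` (or 1/0).
#' @param model a `predictionModel`.
#' @param rounded use the rounded display equations instead of the
#'   full-precision coefficients.
#' @return Predicted anteversion, degrees.
#' @export
predictFa <- function(aw, sex, model, rounded = FALSE) {
  male <- if (is.character(sex) || is.factor(sex))
    as.integer(as.character(sex) == "male") else as.integer(sex)
  stopifnot(all(male %in% c(0L, 1L)))
  if (rounded) {
    intercept <- ifelse(male == 1, model$rounded$intercept_male,
                        model$rounded$intercept_female)
    model$rounded$slope * aw + intercept
  } else {
    model$coef_const + model$coef_aw * aw + model$coef_sex * male
  }
}

#' Fraction of hips with prediction error above a threshold
#'
#' Uses the rounded display equations (the form a surgeon would apply) and
#' a strict inequality: an error of exactly the threshold does not count.
#'
#' @param cohort a `cohortTable`.
#' @param model a `predictionModel`.
#' @param threshold degrees (default 10).
#' @return Proportion in [0, 1].
#' @export
errorGt10Fraction <- function(cohort, model, threshold = 10) {
  stopifnot(nrow(cohort) > 0)
  pred <- predictFa(cohort$aw, cohort$sex_code, model, rounded = TRUE)
  mean(abs(cohort$fa - pred) > threshold)
}

#' Closed-form large-sample analogue of the error fraction
#'
#' Under the generative model the error about the (full-precision)
#' equation is Gaussian, so the exceedance fraction converges to
#' `2 * (1 - pnorm(threshold / residual_sd))`.
#'
#' @param residual_sd residual SD, degrees.
#' @param threshold degrees.
#' @return Limiting proportion.
#' @export
errorFractionClosedForm <- function(residual_sd, threshold = 10) {
  2 * stats::pnorm(threshold / residual_sd, lower.tail = FALSE)
}

#' Count-weighted pooled mean
#'
#' @param group_means numeric vector of subgroup means, degrees.
#' @param group_counts matching positive counts.
#' @param digits decimals for reporting (default 1).
#' @return Pooled mean rounded half-up at `digits`.
#' @export
pooledMean <- function(group_means, group_counts, digits = 1) {
  if (length(group_means) != length(group_counts))
    stop("group_means and group_counts differ in length")
  stopifnot(all(group_counts > 0))
  roundHalfUp(sum(group_means * group_counts) / sum(group_counts), digits)
}
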