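# Synthetic cohort generator for the statistical layer. The generative
# model is the fitted prediction equation: anteversion is linear in the
# anterior-wall angle and sex (coded 0 = female, 1 = male) plus Gaussian
# residual; the anterior-wall angle is normal within sex; the neck-shaft
# angle is independent normal.

#' Cohort generative parameters
#'
#' Defaults reproduce the study cohort's printed marginals: 53% male hips,
#' sex-specific anterior-wall means 14.6/20.8 deg (SD 6.6/8.2), prediction
#' coefficients (4.330, 0.744, -4.998), residual SD derived from the total
#' anteversion SD 10.8 deg and fit R-squared 0.507, neck-shaft angle
#' 127.3 +/- 5.4 deg, and 67% hips with osteonecrosis of the femoral head
#' (a label assigned independently of the angles, matching the observed
#' null group differences).
#'
#' @param n_hips number of hips.
#' @param male_fraction proportion of male hips.
#' @param aw_mean_by_sex,aw_sd_by_sex named or ordered pairs
#'   (male, female), degrees.
#' @param coef_const,coef_aw,coef_sex prediction coefficients (degrees,
#'   unitless slope, male-indicator effect in degrees).
#' @param residual_sd residual SD of anteversion about the linear
#'   predictor, degrees.
#' @param nsa_mean,nsa_sd neck-shaft angle marginal, degrees.
#' @param onfh_fraction proportion labelled ONFH.
#' @param seed integer RNG seed.
#' @return An object of class `cohortParams`.
#' @export
cohortParams <- function(n_hips = 100,
                         male_fraction = 0.53,
                         aw_mean_by_sex = c(male = 14.6, female = 20.8),
                         aw_sd_by_sex = c(male = 6.6, female = 8.2),
                         coef_const = 4.330, coef_aw = 0.744,
                         coef_sex = -4.998,
                         residual_sd = deriveResidualSd(10.8, 0.507),
                         nsa_mean = 127.3, nsa_sd = 5.4,
                         onfh_fraction = 0.67,
                         seed = 1L) {
  p <- structure(list(n_hips = as.integer(n_hips),
                      male_fraction = male_fraction,
                      aw_mean_by_sex = aw_mean_by_sex,
                      aw_sd_by_sex = aw_sd_by_sex,
                      coef_const = coef_const, coef_aw = coef_aw,
                      coef_sex = coef_sex, residual_sd = residual_sd,
                      nsa_mean = nsa_mean, nsa_sd = nsa_sd,
                      onfh_fraction = onfh_fraction, seed = as.integer(seed)),
                 class = "cohortParams")
  stopifnot(p$n_hips > 0, all(p$aw_sd_by_sex > 0), p$nsa_sd > 0,
            p$residual_sd >= 0,
            p$male_fraction >= 0, p$male_fraction <= 1,
            p$onfh_fraction >= 0, p$onfh_fraction <= 1)
  p
}

#' Residual SD from a total SD and a coefficient of determination
#'
#' For a linear model, the residual standard deviation is
#' `total_sd * sqrt(1 - r_squared)`.
#'
#' @param total_sd marginal SD of the response, degrees.
#' @param r_squared coefficient of determination in [0, 1).
#' @return Residual SD, degrees.
#' @export
deriveResidualSd <- function(total_sd, r_squared) {
  stopifnot(total_sd >= 0, r_squared >= 0, r_squared < 1)
  total_sd * sqrt(1 - r_squared)
}

#' Population explained variance of the cohort generative model
#'
#' Closed-form variance of the linear predictor
#' `coef_aw * AW + coef_sex * male` under the two-sex mixture, including
#' the AW-sex covariance induced by the sex-specific AW means.
#'
#' @param params a `cohortParams`.
#' @return Explained variance, degrees squared.
#' @export
explainedVariance <- function(params) {
  p <- params$male_fraction
  mu <- params$aw_mean_by_sex; sd <- params$aw_sd_by_sex
  m_aw <- p * mu[[1]] + (1 - p) * mu[[2]]
  v_aw <- p * (sd[[1]]^2 + mu[[1]]^2) + (1 - p) * (sd[[2]]^2 + mu[[2]]^2) - m_aw^2
  cov_aw_sex <- p * (1 - p) * (mu[[1]] - mu[[2]])
  params$coef_aw^2 * v_aw + params$coef_sex^2 * p * (1 - p) +
    2 * params$coef_aw * params$coef_sex * cov_aw_sex
}

#' Residual SD that yields a target population R-squared
#'
#' Chooses the residual SD so the generative model's population coefficient
#' of determination equals `r_squared`, given the explained variance
#' implied by the cohort parameters.
#'
#' @param params a `cohortParams`.
#' @param r_squared target population R-squared in (0, 1).
#' @return Residual SD, degrees.
#' @export
calibrateResidualSd <- function(params, r_squared) {
  stopifnot(r_squared > 0, r_squared < 1)
  sqrt(explainedVariance(params) * (1 - r_squared) / r_squared)
}

#' Simulate a cohort of per-hip angle records
#'
#' @param params a `cohortParams`.
#' @return A `data.frame` of class `cohortTable` with columns `hip_id`,
#'   `sex` ("male"/"female"), `sex_code` (1 = male, 0 = female), `group`
#'   ("ONFH"/"normal"), `aw`, `fa`, `nsa` (degrees).
#' @export
simulateCohort <- function(params) {
  stopifnot(inherits(params, "cohortParams"))
  withSeed(params$seed, {
    n <- params$n_hips
    male <- stats::rbinom(n, 1, params$male_fraction)
    aw <- stats::rnorm(n,
                       mean = ifelse(male == 1, params$aw_mean_by_sex[[1]],
                                     params$aw_mean_by_sex[[2]]),
                       sd = ifelse(male == 1, params$aw_sd_by_sex[[1]],
                                   params$aw_sd_by_sex[[2]]))
    fa <- params$coef_const + params$coef_aw * aw + params$coef_sex * male +
      stats::rnorm(n, 0, params$residual_sd)
    nsa <- stats::rnorm(n, params$nsa_mean, params$nsa_sd)
    onfh <- stats::rbinom(n, 1, params$onfh_fraction)
    structure(data.frame(hip_id = seq_len(n),
                         sex = ifelse(male == 1, "male", "female"),
                         sex_code = male,
                         group = ifelse(onfh == 1, "ONFH", "normal"),
                         aw = aw, fa = fa, nsa = nsa,
                         stringsAsFactors = FALSE),
              class = c("cohortTable", "data.frame"))
  })
}

# Evaluate expr under a temporary RNG state.
withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  expr
}

#' Simulate repeated-observer measurements
#'
#' Emulates the study's reliability design: two observers, each measuring
#' every hip in two sessions. Replicates are the hip's true value plus a
#' fixed per-observer bias (+/- delta) plus independent session noise. The
#' session-noise variance is set from the intraobserver target and the
#' observer offset from the interobserver target via the closed-form
#' variance decomposition, so the population intraclass correlations equal
#' the targets:
#' \deqn{ICC_{intra} = \sigma_T^2 / (\sigma_T^2 + \sigma_e^2)}
#' \deqn{ICC_{inter} = \sigma_T^2 / (\sigma_T^2 + 2\delta^2 + \sigma_e^2/2)}
#' where the interobserver comparison uses session-averaged values.
#' Observer biases are fixed offsets rather than random draws: with only
#' two observers a random bias is a one-degree-of-freedom quantity and the
#' realized ICC would not concentrate at any sample size.
#'
#' @param cohort a `cohortTable`.
#' @param target_icc_intra,target_icc_inter population ICC targets in (0, 1).
#' @param seed integer RNG seed.
#' @param variable which cohort column to replicate (default `"fa"`).
#' @return An object of class `observerReplicates`: a list with `values`
#'   (n x 2 observers x 2 sessions array), the targets, and the variance
#'   components used.
#' @export
simulateObservers <- function(cohort, target_icc_intra, target_icc_inter,
                              seed = 1L, variable = "fa") {
  stopifnot(variable %in% names(cohort))
  if (!(target_icc_intra > 0 && target_icc_intra < 1))
    stop("target intraobserver ICC must lie strictly inside (0, 1)")
  if (!(target_icc_inter > 0 && target_icc_inter < 1))
    stop("target interobserver ICC must lie strictly inside (0, 1)")
  truth <- cohort[[variable]]
  var_t <- stats::var(truth)
  var_e <- var_t * (1 - target_icc_intra) / target_icc_intra
  bias2 <- (var_t * (1 / target_icc_inter - 1) - var_e / 2) / 2
  if (bias2 < 0)
    stop("incompatible targets: interobserver ICC too high for the intraobserver session noise")
  delta <- sqrt(bias2)
  n <- length(truth)
  withSeed(seed, {
    vals <- array(NA_real_, dim = c(n, 2, 2),
                  dimnames = list(NULL, c("obs1", "obs2"), c("s1", "s2")))
    for (j in 1:2) for (k in 1:2)
      vals[, j, k] <- truth + c(-delta, delta)[j] + stats::rnorm(n, 0, sqrt(var_e))
    structure(list(values = vals,
                   target_icc_intra = target_icc_intra,
                   target_icc_inter = target_icc_inter,
                   var_true = var_t, var_session = var_e, bias = delta),
              class = "observerReplicates")
  })
}
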