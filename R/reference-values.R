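#' Published validation-study predictor moments
#'
#' Means and standard deviations of the demographic and selected behavioral
#' predictors reported by the second (within-subjects, n = 90) online
#' validation study of the assessment battery. These printed estimates serve
#' as generative ground truth for parameter-recovery simulations via
#' [simulate_from_fitted_model()].
#'
#' @return A tibble with columns `variable`, `dist`, `mean`, `sd`
#'   (`gender` is Bernoulli on male = 1 with `mean` the male proportion).
#' @export
#' @examples
#' reference_moments()
reference_moments <- function() {
  tibble(
    variable = c(
      "age", "gender", "d2_n_errors", "dmts_n_correct", "swm_n_within_errors"
    ),
    dist = c("normal", "bernoulli", "normal", "normal", "normal"),
    mean = c(37.944, 57 / 90, 42.811, 31.700, 19.822),
    sd = c(11.155, NA, 52.897, 6.523, 38.204)
  )
}

#' Published combined-model regression estimates
#'
#' The hierarchical combined model reported by the validation study
#' (n = 90): a demographics-only null block (age, gender) and a full block
#' adding one selected measure per task -- d2 total errors, DMTS correct
#' choices, SWM within errors. Residual standard deviations are derived from
#' the outcome spread and the models' R-squared
#' (`sd_y * sqrt(1 - R2)`, rounded to 6.6 and 5.6).
#'
#' @return A list with `null` and `full` coefficient vectors,
#'   `null_residual_sd`, `full_residual_sd`, `n`, `r2`, `delta_r2`,
#'   `f` and `delta_f`.
#' @export
reference_combined_fit <- function() {
  list(
    null = c(`(Intercept)` = 13.966, age = -0.180, gender = -0.487),
    null_residual_sd = 6.6,
    full = c(
      `(Intercept)` = 16.176, age = -0.069, gender = -0.649,
      d2_n_errors = 0.035, dmts_n_correct = -0.272,
      swm_n_within_errors = 0.038
    ),
    full_residual_sd = 5.6,
    n = 90L,
    r2 = c(null = 0.083, full = 0.344),
    delta_r2 = 0.261,
    f = c(null = 3.944, full = 8.799),
    delta_f = 11.119
  )
}
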