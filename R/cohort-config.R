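#' Configuration for the synthetic longitudinal cohort generator
#'
#' Defines the study conditions a simulated panel should emulate: a 4-wave
#' survey of adults aged 60+ with item-level CESD-10 depression responses,
#' cognitive subtask scores, demographics and auxiliary covariates with
#' missingness.  The planted mechanism couples depressive worsening at wave
#' `t` to latent cognitive decline at wave `t+1` (see [simulate_cohort()]).
#'
#' @param n_participants Number of participants (positive integer).
#' @param n_waves Number of survey waves (integer >= 2).
#' @param seed Integer seed; identical configs + seeds give byte-identical
#'   panels.
#' @param depressed_fraction Proportion in (0, 1) of participants whose
#'   latent depressive severity is centred in the high (symptomatic) regime.
#' @param effect_size Non-negative real: decrement of latent cognition (in
#'   latent SD units, roughly a log-odds scale for the threshold-crossing
#'   MCI outcome) per unit of positive depressive-severity change between
#'   consecutive waves.
#' @param missing_rate Proportion in \[0, 0.5\] of auxiliary-feature cells
#'   set missing completely at random.  Scale items are always complete.
#' @param n_aux_features Number of auxiliary numeric covariates; odd-indexed
#'   ones load weakly on latent severity, even-indexed ones are pure noise.
#' @param wave_years Calendar year of each wave (length `n_waves`,
#'   increasing); ages advance by the wave gaps.
#' @param sex_probs,education_probs,residence_probs,marital_probs Named
#'   category probabilities (each must sum to 1).  Defaults approximate a
#'   Chinese ageing-cohort profile: mostly primary-or-below education,
#'   majority rural, mostly married.
#' @param ar_rho AR(1) persistence of the latent depressive-severity
#'   deviation (default 0.7).
#' @param base_decline Per-wave decrement of latent cognition common to all
#'   participants.
#' @param cog_innovation_sd SD of the per-wave latent-cognition noise.
#' @param severity_shift Latent severity group means are `+severity_shift`
#'   (symptomatic group) and `-severity_shift` (normal group).
#' @param dropout_rate Optional per-wave attrition probability (default 0:
#'   complete panels).  No claim of realism is made for attrition patterns.
#'
#' @return A list of class `cohort_config`.
#' @seealso [simulate_cohort()]
#' @export
#' @examples
#' cfg <- cohort_config(n_participants = 50, seed = 1)
#' cfg$n_waves
cohort_config <- function(n_participants = 2000,
                          n_waves = 4,
                          seed = 1L,
                          depressed_fraction = 0.5,
                          effect_size = 2.5,
                          missing_rate = 0.1,
                          n_aux_features = 6,
                          wave_years = c(2011, 2013, 2015, 2018),
                          sex_probs = c(male = 0.52, female = 0.48),
                          education_probs = c(primary_or_below = 0.81,
                                              middle = 0.12,
                                              high_or_technical = 0.05,
                                              college_or_above = 0.02),
                          residence_probs = c(rural = 0.62, urban = 0.38),
                          marital_probs = c(married = 0.82,
                                            unmarried = 0.01,
                                            divorced = 0.01,
                                            widowed = 0.16),
                          ar_rho = 0.7,
                          base_decline = 0.15,
                          cog_innovation_sd = 0.3,
                          severity_shift = 1.2,
                          dropout_rate = 0) {
  if (length(n_participants) != 1 || is.na(n_participants) ||
      n_participants < 1 || n_participants != round(n_participants)) {
    abort("`n_participants` must be a positive integer.")
  }
  if (n_waves < 2 || n_waves != round(n_waves)) {
    abort("`n_waves` must be an integer >= 2.")
  }
  if (missing_rate < 0 || missing_rate > 0.5) {
    abort("`missing_rate` must lie in [0, 0.5].")
  }
  if (effect_size < 0) abort("`effect_size` must be >= 0.")
  if (depressed_fraction <= 0 || depressed_fraction >= 1) {
    abort("`depressed_fraction` must lie strictly in (0, 1).")
  }
  if (n_aux_features < 0 || n_aux_features != round(n_aux_features)) {
    abort("`n_aux_features` must be a non-negative integer.")
  }
  if (length(wave_years) != n_waves || any(diff(wave_years) <= 0)) {
    abort("`wave_years` must be increasing and of length `n_waves`.")
  }
  if (dropout_rate < 0 || dropout_rate >= 1) {
    abort("`dropout_rate` must lie in [0, 1).")
  }
  for (nm in c("sex_probs", "education_probs", "residence_probs",
               "marital_probs")) {
    p <- get(nm)
    if (is.null(names(p)) || any(p < 0) || abs(sum(p) - 1) > 1e-8) {
      abort(sprintf("`%s` must be named, non-negative, and sum to 1.", nm))
    }
  }
  structure(
    list(n_participants = as.integer(n_participants),
         n_waves = as.integer(n_waves),
         seed = as.integer(seed),
         depressed_fraction = depressed_fraction,
         effect_size = effect_size,
         missing_rate = missing_rate,
         n_aux_features = as.integer(n_aux_features),
         wave_years = wave_years,
         sex_probs = sex_probs,
         education_probs = education_probs,
         residence_probs = residence_probs,
         marital_probs = marital_probs,
         ar_rho = ar_rho,
         base_decline = base_decline,
         cog_innovation_sd = cog_innovation_sd,
         severity_shift = severity_shift,
         dropout_rate = dropout_rate),
    class = "cohort_config")
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("<cohort_config>\n")
  cat(sprintf("  %d participants x %d waves (seed %d)\n",
              x$n_participants, x$n_waves, x$seed))
  cat(sprintf("  depressed fraction %.2f, effect size %.2f, missing rate %.2f\n",
              x$depressed_fraction, x$effect_size, x$missing_rate))
  cat(sprintf("  %d auxiliary features, attrition %.2f\n",
              x$n_aux_features, x$dropout_rate))
  invisible(x)
}
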