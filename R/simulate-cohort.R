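#' Simulate a longitudinal ageing cohort with a planted depression-to-MCI effect
#'
#' Generates a wave-indexed panel (one row per participant per wave) with the
#' schema of a CHARLS-style ageing survey: demographics, ten CESD-10 item
#' responses (0-3), five cognitive subtask scores, and auxiliary covariates
#' with missing-completely-at-random cells.
#'
#' The generating mechanism has two coupled latent processes per participant:
#' \describe{
#'   \item{depressive severity}{`s_t = mu + z_t`, where `mu` is
#'     `+severity_shift` for the symptomatic group (a `depressed_fraction`
#'     Bernoulli draw) and `-severity_shift` otherwise, and `z_t` is a
#'     stationary AR(1) deviation with persistence `ar_rho` and unit
#'     stationary variance.}
#'   \item{cognition}{`c_t = c_{t-1} - base_decline -
#'     effect_size * max(0, s_t - s_{t-1}) + noise`, so cognitive decline
#'     steepens when depressive severity worsens -- the planted temporal
#'     effect a downstream risk model should recover.}
#' }
#' CESD-10 items are emitted from severity by a graded-response map (three
#' thresholds at -0.5, 0.5, 1.5 with logistic item noise, scale 0.3), which
#' places the expected item total near the conventional cutoff of 10 when
#' latent severity is 0.  Cognitive subtasks are linear maps of latent
#' cognition rounded and clipped to their instrument ranges (word recall
#' 0-10 twice, orientation 0-5, serial subtraction 0-5, pentagon copy 0-1).
#'
#' @param config A [cohort_config()] object.
#' @return A tibble with one row per participant-wave and columns
#'   `participant_id`, `wave`, `year`, `age`, `sex`, `education`,
#'   `residence`, `marital`, `cesd_1` ... `cesd_10`, `imm_recall`,
#'   `del_recall`, `orientation`, `calculation`, `pentagon`, and
#'   `aux_1` ... `aux_k`.
#' @export
#' @examples
#' cohort <- simulate_cohort(cohort_config(n_participants = 30, seed = 7))
#' dplyr::count(cohort, wave)
simulate_cohort <- function(config = cohort_config()) {
  if (!inherits(config, "cohort_config")) {
    abort("`config` must be created with `cohort_config()`.")
  }
  withr::with_seed(config$seed, simulate_cohort_impl(config))
}

simulate_cohort_impl <- function(config) {
  n <- config$n_participants
  W <- config$n_waves
  ids <- sprintf("P%05d", seq_len(n))

  ## demographics (fixed per participant)
  sex <- sample(names(config$sex_probs), n, TRUE, config$sex_probs)
  education <- sample(names(config$education_probs), n, TRUE,
                      config$education_probs)
  residence <- sample(names(config$residence_probs), n, TRUE,
                      config$residence_probs)
  marital <- sample(names(config$marital_probs), n, TRUE,
                    config$marital_probs)

  ## age at wave 1: normal(66, 5.3) truncated at the inclusion age of 60
  age1 <- rnorm(n, 66, 5.3)
  while (any(age1 < 60)) {
    idx <- which(age1 < 60)
    age1[idx] <- rnorm(length(idx), 66, 5.3)
  }
  age1 <- floor(age1)   # whole years, so wave gaps are exact
  gaps <- c(0, diff(config$wave_years))

  ## latent severity: group mean +/- shift plus stationary AR(1) deviation
  dep_group <- rbinom(n, 1, config$depressed_fraction)
  mu <- ifelse(dep_group == 1, config$severity_shift, -config$severity_shift)
  z <- matrix(0, n, W)
  z[, 1] <- rnorm(n)
  innov_sd <- sqrt(1 - config$ar_rho^2)
  for (w in 2:W) z[, w] <- config$ar_rho * z[, w - 1] + rnorm(n, 0, innov_sd)
  sev <- mu + z

  ## latent cognition: drift down, steeper under depressive worsening
  cog <- matrix(0, n, W)
  cog[, 1] <- rnorm(n)
  for (w in 2:W) {
    worsening <- pmax(0, sev[, w] - sev[, w - 1])
    cog[, w] <- cog[, w - 1] - config$base_decline -
      config$effect_size * worsening +
      rnorm(n, 0, config$cog_innovation_sd)
  }

  ## attrition: participant observed through wave L only
  last_wave <- rep(W, n)
  if (config$dropout_rate > 0 && W >= 3) {
    for (w in 2:(W - 1)) {
      drops <- last_wave == W & rbinom(n, 1, config$dropout_rate) == 1
      ## a drop decided after wave w truncates the panel at wave w
      last_wave[drops] <- w
    }
  }

  k_aux <- config$n_aux_features
  aux_load <- if (k_aux > 0) ifelse(seq_len(k_aux) %% 2 == 1, 0.4, 0) else numeric(0)

  waves <- vector("list", W)
  for (w in seq_len(W)) {
    s_w <- sev[, w]
    items <- emit_cesd_items(s_w)
    subtasks <- emit_cognitive_subtasks(cog[, w])
    row <- tibble(
      participant_id = ids,
      wave = as.integer(w),
      year = as.integer(config$wave_years[w]),
      age = age1 + sum(gaps[seq_len(w)]),
      sex = sex, education = education,
      residence = residence, marital = marital)
    row <- bind_cols_strict(row, items, subtasks)
    if (k_aux > 0) {
      aux <- vapply(seq_len(k_aux), function(j) {
        v <- aux_load[j] * z[, w] + rnorm(n)
        if (config$missing_rate > 0) {
          v[runif(n) < config$missing_rate] <- NA_real_
        }
        v
      }, numeric(n))
      colnames(aux) <- paste0("aux_", seq_len(k_aux))
      row <- bind_cols_strict(row, as_tibble(aux))
    }
    waves[[w]] <- row[w <= last_wave, , drop = FALSE]
  }
  out <- bind_rows(waves)
  out <- arrange(out, .data$participant_id, .data$wave)
  out
}

## graded-response emission: one logistic noise draw per (record, item),
## thresholds chosen so E[item total] ~ 10 at latent severity 0
emit_cesd_items <- function(severity) {
  n <- length(severity)
  thresholds <- c(-0.5, 0.5, 1.5)
  items <- vapply(seq_len(10), function(j) {
    e <- severity + rlogis(n, 0, 0.3)
    as.integer((e > thresholds[1]) + (e > thresholds[2]) + (e > thresholds[3]))
  }, integer(n))
  colnames(items) <- paste0("cesd_", seq_len(10))
  as_tibble(items)
}

emit_cognitive_subtasks <- function(cognition) {
  n <- length(cognition)
  clamp_int <- function(x, lo, hi) as.integer(pmin(hi, pmax(lo, round(x))))
  tibble(
    imm_recall = clamp_int(5.0 + 1.6 * cognition + rnorm(n, 0, 0.7), 0, 10),
    del_recall = clamp_int(4.5 + 1.8 * cognition + rnorm(n, 0, 0.7), 0, 10),
    orientation = clamp_int(4.0 + 0.8 * cognition + rnorm(n, 0, 0.5), 0, 5),
    calculation = clamp_int(3.0 + 1.0 * cognition + rnorm(n, 0, 0.5), 0, 5),
    pentagon = as.integer(rbinom(n, 1, plogis(1 + 1.5 * cognition))))
}

bind_cols_strict <- function(...) {
  pieces <- list(...)
  out <- pieces[[1]]
  for (p in pieces[-1]) out[colnames(p)] <- p
  out
}
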