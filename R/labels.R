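#' Assign 5-year age strata starting at 60
#'
#' Ages are binned into 5-year intervals (60-64, 65-69, ...); ages at or
#' above `top` fall into an open-ended top stratum.  Ages below 60 are an
#' error (the inclusion age of the cohort design).
#'
#' @param age Numeric age(s) in years, all >= 60.
#' @param width Stratum width in years (default 5).
#' @param top Lower bound of the open-ended top stratum (default 85).
#' @return A tibble with columns `lower`, `upper` (inclusive; `Inf` for the
#'   top stratum) and `stratum` (a label such as `"60-64"` or `"85+"`).
#' @export
#' @examples
#' assign_age_stratum(c(60, 64, 65, 90))
assign_age_stratum <- function(age, width = 5, top = 85) {
  if (any(is.na(age))) abort("`age` must not contain missing values.")
  if (any(age < 60)) {
    abort(sprintf("Age %s is below the inclusion age of 60.",
                  format(age[age < 60][1])))
  }
  lower <- 60 + width * floor((age - 60) / width)
  lower <- pmin(lower, top)
  upper <- ifelse(lower >= top, Inf, lower + width - 1)
  finite_upper <- ifelse(is.finite(upper), upper, lower)
  tibble(lower = lower, upper = upper,
         stratum = ifelse(is.infinite(upper),
                          sprintf("%d+", as.integer(lower)),
                          sprintf("%d-%d", as.integer(lower),
                                  as.integer(finite_upper))))
}

#' Label mild cognitive impairment by an age-normed threshold
#'
#' Within each 5-year age stratum, records whose cognitive composite lies
#' strictly below the stratum mean minus one (sample, n-1 denominator)
#' standard deviation are labelled MCI.  Strata with fewer than two records
#' have an undefined SD: their members are labelled normal with a warning.
#'
#' @param data A data frame with one row per observation, containing an age
#'   column and a cognitive-total column.
#' @param age_col,total_col Column names (default `"age"`, `"cog_total"`).
#' @param width,top Stratum geometry, passed to [assign_age_stratum()].
#' @return The input tibble with a logical `mci` column appended.
#' @export
#' @examples
#' d <- tibble::tibble(age = c(61, 62, 63, 64), cog_total = c(0, 20, 20, 20))
#' label_mci(d)$mci  # TRUE FALSE FALSE FALSE (threshold 15 - 10 = 5)
label_mci <- function(data, age_col = "age", total_col = "cog_total",
                      width = 5, top = 85) {
  if (!all(c(age_col, total_col) %in% names(data))) {
    abort(sprintf("`data` must contain columns `%s` and `%s`.",
                  age_col, total_col))
  }
  strata <- assign_age_stratum(data[[age_col]], width = width, top = top)
  total <- data[[total_col]]
  out <- as_tibble(data)
  out$mci <- rep(NA, nrow(out))
  small <- character(0)
  for (s in unique(strata$stratum)) {
    idx <- which(strata$stratum == s)
    v <- total[idx]
    if (sum(!is.na(v)) < 2) {
      out$mci[idx] <- FALSE
      small <- c(small, s)
      next
    }
    threshold <- mean(v, na.rm = TRUE) - sd(v, na.rm = TRUE)
    out$mci[idx] <- !is.na(v) & v < threshold
  }
  if (length(small) > 0) {
    warn(sprintf(
      "Age stratum(s) %s have fewer than 2 scored members; SD is undefined, members labelled normal.",
      paste(small, collapse = ", ")))
  }
  out
}

#' Score a cohort panel and attach depression and MCI labels
#'
#' Adds `cesd_total` (0-30), `depressed` (CESD-10 total >= 10), `cog_total`
#' (0-31 composite) and the age-normed `mci` label to a cohort table.  MCI
#' labelling pools all participant-wave records and stratifies by the age at
#' each observation, so the normative threshold is age-referenced.
#'
#' @param cohort A cohort tibble from [simulate_cohort()] or [read_cohort()].
#' @param reverse_positive Passed to [score_cesd10()].
#' @param width,top Stratum geometry, passed to [label_mci()].
#' @return The cohort with `cesd_total`, `depressed`, `cog_total` and `mci`
#'   columns appended.
#' @export
#' @examples
#' cohort <- simulate_cohort(cohort_config(n_participants = 100, seed = 1))
#' scored <- score_cohort(cohort)
#' mean(scored$depressed)
score_cohort <- function(cohort, reverse_positive = FALSE,
                         width = 5, top = 85) {
  validate_cohort(cohort)
  out <- as_tibble(cohort)
  out$cesd_total <- score_cesd10(out[paste0("cesd_", 1:10)],
                                 reverse_positive = reverse_positive)
  out$depressed <- classify_depression(out$cesd_total) == "depressed"
  cog <- score_cognition(out$imm_recall, out$del_recall, out$orientation,
                         out$calculation, out$pentagon)
  out$cog_total <- cog$total
  out <- label_mci(out, width = width, top = top)
  out
}
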