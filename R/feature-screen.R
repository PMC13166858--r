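#' One-hot encode the categorical demographics of a cohort
#'
#' Expands `sex`, `education`, `residence` and `marital` into 0/1 indicator
#' columns with the first (reference) level dropped, leaving all other
#' columns untouched.  Indicator names are `<variable>_<level>`.
#'
#' @param cohort A cohort tibble.
#' @return The cohort with indicator columns appended.
#' @export
encode_cohort <- function(cohort) {
  out <- as_tibble(cohort)
  specs <- list(sex = "male", education = "primary_or_below",
                residence = "rural", marital = "married")
  for (var in names(specs)) {
    if (!var %in% names(out)) next
    levels <- setdiff(sort(unique(out[[var]])), specs[[var]])
    for (lv in levels) {
      out[[paste0(var, "_", lv)]] <- as.integer(out[[var]] == lv)
    }
  }
  out
}

#' Default feature declarations for a generated cohort
#'
#' Screening operates on declared metadata rather than re-deriving semantic
#' judgements: each candidate feature is flagged as outcome-derived
#' (cognitive assessment metrics and their derivatives), inconsistently
#' measured across waves, or a composite overlapping other candidates (the
#' CESD-10 total, which duplicates its items).  For cohorts produced by
#' [simulate_cohort()] + [score_cohort()] + [encode_cohort()] this helper
#' emits the appropriate declarations; bespoke cohorts can build the same
#' tibble by hand.
#'
#' @param cohort An encoded, scored cohort tibble.
#' @param inconsistent Character vector of feature names measured
#'   inconsistently across waves (default none).
#' @return A tibble with columns `name`, `outcome_derived`,
#'   `inconsistent_across_waves`, `composite_overlapping`.
#' @export
feature_declarations <- function(cohort, inconsistent = character(0)) {
  bookkeeping <- c("participant_id", "wave", "year",
                   "sex", "education", "residence", "marital")
  outcome <- c("imm_recall", "del_recall", "orientation", "calculation",
               "pentagon", "cog_total", "mci")
  composite <- c("cesd_total", "depressed")
  candidates <- setdiff(names(cohort), bookkeeping)
  tibble(
    name = candidates,
    outcome_derived = candidates %in% outcome,
    inconsistent_across_waves = candidates %in% inconsistent,
    composite_overlapping = candidates %in% composite)
}

#' Per-feature screening metadata
#'
#' Computes the overall missing rate of each declared feature (missing cells
#' over total cells, pooled across all waves) and carries the declaration
#' flags forward.
#'
#' @param cohort A cohort tibble.
#' @param declarations A declarations tibble as from [feature_declarations()].
#' @return A tibble with columns `name`, `missing_rate`, `outcome_derived`,
#'   `inconsistent_across_waves`, `composite_overlapping`.
#' @export
compute_feature_meta <- function(cohort, declarations) {
  absent <- setdiff(declarations$name, names(cohort))
  if (length(absent) > 0) {
    abort(sprintf("Declared feature(s) absent from the cohort: %s.",
                  paste(absent, collapse = ", ")))
  }
  tibble(
    name = declarations$name,
    missing_rate = vapply(declarations$name,
                          function(nm) mean(is.na(cohort[[nm]])),
                          numeric(1), USE.NAMES = FALSE),
    outcome_derived = declarations$outcome_derived,
    inconsistent_across_waves = declarations$inconsistent_across_waves,
    composite_overlapping = declarations$composite_overlapping)
}

#' Multi-stage feature screening
#'
#' Applies the four exclusion rules in one pass, retaining a feature only if
#' it is (1) not outcome-derived, (2) not inconsistently measured across
#' waves, (3) has an overall missing rate of at most 20 percent (the rule
#' excludes strictly greater than 20 percent), and (4) is not a composite
#' indicator overlapping other candidates.  Input order is preserved and the
#' operation is idempotent.
#'
#' @param meta A metadata tibble from [compute_feature_meta()].
#' @param max_missing Missing-rate bound (default 0.20; exclusion is strict
#'   `>`).
#' @return Character vector of retained feature names.
#' @export
#' @examples
#' meta <- tibble::tibble(
#'   name = c("a", "b"), missing_rate = c(0.2, 0.21),
#'   outcome_derived = FALSE, inconsistent_across_waves = FALSE,
#'   composite_overlapping = FALSE)
#' screen_features(meta)  # "a": exactly 20% missing is retained
screen_features <- function(meta, max_missing = 0.20) {
  if (nrow(meta) == 0) return(character(0))
  keep <- !meta$outcome_derived &
    !meta$inconsistent_across_waves &
    meta$missing_rate <= max_missing &
    !meta$composite_overlapping
  meta$name[keep]
}
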