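#' Read and write cohort tables
#'
#' Cohort panels are stored as UTF-8 comma-separated text with one header
#' row, one row per participant-wave, and the empty string as the missing
#' marker.  `write_cohort()` validates the schema before writing;
#' `read_cohort()` validates after reading, so a round trip reproduces the
#' records exactly (including missing cells).
#'
#' @param cohort A cohort tibble as produced by [simulate_cohort()]
#'   (optionally with scored columns added by [score_cohort()]).
#' @param path File path.
#' @return `write_cohort()` returns `path` invisibly; `read_cohort()`
#'   returns a validated cohort tibble.
#' @export
#' @examples
#' f <- tempfile(fileext = ".csv")
#' cohort <- simulate_cohort(cohort_config(n_participants = 5, seed = 1))
#' write_cohort(cohort, f)
#' identical(read_cohort(f), cohort)
write_cohort <- function(cohort, path) {
  validate_cohort(cohort)
  out <- cohort
  ## doubles are written with 17 significant digits so a read-back
  ## reproduces every value bit-exactly
  for (nm in names(out)) {
    if (is.double(out[[nm]])) {
      v <- sprintf("%.17g", out[[nm]])
      v[is.na(out[[nm]])] <- NA_character_
      out[[nm]] <- v
    }
  }
  readr::write_csv(out, path, na = "")
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  header <- names(readr::read_csv(path, n_max = 0, show_col_types = FALSE,
                                  name_repair = "minimal"))
  if (!all(required_cohort_columns() %in% header)) {
    missing <- setdiff(required_cohort_columns(), header)
    abort(sprintf("Malformed cohort header: missing column(s) %s.",
                  paste(missing, collapse = ", ")))
  }
  types <- cohort_col_types(header)
  out <- readr::read_csv(path, col_types = types, na = "")
  out <- as_tibble(out)
  attr(out, "spec") <- NULL
  attr(out, "problems") <- NULL
  ## double columns come in as text and go through strtod, which rounds
  ## correctly to the nearest binary64 -- bit-exact round trips
  for (nm in names(out)) {
    if (is.character(out[[nm]]) && !nm %in% character_cohort_columns()) {
      out[[nm]] <- as.numeric(out[[nm]])
    }
  }
  validate_cohort(out)
  out
}

integer_cohort_columns <- function() {
  c("wave", "year", paste0("cesd_", 1:10),
    "imm_recall", "del_recall", "orientation", "calculation", "pentagon")
}

character_cohort_columns <- function() {
  c("participant_id", "sex", "education", "residence", "marital")
}

required_cohort_columns <- function() {
  c("participant_id", "wave", "age", paste0("cesd_", 1:10),
    "imm_recall", "del_recall", "orientation", "calculation", "pentagon")
}

cohort_col_types <- function(header) {
  spec <- lapply(header, function(nm) {
    if (nm %in% character_cohort_columns()) readr::col_character()
    else if (nm %in% c(integer_cohort_columns(), "cesd_total", "cog_total")) {
      readr::col_integer()
    } else if (nm %in% c("depressed", "mci")) readr::col_logical()
    else readr::col_character()
  })
  names(spec) <- header
  do.call(readr::cols, spec)
}

#' Validate a cohort table against the panel schema
#'
#' Checks column presence, item and subtask ranges, and uniqueness of the
#' (participant, wave) key.  Errors name the offending row and column.
#'
#' @param cohort A cohort tibble.
#' @return The input, invisibly, if valid.
#' @export
validate_cohort <- function(cohort) {
  missing <- setdiff(required_cohort_columns(), names(cohort))
  if (length(missing) > 0) {
    abort(sprintf("Cohort is missing column(s): %s.",
                  paste(missing, collapse = ", ")))
  }
  if (nrow(cohort) == 0) return(invisible(cohort))
  key <- paste(cohort$participant_id, cohort$wave)
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1]
    abort(sprintf("Duplicate (participant, wave) key: %s.", dup))
  }
  ranges <- c(
    setNames(rep(list(c(0, 3)), 10), paste0("cesd_", 1:10)),
    list(imm_recall = c(0, 10), del_recall = c(0, 10),
         orientation = c(0, 5), calculation = c(0, 5), pentagon = c(0, 1)))
  for (col in names(ranges)) {
    v <- cohort[[col]]
    bad <- which(!is.na(v) & (v < ranges[[col]][1] | v > ranges[[col]][2] |
                                v != round(v)))
    if (length(bad) > 0) {
      abort(sprintf(
        "Out-of-range value %s in column `%s` at row %d (allowed %d..%d).",
        format(v[bad[1]]), col, bad[1],
        ranges[[col]][1], ranges[[col]][2]))
    }
  }
  if (any(!is.na(cohort$age) & cohort$age < 60)) {
    bad <- which(cohort$age < 60)[1]
    abort(sprintf("Age below the inclusion age of 60 at row %d.", bad))
  }
  invisible(cohort)
}
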