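#' Score the 10-item CES-D depression scale
#'
#' Plain sum of the ten item responses, each on a 0-3 frequency scale, for a
#' total in 0-30.  By default no items are reverse-coded; set
#' `reverse_positive = TRUE` to reverse the two positively worded items
#' (items 5 and 8) before summing, the convention used by some CES-D-10
#' administrations.
#'
#' @param items A numeric vector of length 10, or a matrix / data frame with
#'   10 columns (one row per respondent), each value in 0..3.
#' @param reverse_positive Reverse-code items 5 and 8 as `3 - x`?
#'   Default `FALSE`.
#' @return Integer total(s) in 0..30.
#' @export
#' @examples
#' score_cesd10(rep(3, 10))  # 30
#' score_cesd10(c(1, 1, 1, 1, 1, 0, 0, 0, 0, 0))  # 5
score_cesd10 <- function(items, reverse_positive = FALSE) {
  m <- as_item_matrix(items, 10, "CESD-10")
  bad <- which(is.na(m) | m < 0 | m > 3 | m != round(m), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    abort(sprintf("CESD-10 item %d (respondent %d) is outside 0..3.",
                  bad[1, 2], bad[1, 1]))
  }
  if (reverse_positive) {
    m[, c(5, 8)] <- 3 - m[, c(5, 8)]
  }
  as.integer(rowSums(m))
}

as_item_matrix <- function(items, k, label) {
  if (is.data.frame(items)) items <- as.matrix(items)
  if (is.null(dim(items))) {
    if (length(items) != k) {
      abort(sprintf("%s requires exactly %d items, got %d.",
                    label, k, length(items)))
    }
    items <- matrix(items, nrow = 1)
  }
  if (ncol(items) != k) {
    abort(sprintf("%s requires exactly %d items, got %d columns.",
                  label, k, ncol(items)))
  }
  storage.mode(items) <- "double"
  items
}

#' Classify depressive-symptom status from a CESD-10 total
#'
#' Totals at or above the cutoff (default 10) are classified as
#' `"depressed"`, totals below as `"normal"`.
#'
#' @param total Integer total(s) in 0..30.
#' @param cutoff Symptom cutoff; default 10.
#' @return Character vector, `"depressed"` or `"normal"`.
#' @export
#' @examples
#' classify_depression(c(9, 10))  # "normal" "depressed"
classify_depression <- function(total, cutoff = 10) {
  if (any(is.na(total) | total < 0 | total > 30)) {
    abort("CESD-10 totals must lie in 0..30.")
  }
  ifelse(total >= cutoff, "depressed", "normal")
}

#' Score the cognitive composite
#'
#' Sums the five subtasks of the two-dimension neuropsychological battery:
#' episodic memory (immediate + delayed 10-word recall, 0-10 each) and
#' global mental status (temporal orientation 0-5, serial subtraction 0-5,
#' pentagon copy 0-1), for a composite total in 0-31.
#'
#' @param imm_recall,del_recall Word-recall scores, 0..10.
#' @param orientation Temporal-orientation score, 0..5.
#' @param calculation Serial-subtraction score, 0..5.
#' @param pentagon Pentagon-copy score, 0..1.
#' @return A tibble echoing the five components plus `episodic` (0-20),
#'   `mental_status` (0-11) and `total` (0-31).
#' @export
#' @examples
#' score_cognition(10, 10, 5, 5, 1)$total  # 31
score_cognition <- function(imm_recall, del_recall, orientation,
                            calculation, pentagon) {
  parts <- list(imm_recall = imm_recall, del_recall = del_recall,
                orientation = orientation, calculation = calculation,
                pentagon = pentagon)
  limits <- list(imm_recall = 10, del_recall = 10, orientation = 5,
                 calculation = 5, pentagon = 1)
  n <- max(lengths(parts))
  for (nm in names(parts)) {
    v <- parts[[nm]]
    bad <- which(!is.na(v) & (v < 0 | v > limits[[nm]] | v != round(v)))
    if (length(bad) > 0) {
      abort(sprintf("`%s` value %s (element %d) is outside 0..%d.",
                    nm, format(v[bad[1]]), bad[1], limits[[nm]]))
    }
    parts[[nm]] <- as.integer(rep_len(v, n))
  }
  out <- as_tibble(parts)
  out$episodic <- out$imm_recall + out$del_recall
  out$mental_status <- out$orientation + out$calculation + out$pentagon
  out$total <- out$episodic + out$mental_status
  out
}
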