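#' Build sliding-window training samples
#'
#' Converts a scored, labelled, imputed cohort into (wave `t` -> wave `t+1`)
#' samples.  A window starts at wave `t` for a participant when all of:
#' \itemize{
#'   \item the participant is depressed (CESD-10 total >= 10) at wave `t`
#'     -- the exposure condition;
#'   \item the participant is \emph{not} MCI at wave `t` -- excluding
#'     records where the temporal sequence of depression and impairment
#'     would be unclear;
#'   \item cognition is observed at wave `t+1`, so the next-wave label is
#'     defined.
#' }
#' The label is the MCI status at wave `t+1`; the feature sequence carries
#' the retained features at the window's two waves (windows are pairwise).
#'
#' @param cohort A cohort tibble that has been through [score_cohort()]
#'   (and, if it has missing feature cells, [impute_mi_mean()]).
#' @param features Character vector of retained feature names, e.g. from
#'   [screen_features()]; all must be numeric and complete.
#' @return A tibble with columns `participant_id`, `window_index` (the wave
#'   `t` the window starts at), `label` (integer 0/1: MCI at `t+1`) and
#'   `features` (list column of 2 x length(features) matrices, rows = waves
#'   `t`, `t+1`).
#' @export
build_windows <- function(cohort, features) {
  needed <- c("depressed", "mci", "cog_total")
  if (!all(needed %in% names(cohort))) {
    abort("Cohort must be scored with `score_cohort()` before windowing.")
  }
  absent <- setdiff(features, names(cohort))
  if (length(absent) > 0) {
    abort(sprintf("Retained feature(s) absent from cohort: %s.",
                  paste(absent, collapse = ", ")))
  }
  for (f in features) {
    if (!is.numeric(cohort[[f]])) {
      abort(sprintf("Feature `%s` is not numeric; encode it first.", f))
    }
    if (anyNA(cohort[[f]])) {
      abort(sprintf("Feature `%s` has missing cells; impute first.", f))
    }
  }
  cohort <- arrange(as_tibble(cohort), .data$participant_id, .data$wave)
  n_waves_per <- table(cohort$participant_id)
  if (all(n_waves_per < 2)) {
    warn("No participant has 2 or more waves; returning zero windows.")
    return(empty_windows())
  }

  fmat <- as.matrix(cohort[features])
  rows <- split(seq_len(nrow(cohort)), cohort$participant_id)
  samples <- list()
  for (id in names(rows)) {
    idx <- rows[[id]]
    waves <- cohort$wave[idx]
    for (k in seq_len(length(idx) - 1)) {
      if (waves[k + 1] != waves[k] + 1) next  # non-consecutive waves
      i_t <- idx[k]; i_n <- idx[k + 1]
      if (!isTRUE(cohort$depressed[i_t])) next
      if (is.na(cohort$mci[i_t]) || cohort$mci[i_t]) next
      if (is.na(cohort$cog_total[i_n]) || is.na(cohort$mci[i_n])) next
      seq_mat <- fmat[c(i_t, i_n), , drop = FALSE]
      rownames(seq_mat) <- NULL
      samples[[length(samples) + 1]] <- list(
        participant_id = id,
        window_index = as.integer(waves[k]),
        label = as.integer(cohort$mci[i_n]),
        features = seq_mat)
    }
  }
  if (length(samples) == 0) return(empty_windows())
  tibble(
    participant_id = vapply(samples, `[[`, character(1), "participant_id"),
    window_index = vapply(samples, `[[`, integer(1), "window_index"),
    label = vapply(samples, `[[`, integer(1), "label"),
    features = lapply(samples, `[[`, "features"))
}

empty_windows <- function() {
  tibble(participant_id = character(0), window_index = integer(0),
         label = integer(0), features = list())
}

#' Split window samples into train / validation / test partitions
#'
#' The partition is by participant (all windows of one person land in the
#' same split, preventing leakage across windows) and stratified on the
#' participant-level outcome (whether any of their windows is labelled
#' positive).  Allocation uses largest-remainder rounding against the global
#' split fractions, so realised sizes track the requested proportions to
#' within one participant.
#'
#' @param windows A window tibble from [build_windows()].
#' @param fractions Named numeric vector summing to 1; default
#'   `c(train = 0.7, validation = 0.15, test = 0.15)`.
#' @param seed Integer seed.
#' @return A named list of window tibbles (one per split) with an
#'   `assignment` attribute mapping participants to splits.
#' @export
split_dataset <- function(windows,
                          fractions = c(train = 0.7, validation = 0.15,
                                        test = 0.15),
                          seed = 1L) {
  if (abs(sum(fractions) - 1) > 1e-8) abort("`fractions` must sum to 1.")
  if (is.null(names(fractions)) || any(names(fractions) == "")) {
    abort("`fractions` must be named.")
  }
  participants <- windows %>%
    group_by(.data$participant_id) %>%
    summarise(any_positive = any(.data$label == 1), .groups = "drop")

  splits <- names(fractions)
  assignment <- withr::with_seed(as.integer(seed), {
    alloc <- rep(NA_character_, nrow(participants))
    total_target <- fractions * nrow(participants)
    given <- setNames(numeric(length(splits)), splits)
    for (grp in unique(participants$any_positive)) {
      idx <- which(participants$any_positive == grp)
      idx <- sample(idx)
      ideal <- fractions * length(idx)
      counts <- floor(ideal)
      left <- length(idx) - sum(counts)
      if (left > 0) {
        ## hand remainders to the splits furthest below their global target
        deficit <- (total_target - given - counts) / pmax(total_target, 1)
        for (s in names(sort(deficit, decreasing = TRUE))[seq_len(left)]) {
          counts[s] <- counts[s] + 1
        }
      }
      pos <- 1
      for (s in splits) {
        if (counts[s] > 0) {
          alloc[idx[pos:(pos + counts[s] - 1)]] <- s
          pos <- pos + counts[s]
        }
      }
      given <- given + counts
    }
    alloc
  })
  assignment_tbl <- tibble(participant_id = participants$participant_id,
                           split = assignment)
  out <- lapply(splits, function(s) {
    ids <- assignment_tbl$participant_id[assignment_tbl$split == s]
    windows[windows$participant_id %in% ids, , drop = FALSE]
  })
  names(out) <- splits
  for (s in splits) {
    labs <- out[[s]]$label
    if (length(unique(labs)) < 2) {
      abort(sprintf(
        "Split `%s` received zero samples of one class; use a larger cohort.",
        s))
    }
  }
  attr(out, "assignment") <- assignment_tbl
  out
}

#' Flatten window feature sequences into a fixed-length design matrix
#'
#' Concatenates the per-wave feature vectors of each window (wave `t`
#' features first, then wave `t+1`), the input format used by the
#' non-sequential baseline learners.
#'
#' @param windows A window tibble.
#' @return A numeric matrix with one row per window.
#' @export
flatten_windows <- function(windows) {
  if (nrow(windows) == 0) return(matrix(numeric(0), 0, 0))
  mats <- windows$features
  out <- t(vapply(mats, function(m) as.vector(t(m)), numeric(length(mats[[1]]))))
  fn <- colnames(mats[[1]])
  if (!is.null(fn)) {
    colnames(out) <- as.vector(vapply(seq_len(nrow(mats[[1]])),
                                      function(t) paste0(fn, "_w", t),
                                      character(length(fn))))
  }
  out
}
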