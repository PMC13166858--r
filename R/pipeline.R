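#' One-call cohort preparation: score, encode, screen, impute, window
#'
#' Convenience wrapper chaining the preparation stages in their canonical
#' order: [score_cohort()] (instrument scoring and labels), [encode_cohort()]
#' (one-hot demographics), [feature_declarations()] +
#' [compute_feature_meta()] + [screen_features()] (four-rule screening),
#' [impute_mi_mean()] over the retained features (only if any are
#' incomplete), and [build_windows()].
#'
#' @param cohort A raw cohort tibble ([simulate_cohort()] / [read_cohort()]).
#' @param seed Seed for the imputation draws.
#' @param reverse_positive Passed to [score_cohort()].
#' @param inconsistent Passed to [feature_declarations()].
#' @return A list with `windows` (tibble from [build_windows()]), `meta`
#'   (screening metadata) and `retained` (the feature manifest).
#' @export
#' @examples
#' prep <- prepare_cohort_windows(
#'   simulate_cohort(cohort_config(n_participants = 100, seed = 1)))
#' nrow(prep$windows)
prepare_cohort_windows <- function(cohort, seed = 1L,
                                   reverse_positive = FALSE,
                                   inconsistent = character(0)) {
  scored <- encode_cohort(score_cohort(cohort,
                                       reverse_positive = reverse_positive))
  meta <- compute_feature_meta(scored,
                               feature_declarations(scored, inconsistent))
  retained <- screen_features(meta)
  if (any(meta$missing_rate[meta$name %in% retained] > 0)) {
    scored <- impute_mi_mean(scored, seed = seed, cols = retained)
  }
  list(windows = build_windows(scored, retained), meta = meta,
       retained = retained)
}
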