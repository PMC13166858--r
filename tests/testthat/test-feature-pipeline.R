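toy_meta <- function() {
  tibble(
    name = c("dep_var", "drifting", "holey", "composite", "clean_a", "clean_b"),
    missing_rate = c(0, 0, 0.3, 0, 0.2, 0.05),
    outcome_derived = c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE),
    inconsistent_across_waves = c(FALSE, TRUE, FALSE, FALSE, FALSE, FALSE),
    composite_overlapping = c(FALSE, FALSE, FALSE, TRUE, FALSE, FALSE))
}

test_that("feature missing rates are pooled cell ratios", {
  d <- tibble(participant_id = letters[1:5], wave = 1L,
              f1 = c(1, NA, 3, 4, 5), f2 = 1:5, f3 = c(NA, NA, NA, 4, 5))
  decl <- tibble(name = c("f1", "f2", "f3"), outcome_derived = FALSE,
                 inconsistent_across_waves = FALSE,
                 composite_overlapping = FALSE)
  meta <- compute_feature_meta(d, decl)
  expect_equal(meta$missing_rate, c(0.2, 0, 0.6))
  expect_error(compute_feature_meta(d, dplyr::mutate(decl, name = c("f1", "f2", "zz"))),
               "absent")
})

test_that("screening applies all four exclusion rules and keeps boundary cases", {
  retained <- screen_features(toy_meta())
  expect_identical(retained, c("clean_a", "clean_b"))
  ## missing rate exactly 0.20 is retained: the rule is strictly > 20%
  expect_true("clean_a" %in% retained)
  expect_identical(screen_features(toy_meta()[0, ]), character(0))
})

test_that("screening is idempotent and order preserving", {
  meta <- toy_meta()
  retained <- screen_features(meta)
  again <- screen_features(meta[meta$name %in% retained, ])
  expect_identical(again, retained)
  rev_meta <- meta[rev(seq_len(nrow(meta))), ]
  expect_identical(screen_features(rev_meta), rev(retained))
})

test_that("imputation is the identity on complete data", {
  d <- tibble(a = rnorm(10), b = rnorm(10))
  expect_identical(impute_mi_mean(d, seed = 1), d)
})

test_that("with no predictive covariates imputation collapses to the column mean", {
  d <- tibble(x = c(2, 4, NA))
  out <- impute_mi_mean(d, m = 200, iters = 3, seed = 5)
  expect_equal(out$x[1:2], c(2, 4))
  expect_lt(abs(out$x[3] - 3), 0.5)
})

test_that("imputation is seeded, complete, and preserves observed cells bit-exactly", {
  withr::with_seed(2, {
    d <- tibble(a = rnorm(40), b = rnorm(40), c = rnorm(40))
    d$a[sample(40, 6)] <- NA
    d$b[sample(40, 5)] <- NA
  })
  out1 <- impute_mi_mean(d, seed = 42)
  out2 <- impute_mi_mean(d, seed = 42)
  expect_identical(out1, out2)
  expect_false(anyNA(out1))
  obs <- !is.na(d$a)
  expect_identical(out1$a[obs], d$a[obs])
  out3 <- impute_mi_mean(d, seed = 43)
  expect_false(identical(out1, out3))
})

test_that("fully missing columns cannot be imputed", {
  d <- tibble(a = c(NA_real_, NA_real_), b = c(1, 2))
  expect_error(impute_mi_mean(d, seed = 1), "entirely missing")
})

test_that("window construction follows the exposure and temporal-sequence rules", {
  base <- tibble(
    participant_id = "p1", wave = 1:3, year = c(2011L, 2013L, 2015L),
    age = c(65, 67, 69), f = c(0.1, 0.2, 0.3),
    depressed = c(TRUE, TRUE, FALSE),
    mci = c(FALSE, FALSE, TRUE),
    cog_total = c(20L, 18L, 5L))
  win <- build_windows(base, "f")
  ## depressed and unimpaired at waves 1 and 2 -> two windows, second converts
  expect_equal(win$window_index, c(1L, 2L))
  expect_equal(win$label, c(0L, 1L))
  expect_equal(win$features[[1]][, "f"], c(0.1, 0.2))

  never_dep <- dplyr::mutate(base, depressed = FALSE)
  expect_equal(nrow(build_windows(never_dep, "f")), 0)

  already_mci <- dplyr::mutate(base, mci = c(TRUE, TRUE, TRUE))
  expect_equal(nrow(build_windows(already_mci, "f")), 0)
})

test_that("window enumeration matches a brute-force oracle over random cohorts", {
  for (seed in 1:50) {
    cfg <- cohort_config(n_participants = 30, seed = seed,
                         missing_rate = 0, n_aux_features = 2,
                         dropout_rate = 0.2)
    scored <- score_cohort(simulate_cohort(cfg))
    feats <- c("age", "cesd_1")
    win <- build_windows(scored, feats)
    ## oracle: enumerate eligible (participant, t) pairs by direct loops
    expected <- 0
    for (id in unique(scored$participant_id)) {
      rows <- scored[scored$participant_id == id, ]
      for (t in rows$wave) {
        now <- rows[rows$wave == t, ]
        nxt <- rows[rows$wave == t + 1, ]
        if (nrow(nxt) == 1 && isTRUE(now$depressed) && !isTRUE(now$mci) &&
            !is.na(nxt$cog_total)) {
          expected <- expected + 1
        }
      }
    }
    expect_equal(nrow(win), expected)
  }
})

test_that("windowing demands scored cohorts and complete features", {
  cohort <- simulate_cohort(cohort_config(n_participants = 10, seed = 1))
  expect_error(build_windows(cohort, "age"), "score_cohort")
  scored <- score_cohort(cohort)
  expect_error(build_windows(scored, "aux_1"), "impute first")
  expect_error(build_windows(scored, "sex"), "not numeric")
  one_wave <- scored[scored$wave == 1, ]
  expect_warning(out <- build_windows(one_wave, "age"), "2 or more waves")
  expect_equal(nrow(out), 0)
})

test_that("splits are by participant, stratified, seeded, and near the fractions", {
  win <- make_windows(n_participants = 150, seed = 19)
  sp <- split_dataset(win, seed = 4)
  asg <- attr(sp, "assignment")
  ## no participant in two splits; every window accounted for
  ids <- lapply(sp, function(w) unique(w$participant_id))
  expect_equal(length(Reduce(intersect, ids)), 0)
  expect_equal(sum(vapply(sp, nrow, integer(1))), nrow(win))
  ## all windows of one participant land together
  by_id <- table(asg$participant_id)
  expect_true(all(by_id == 1))
  ## participant counts near fractions
  counts <- table(asg$split)
  n <- nrow(asg)
  expect_lte(abs(counts[["train"]] - 0.7 * n), 2)
  expect_lte(abs(counts[["validation"]] - 0.15 * n), 2)
  ## seeded determinism
  sp2 <- split_dataset(win, seed = 4)
  expect_identical(attr(sp2, "assignment"), asg)
  sp3 <- split_dataset(win, seed = 5)
  expect_false(identical(attr(sp3, "assignment"), asg))
})

test_that("degenerate splits raise an actionable error", {
  win <- make_windows(n_participants = 30, seed = 23)
  expect_error(
    split_dataset(win, fractions = c(train = 0.9, validation = 0.05,
                                     test = 0.05), seed = 1),
    "larger")
  expect_error(split_dataset(win, fractions = c(train = 0.5, test = 0.4),
                             seed = 1), "sum to 1")
})
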