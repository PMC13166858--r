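test_that("gradient accumulation equals one step on the union batch", {
  cfg <- tiny_model_config()          # dropout 0: gradients are deterministic
  win <- make_windows(n_participants = 60, seed = 3)
  xs <- lapply(win$features[1:16], function(m) scale(m))
  y <- win$label[1:16]
  params <- init_transformer_params(cfg, ncol(xs[[1]]), seed = 5)
  for (acc in c(1, 2, 4)) {
    groups <- split(1:16, ceiling(seq_len(16) / (16 / acc)))
    acc_grads <- NULL
    for (g in groups) {
      bg <- mcirisk:::batch_gradients(g, xs, y, params, cfg)
      acc_grads <- if (is.null(acc_grads)) bg$grads
                   else purrr::map2(acc_grads, bg$grads, `+`)
    }
    acc_grads <- lapply(acc_grads, function(g) g / length(groups))
    union_grads <- mcirisk:::batch_gradients(1:16, xs, y, params, cfg)$grads
    for (nm in names(union_grads)) {
      expect_equal(acc_grads[[nm]], union_grads[[nm]], tolerance = 1e-6,
                   label = sprintf("accumulated %s at accumulation %d", nm, acc))
    }
  }
})

test_that("training is reproducible for a fixed seed", {
  cfg <- tiny_model_config()
  win <- make_windows(n_participants = 80, seed = 6)
  sp <- split_dataset(win, fractions = c(train = 0.6, validation = 0.4),
                      seed = 2)
  tc <- train_config(max_epochs = 2, seed = 9, batch_size = 16)
  f1 <- fit_mci_transformer(sp$train, sp$validation, cfg, tc)
  f2 <- fit_mci_transformer(sp$train, sp$validation, cfg, tc)
  expect_equal(f1$params, f2$params, tolerance = 1e-15)
  expect_equal(f1$log, f2$log)
  tc2 <- train_config(max_epochs = 2, seed = 10, batch_size = 16)
  f3 <- fit_mci_transformer(sp$train, sp$validation, cfg, tc2)
  expect_false(isTRUE(all.equal(f1$params, f3$params)))
})

test_that("dropout is active in training and seeded", {
  cfg <- tiny_model_config(dropout = 0.5)
  params <- init_transformer_params(cfg, 3, seed = 1)
  x <- matrix(rnorm(6), 2, 3)
  p_inference <- replicate(3, forward_predict(x, params, cfg)$prob)
  expect_equal(diff(range(p_inference)), 0)
  withr::with_seed(4, {
    p_a <- forward_predict(x, params, cfg, training = TRUE)$prob
  })
  withr::with_seed(4, {
    p_b <- forward_predict(x, params, cfg, training = TRUE)$prob
  })
  expect_identical(p_a, p_b)
  withr::with_seed(5, {
    p_c <- forward_predict(x, params, cfg, training = TRUE)$prob
  })
  expect_false(identical(p_a, p_c))
})

test_that("patience zero stops at the first non-improving epoch", {
  cfg <- tiny_model_config()
  win <- make_windows(n_participants = 80, seed = 6)
  sp <- split_dataset(win, fractions = c(train = 0.6, validation = 0.4),
                      seed = 2)
  fit <- fit_mci_transformer(sp$train, sp$validation, cfg,
                             train_config(max_epochs = 30, patience = 0,
                                          seed = 3))
  ## the run ends exactly one epoch after the best one
  expect_lt(nrow(fit$log), 30)
  expect_equal(nrow(fit$log), fit$best_epoch + 1)
})

test_that("the trainer refuses a single-class validation split", {
  cfg <- tiny_model_config()
  win <- make_windows(n_participants = 60, seed = 3)
  bad_val <- win[win$label == 0, ][1:5, ]
  expect_error(fit_mci_transformer(win, bad_val, cfg, train_config()),
               "both classes")
})

test_that("grid search is exhaustive, deduplicated and tie-broken as documented", {
  cfg <- tiny_model_config()
  win <- make_windows(n_participants = 80, seed = 12)
  sp <- split_dataset(win, fractions = c(train = 0.6, validation = 0.4),
                      seed = 2)
  tc <- train_config(max_epochs = 1, seed = 5)
  ## single cell: returns that configuration
  single <- tune_grid(sp$train, sp$validation,
                      data.frame(alpha = 1e-3), cfg, tc)
  expect_equal(single$best$alpha, 1e-3)
  expect_equal(nrow(single$results), 1)
  ## duplicates collapse before fitting
  dup <- tune_grid(sp$train, sp$validation,
                   data.frame(alpha = c(1e-3, 1e-3, 3e-4)), cfg, tc)
  expect_equal(nrow(dup$results), 2)
  ## self-consistency: the reported best is the argmax of the table
  ord <- order(-dup$results$val_auc,
               -ifelse(is.na(dup$results$val_f1), -Inf, dup$results$val_f1),
               dup$results$alpha)
  expect_equal(dup$best, dup$results[ord[1], ])
  expect_error(tune_grid(sp$train, sp$validation, data.frame(), cfg, tc),
               "empty")
})

test_that("baseline learners are seeded and collapse to chance on constant features", {
  win <- make_windows(n_participants = 100, seed = 25)
  sp <- split_dataset(win, seed = 3)
  ## constant features carry no signal
  flat <- lapply(sp, function(w) {
    w$features <- lapply(w$features, function(m) {m[] <- 1; m})
    w
  })
  rep1 <- run_baselines(flat, seed = 7, nrounds = 10)
  expect_true(all(abs(rep1$auc[rep1$split == "test"] - 0.5) < 0.12))
  rep2 <- run_baselines(flat, seed = 7, nrounds = 10)
  expect_identical(rep1, rep2)
  expect_setequal(rep1$model, c("xgboost", "svm"))
})

test_that("baselines recover the planted signal on informative features", {
  win <- make_windows(n_participants = 300, seed = 26)
  sp <- split_dataset(win, seed = 3)
  rep <- run_baselines(sp, seed = 7, nrounds = 50)
  expect_true(all(rep$auc[rep$split == "test"] > 0.6))
})

test_that("the attention heatmap has manifest-aligned rows and honest zeros", {
  cfg <- tiny_model_config()
  win <- make_windows(n_participants = 60, seed = 3)
  sp <- split_dataset(win, fractions = c(train = 0.6, validation = 0.4),
                      seed = 2)
  fit <- fit_mci_transformer(sp$train, sp$validation, cfg,
                             train_config(max_epochs = 1, seed = 1))
  hm <- export_attention_heatmap(fit, sp$validation)
  expect_equal(dim(hm), c(length(fit$feature_names), cfg$d_model))
  expect_identical(rownames(hm), fit$feature_names)
  expect_true(all(hm >= 0))
  ## zero input projection produces an all-zero attribution matrix
  fit0 <- fit
  fit0$params$w_in <- fit0$params$w_in * 0
  hm0 <- export_attention_heatmap(fit0, sp$validation)
  expect_true(all(hm0 == 0))
  ## CSV export round-trips the matrix
  f <- withr::local_tempfile(fileext = ".csv")
  export_attention_heatmap(fit, sp$validation, path = f)
  back <- readr::read_csv(f, show_col_types = FALSE)
  expect_equal(back$feature, rownames(hm))
  expect_equal(as.matrix(back[, -1]), unclass(hm)[, ], ignore_attr = TRUE,
               tolerance = 1e-12)
})

test_that("tidy and glance summarise a fit in broom style", {
  cfg <- tiny_model_config()
  win <- make_windows(n_participants = 60, seed = 3)
  sp <- split_dataset(win, fractions = c(train = 0.6, validation = 0.4),
                      seed = 2)
  fit <- fit_mci_transformer(sp$train, sp$validation, cfg,
                             train_config(max_epochs = 1, seed = 1))
  td <- tidy(fit)
  expect_true(all(c("term", "n_values", "mean", "sd") %in% names(td)))
  expect_equal(sum(td$n_values), n_model_params(cfg, ncol(win$features[[1]])))
  gl <- glance(fit)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$n_params, sum(td$n_values))
  expect_s3_class(autoplot(fit), "ggplot")
})
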