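#' Gradient-boosted-tree and kernel-margin baselines
#'
#' Fits XGBoost and a radial-kernel SVM on the same splits as the
#' transformer, with the window feature sequences flattened to fixed-length
#' vectors (wave `t` features concatenated with wave `t+1` features), and
#' evaluates them with the identical six-metric report.
#'
#' @param splits A named list of window tibbles from [split_dataset()]
#'   (must contain `train` and `test`; `validation` is unused here).
#' @param seed Integer seed; fixed seed gives identical reports.
#' @param nrounds,max_depth,eta XGBoost settings (defaults 100, 3, 0.1).
#' @return A tibble with one row per (model, split) holding the six metrics
#'   and confusion counts.
#' @export
run_baselines <- function(splits, seed = 1L, nrounds = 100, max_depth = 3,
                          eta = 0.1) {
  x_train <- flatten_windows(splits$train)
  x_test <- flatten_windows(splits$test)
  y_train <- splits$train$label
  y_test <- splits$test$label

  ## standardise with training statistics (shared with the SVM)
  centre <- colMeans(x_train)
  scl <- apply(x_train, 2, sd)
  scl[scl == 0 | is.na(scl)] <- 1
  zs <- function(x) sweep(sweep(x, 2, centre, "-"), 2, scl, "/")

  preds <- withr::with_seed(as.integer(seed), {
    dtrain <- xgboost::xgb.DMatrix(x_train, label = y_train, nthread = 1)
    xgb <- xgboost::xgb.train(
      params = list(objective = "binary:logistic", max_depth = max_depth,
                    eta = eta, nthread = 1),
      data = dtrain, nrounds = nrounds, verbose = 0)
    svm_fit <- e1071::svm(zs(x_train), factor(y_train, levels = c(0, 1)),
                          kernel = "radial", probability = TRUE,
                          scale = FALSE)
    svm_prob <- function(x) {
      attr(predict(svm_fit, zs(x), probability = TRUE),
           "probabilities")[, "1"]
    }
    list(xgboost = list(train = predict(xgb, x_train),
                        test = predict(xgb, x_test)),
         svm = list(train = svm_prob(x_train), test = svm_prob(x_test)))
  })

  labels <- list(train = y_train, test = y_test)
  bind_rows(lapply(names(preds), function(model) {
    bind_rows(lapply(c("train", "test"), function(split) {
      dplyr::bind_cols(tibble(model = model, split = split),
                       compute_metrics(labels[[split]],
                                       preds[[model]][[split]]))
    }))
  }))
}
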