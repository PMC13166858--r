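#' Exhaustive grid search over training hyperparameters
#'
#' Fits one model per distinct grid row (duplicates are removed first) and
#' selects the best configuration by validation AUC, breaking ties by
#' validation F1 and then by the smallest learning rate.  A Bayesian
#' proposal function can be plugged in through `extra_configs` to extend the
#' evaluated set; the core search itself is the exhaustive grid.
#'
#' @param train_windows,val_windows Window tibbles.
#' @param grid A data frame with any of the columns `alpha` (learning
#'   rate), `weight_decay` and `batch_size`; other training settings come
#'   from `base_train`.
#' @param config A [model_config()].
#' @param base_train A [train_config()] supplying the non-tuned settings.
#' @param extra_configs Optional data frame of additional configurations to
#'   evaluate (the pluggable optimisation hook); same columns as `grid`.
#' @return A list with `best` (one-row tibble), `results` (one row per
#'   evaluated configuration) and `fit` (the refitted best model).
#' @export
tune_grid <- function(train_windows, val_windows, grid,
                      config = model_config(),
                      base_train = train_config(),
                      extra_configs = NULL) {
  grid <- as_tibble(grid)
  if (!is.null(extra_configs)) grid <- bind_rows(grid, as_tibble(extra_configs))
  if (nrow(grid) == 0) abort("The hyperparameter grid is empty.")
  grid <- grid[!duplicated(grid), , drop = FALSE]

  rows <- vector("list", nrow(grid))
  fits <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    tc <- base_train
    for (nm in intersect(names(grid), c("alpha", "weight_decay",
                                        "batch_size"))) {
      tc[[nm]] <- if (nm == "batch_size") as.integer(grid[[nm]][i])
                  else grid[[nm]][i]
    }
    fit <- fit_mci_transformer(train_windows, val_windows, config, tc)
    val <- predict(fit, val_windows)
    mets <- compute_metrics(val$label, val$prob)
    rows[[i]] <- dplyr::bind_cols(grid[i, , drop = FALSE],
                                  tibble(val_auc = mets$auc,
                                         val_f1 = mets$f1))
    fits[[i]] <- fit
  }
  results <- bind_rows(rows)
  ord <- order(-results$val_auc, -replace_na_num(results$val_f1),
               if ("alpha" %in% names(results)) results$alpha
               else seq_len(nrow(results)))
  best_i <- ord[1]
  list(best = results[best_i, , drop = FALSE], results = results,
       fit = fits[[best_i]])
}

replace_na_num <- function(x) ifelse(is.na(x), -Inf, x)
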