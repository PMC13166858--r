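#' Training configuration
#'
#' @param batch_size Mini-batch size (default 32).
#' @param accumulation Number of consecutive mini-batches whose mean
#'   gradients are averaged before each optimizer step (default 4,
#'   emulating a four-fold larger effective batch).
#' @param max_epochs Upper bound on training epochs (default 20).
#' @param patience Early-stopping patience in epochs on the monitored
#'   validation metric (default 3; `patience = 0` stops at the first
#'   non-improving epoch).  The best-validation checkpoint is restored.
#' @param monitor Validation metric to monitor, `"auc"` (default, maximised)
#'   or `"loss"` (minimised).
#' @param seed Integer seed governing initialisation, shuffling and dropout.
#' @param alpha,weight_decay AdamW learning rate and decay factor
#'   (defaults 3e-4 and 0.01).
#' @param verbose Print one line per epoch?
#' @return A list of class `train_config`.
#' @export
train_config <- function(batch_size = 32, accumulation = 4, max_epochs = 20,
                         patience = 3, monitor = c("auc", "loss"),
                         seed = 1L, alpha = 3e-4, weight_decay = 0.01,
                         verbose = FALSE) {
  monitor <- match.arg(monitor)
  if (accumulation < 1) abort("`accumulation` must be >= 1.")
  if (batch_size < 1) abort("`batch_size` must be >= 1.")
  structure(
    list(batch_size = as.integer(batch_size),
         accumulation = as.integer(accumulation),
         max_epochs = as.integer(max_epochs),
         patience = as.integer(patience), monitor = monitor,
         seed = as.integer(seed), alpha = alpha,
         weight_decay = weight_decay, verbose = isTRUE(verbose)),
    class = "train_config")
}

## mean-reduced loss gradient over one mini-batch of windows
batch_gradients <- function(idx, xs, labels, params, config) {
  grads <- NULL
  loss <- 0
  for (i in idx) {
    fwd <- forward_predict(xs[[i]], params, config,
                           training = config$dropout > 0, keep_cache = TRUE)
    loss <- loss + bce_loss(labels[i], fwd$prob, reduction = "sum")
    g <- backward_predict(fwd$cache, params, config, fwd$prob - labels[i])
    grads <- if (is.null(grads)) g else map2(grads, g, `+`)
  }
  list(grads = lapply(grads, function(g) g / length(idx)),
       loss = loss / length(idx))
}

#' Fit the transformer risk model
#'
#' Trains on the window samples with mean-reduced binary cross-entropy,
#' AdamW, gradient accumulation and early stopping on the validation
#' metric.  Continuous features are standardised with training-split means
#' and SDs (stored in the fit and applied at prediction time).  The run is
#' fully seeded: initialisation, shuffling and dropout reproduce exactly for
#' a fixed `train_config$seed`.
#'
#' @param train_windows,val_windows Window tibbles from [build_windows()]
#'   (typically the `train` and `validation` elements of [split_dataset()]).
#' @param config A [model_config()].
#' @param train A [train_config()].
#' @return An object of class `mci_transformer`: parameters, configs,
#'   scaler, per-epoch `log` tibble, and the restored best epoch.
#' @export
fit_mci_transformer <- function(train_windows, val_windows,
                                config = model_config(),
                                train = train_config()) {
  if (nrow(train_windows) == 0) abort("No training windows.")
  if (length(unique(val_windows$label)) < 2) {
    abort("Validation set must contain both classes.")
  }
  feature_names <- colnames(train_windows$features[[1]])
  scaler <- fit_scaler(train_windows)
  xs <- lapply(train_windows$features, scale_features, scaler = scaler)
  xs_val <- lapply(val_windows$features, scale_features, scaler = scaler)
  y <- train_windows$label
  y_val <- val_windows$label
  n <- length(xs)

  withr::with_seed(train$seed, {
    params <- init_transformer_params(config, ncol(xs[[1]]),
                                      seed = sample.int(1e6, 1))
    opt <- adamw_init(params, alpha = train$alpha,
                      lambda = train$weight_decay)
    best <- list(metric = -Inf, params = params, epoch = 0L)
    bad_epochs <- 0L
    log <- list()
    for (epoch in seq_len(train$max_epochs)) {
      order_idx <- sample.int(n)
      groups <- split(order_idx,
                      ceiling(seq_along(order_idx) / train$batch_size))
      epoch_loss <- 0
      gi <- 1
      while (gi <= length(groups)) {
        take <- groups[seq(gi, min(gi + train$accumulation - 1,
                                   length(groups)))]
        acc_grads <- NULL
        for (g in take) {
          bg <- batch_gradients(g, xs, y, params, config)
          epoch_loss <- epoch_loss + bg$loss * length(g)
          acc_grads <- if (is.null(acc_grads)) bg$grads
                       else map2(acc_grads, bg$grads, `+`)
        }
        acc_grads <- lapply(acc_grads, function(g) g / length(take))
        step <- adamw_step(params, acc_grads, opt)
        params <- step$params
        opt <- step$state
        gi <- gi + train$accumulation
      }
      val_probs <- vapply(xs_val, function(x) {
        forward_predict(x, params, config)$prob
      }, numeric(1))
      val_auc <- roc_auc(y_val, val_probs)
      val_loss <- bce_loss(y_val, val_probs, reduction = "mean")
      metric <- if (train$monitor == "auc") val_auc else -val_loss
      log[[epoch]] <- tibble(epoch = epoch, train_loss = epoch_loss / n,
                             val_loss = val_loss, val_auc = val_auc)
      if (train$verbose) {
        cat(sprintf("epoch %2d  train loss %.4f  val loss %.4f  val AUC %.4f\n",
                    epoch, epoch_loss / n, val_loss, val_auc))
      }
      if (metric > best$metric) {
        best <- list(metric = metric, params = params, epoch = epoch)
        bad_epochs <- 0L
      } else {
        bad_epochs <- bad_epochs + 1L
        if (bad_epochs > train$patience) break
      }
    }
  })
  structure(
    list(params = best$params, config = config, train = train,
         scaler = scaler, feature_names = feature_names,
         log = bind_rows(log), best_epoch = best$epoch,
         n_train = n, n_val = length(y_val)),
    class = "mci_transformer")
}

fit_scaler <- function(windows) {
  pooled <- do.call(rbind, windows$features)
  centre <- colMeans(pooled)
  scale <- apply(pooled, 2, sd)
  scale[scale == 0 | is.na(scale)] <- 1
  list(centre = centre, scale = scale)
}

#' @export
print.mci_transformer <- function(x, ...) {
  cat("<mci_transformer>\n")
  cat(sprintf("  %d features, d_model %d, %d heads, encoder x%d, decoder x%d\n",
              length(x$feature_names), x$config$d_model, x$config$n_heads,
              x$config$n_encoder_layers, x$config$n_decoder_layers))
  cat(sprintf("  trained on %d windows (%d validation), best epoch %d, val AUC %.3f\n",
              x$n_train, x$n_val, x$best_epoch,
              x$log$val_auc[x$best_epoch]))
  invisible(x)
}

#' Predict next-wave MCI risk for window samples
#'
#' @param object A fitted `mci_transformer`.
#' @param newdata A window tibble.
#' @param ... Unused.
#' @return `newdata` with a `prob` column of risk probabilities appended.
#' @export
predict.mci_transformer <- function(object, newdata, ...) {
  out <- as_tibble(newdata)
  out$prob <- predict_windows(newdata, object$params, object$config,
                              object$scaler)
  out
}

#' @method tidy mci_transformer
#' @export
tidy.mci_transformer <- function(x, ...) {
  tibble(term = names(x$params),
         n_values = vapply(x$params, length, integer(1)),
         mean = vapply(x$params, function(p) mean(as.numeric(p)), numeric(1)),
         sd = vapply(x$params, function(p) {
           if (length(p) > 1) sd(as.numeric(p)) else NA_real_
         }, numeric(1)))
}

#' @method glance mci_transformer
#' @export
glance.mci_transformer <- function(x, ...) {
  tibble(n_train = x$n_train, n_val = x$n_val,
         n_params = sum(vapply(x$params, length, integer(1))),
         epochs_run = nrow(x$log), best_epoch = x$best_epoch,
         val_auc = x$log$val_auc[x$best_epoch],
         val_loss = x$log$val_loss[x$best_epoch])
}

#' @method autoplot mci_transformer
#' @export
autoplot.mci_transformer <- function(object, ...) {
  d <- tidyr::pivot_longer(object$log, c("train_loss", "val_loss", "val_auc"),
                           names_to = "series", values_to = "value")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$epoch, y = .data$value,
                                  colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$best_epoch, linetype = 2) +
    ggplot2::facet_wrap(~series, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "epoch", y = NULL, colour = NULL,
                  title = "Training trajectory (dashed: restored epoch)") +
    ggplot2::theme_minimal()
}
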