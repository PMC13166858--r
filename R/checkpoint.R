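#' Portable text checkpoints
#'
#' Serialises a fitted model -- architecture configuration, training
#' settings, scaler, feature manifest and every named parameter array (with
#' dimensions) -- to a single JSON document, and restores it.  The format is
#' plain text and versioned, so checkpoints can cross machines and R
#' versions.
#'
#' @param fit A fitted `mci_transformer`.
#' @param path Checkpoint file path.
#' @return `write_checkpoint()` returns `path` invisibly;
#'   `read_checkpoint()` returns an `mci_transformer`.
#' @export
write_checkpoint <- function(fit, path) {
  if (!requireNamespace("jsonlite", quietly = TRUE)) {
    abort("Package `jsonlite` is required for checkpoint I/O.")
  }
  payload <- list(
    format = "mcirisk-checkpoint-1",
    config = unclass(fit$config),
    train = unclass(fit$train),
    scaler = fit$scaler,
    feature_names = fit$feature_names,
    best_epoch = fit$best_epoch,
    n_train = fit$n_train, n_val = fit$n_val,
    log = fit$log,
    params = lapply(fit$params, function(p) {
      list(dim = dim(p) %||% length(p), values = as.numeric(p))
    }))
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_checkpoint
#' @export
read_checkpoint <- function(path) {
  if (!requireNamespace("jsonlite", quietly = TRUE)) {
    abort("Package `jsonlite` is required for checkpoint I/O.")
  }
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(payload$format, "mcirisk-checkpoint-1")) {
    abort("Not a recognised checkpoint file.")
  }
  config <- do.call(model_config, payload$config[setdiff(
    names(payload$config), character(0))])
  train <- do.call(train_config, payload$train)
  params <- lapply(payload$params, function(p) {
    if (length(p$dim) == 2) matrix(p$values, p$dim[1], p$dim[2])
    else p$values
  })
  structure(
    list(params = params, config = config, train = train,
         scaler = list(centre = payload$scaler$centre,
                       scale = payload$scaler$scale),
         feature_names = payload$feature_names,
         log = as_tibble(payload$log), best_epoch = payload$best_epoch,
         n_train = payload$n_train, n_val = payload$n_val),
    class = "mci_transformer")
}
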