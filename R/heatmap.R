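#' Feature-by-embedding-dimension attention attribution matrix
#'
#' A constructive interpretation map of a trained model: entry `(f, d)` is
#' the magnitude of the input-projection weight tying feature `f` to
#' embedding dimension `d`, modulated by how much decoder attention mass
#' each wave receives and by the mean absolute (standardised) value of the
#' feature at that wave, averaged over the supplied samples:
#' `M[f, d] = |W_in[f, d]| * sum_t alpha_t * mean_i |x_i[t, f]|`, with
#' `alpha_t` the decoder cross-attention weight on wave `t` averaged over
#' samples and heads.  Rows follow the retained-feature manifest order.
#'
#' @param fit A fitted `mci_transformer`.
#' @param windows Window samples over which attention is averaged.
#' @param path Optional CSV path to write the matrix to.
#' @return A numeric matrix (features x d_model) of class
#'   `mci_attention_heatmap`, invisibly written to `path` if given.
#' @export
export_attention_heatmap <- function(fit, windows, path = NULL) {
  if (is.null(fit$log) || nrow(fit$log) == 0) {
    warn("Model appears untrained; the attribution map reflects the initialisation.")
  }
  nh <- fit$config$n_heads
  n_waves <- nrow(windows$features[[1]])
  alpha <- rep(0, n_waves)
  absx <- matrix(0, n_waves, length(fit$feature_names))
  for (m in windows$features) {
    xs <- scale_features(m, fit$scaler)
    fwd <- forward_predict(xs, fit$params, fit$config, keep_cache = TRUE)
    dec_att <- fwd$cache$dec[[length(fwd$cache$dec)]]$att$weights
    alpha <- alpha + Reduce(`+`, lapply(dec_att, as.numeric)) / nh
    absx <- absx + abs(xs)
  }
  alpha <- alpha / nrow(windows)
  absx <- absx / nrow(windows)
  weight <- as.numeric(t(absx) %*% alpha)      # per-feature attention mass
  mat <- abs(fit$params$w_in) * weight
  rownames(mat) <- fit$feature_names
  colnames(mat) <- paste0("dim_", seq_len(ncol(mat)))
  class(mat) <- c("mci_attention_heatmap", class(mat))
  if (!is.null(path)) {
    readr::write_csv(as_tibble(unclass(mat), rownames = "feature"), path)
  }
  mat
}

#' @method autoplot mci_attention_heatmap
#' @export
autoplot.mci_attention_heatmap <- function(object, ...) {
  d <- as_tibble(unclass(object), rownames = "feature") %>%
    tidyr::pivot_longer(-"feature", names_to = "dimension",
                        values_to = "attribution")
  d$dimension <- as.integer(sub("dim_", "", d$dimension))
  d$feature <- factor(d$feature, levels = rev(rownames(object)))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$dimension, y = .data$feature,
                                  fill = .data$attribution)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "embedding dimension", y = "feature",
                  fill = "attribution",
                  title = "Attention-weighted input attribution") +
    ggplot2::theme_minimal()
}

#' ROC curve plot for one or more score sets
#'
#' @param labels Binary labels.
#' @param probs Scores.
#' @return A ggplot object.
#' @export
plot_roc <- function(labels, probs) {
  pts <- roc_points(labels, probs)
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 3) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "false positive rate", y = "true positive rate",
                  title = sprintf("ROC (AUC = %.3f)",
                                  roc_auc(labels, probs))) +
    ggplot2::theme_minimal()
}
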