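## Parameter initialisation.  Matrices use Glorot-normal scales; layer-norm
## scales start at 1, biases and the relative-bias table at 0; the depthwise
## kernel starts near the identity tap so the convolution is initially a
## gentle perturbation of its input.

glorot <- function(nr, nc) {
  matrix(rnorm(nr * nc, 0, sqrt(2 / (nr + nc))), nr, nc)
}

init_block_params <- function(prefix, cfg) {
  d <- cfg$d_model; dffn <- cfg$d_ffn; k <- cfg$conv_kernel
  dw <- matrix(rnorm(k * d, 0, 0.02), k, d)
  dw[(k + 1) %/% 2, ] <- dw[(k + 1) %/% 2, ] + 1
  p <- list(
    wq = glorot(d, d), wk = glorot(d, d), wv = glorot(d, d),
    wo = glorot(d, d),
    ln1_g = rep(1, d), ln1_b = rep(0, d),
    ffn_w1 = glorot(d, dffn), ffn_b1 = rep(0, dffn),
    ffn_w2 = glorot(dffn, d), ffn_b2 = rep(0, d),
    glu_w = glorot(d, d), glu_b = rep(0, d),
    conv_dw = dw, conv_pw = glorot(d, d), conv_b = rep(0, d),
    ln2_g = rep(1, d), ln2_b = rep(0, d))
  names(p) <- paste0(prefix, "_", names(p))
  p
}

#' Initialise the learnable parameters of the risk model
#'
#' @param config A [model_config()].
#' @param n_features Input feature width.
#' @param seed Integer seed for the random draws.
#' @return A named list of parameter arrays.
#' @export
init_transformer_params <- function(config, n_features, seed = 1L) {
  withr::with_seed(as.integer(seed), {
    d <- config$d_model
    params <- c(
      list(w_in = glorot(n_features, d), b_in = rep(0, d),
           ## positional rows start clearly separated so short sequences are
           ## order-distinguishable from the first step
           pe = matrix(rnorm(config$max_len * d, 0, 0.3),
                       config$max_len, d),
           b_rel = matrix(0, config$n_heads,
                          2 * config$max_relative_distance + 1)),
      unlist(lapply(seq_len(config$n_encoder_layers), function(l) {
        init_block_params(paste0("enc", l), config)
      }), recursive = FALSE),
      list(dec_query = matrix(rnorm(d, 0, 0.02), 1, d)),
      unlist(lapply(seq_len(config$n_decoder_layers), function(l) {
        init_block_params(paste0("dec", l), config)
      }), recursive = FALSE),
      list(head_w = matrix(rnorm(d, 0, 0.02), d, 1), head_b = 0))
    params
  })
}
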