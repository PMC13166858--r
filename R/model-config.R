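#' Transformer architecture configuration
#'
#' Dimensions and numerical constants of the risk model: token width
#' `d_model` (reference configuration 512 with 8 attention heads; smaller
#' widths train comfortably on a desktop CPU and are used throughout the
#' examples), encoder/decoder depth, gated feedforward width, the
#' depthwise-separable convolution kernel, the clipping range of the
#' relative positional bias, and the layer-norm epsilon (1e-12).
#'
#' @param d_model Token embedding width (default 512); must be divisible by
#'   `n_heads`.
#' @param n_heads Number of attention heads (default 8).
#' @param n_encoder_layers,n_decoder_layers Stack depths (defaults 2 and 1).
#' @param d_ffn Feedforward hidden width (default `4 * d_model`).
#' @param dropout Dropout rate applied to attention weights and feedforward
#'   activations during training (default 0.1).
#' @param conv_kernel Odd depthwise kernel width (default 3).
#' @param max_relative_distance Relative positions are clipped to
#'   `[-max_relative_distance, max_relative_distance]` when indexing the
#'   learnable bias table (default 8).
#' @param layernorm_eps Numerical-stability constant of layer normalisation
#'   (default 1e-12).
#' @param max_len Largest supported sequence length for the learnable
#'   positional table (default 8).
#' @return A list of class `model_config`.
#' @export
model_config <- function(d_model = 512, n_heads = 8,
                         n_encoder_layers = 2, n_decoder_layers = 1,
                         d_ffn = 4 * d_model, dropout = 0.1,
                         conv_kernel = 3, max_relative_distance = 8,
                         layernorm_eps = 1e-12, max_len = 8) {
  if (d_model %% n_heads != 0) {
    abort("`d_model` must be divisible by `n_heads`.")
  }
  if (conv_kernel %% 2 != 1) abort("`conv_kernel` must be odd.")
  if (dropout < 0 || dropout >= 1) abort("`dropout` must lie in [0, 1).")
  structure(
    list(d_model = as.integer(d_model), n_heads = as.integer(n_heads),
         n_encoder_layers = as.integer(n_encoder_layers),
         n_decoder_layers = as.integer(n_decoder_layers),
         d_ffn = as.integer(d_ffn), dropout = dropout,
         conv_kernel = as.integer(conv_kernel),
         max_relative_distance = as.integer(max_relative_distance),
         layernorm_eps = layernorm_eps, max_len = as.integer(max_len)),
    class = "model_config")
}

#' @export
print.model_config <- function(x, ...) {
  cat("<model_config>\n")
  cat(sprintf("  d_model %d, %d heads (d_k = %d), encoder x%d, decoder x%d\n",
              x$d_model, x$n_heads, x$d_model %/% x$n_heads,
              x$n_encoder_layers, x$n_decoder_layers))
  cat(sprintf("  d_ffn %d, dropout %.2f, conv kernel %d, rel. distance +/-%d\n",
              x$d_ffn, x$dropout, x$conv_kernel, x$max_relative_distance))
  invisible(x)
}

#' Analytic parameter count of the architecture
#'
#' The total number of learnable scalars is a pure function of the
#' configuration and the input feature width: input projection and bias,
#' positional table, shared relative-bias table, and per layer the four
#' attention projections, two adaptive layer norms, the two feedforward
#' maps, the sigmoid gate, and the depthwise + pointwise convolution, plus
#' the decoder query and the scalar risk head.
#'
#' @param config A [model_config()].
#' @param n_features Input feature width.
#' @return Integer parameter count.
#' @export
n_model_params <- function(config, n_features) {
  d <- config$d_model; dffn <- config$d_ffn; k <- config$conv_kernel
  per_layer <- 4 * d * d + 4 * d +          # q,k,v,o projections + 2 AdaLN
    (d * dffn + dffn) + (dffn * d + d) +    # feedforward maps
    (d * d + d) +                           # sigmoid gate
    (k * d + d * d + d)                     # depthwise + pointwise conv
  n_layers <- config$n_encoder_layers + config$n_decoder_layers
  n_features * d + d +                      # input projection
    config$max_len * d +                    # positional table
    config$n_heads * (2 * config$max_relative_distance + 1) +
    n_layers * per_layer +
    d +                                     # decoder query token
    d + 1                                   # risk head
}
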