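## Forward pass.  Every sublayer follows the residual wiring
## AdaLN(x + Sublayer(x)); within a block the first sublayer is (multi-head)
## attention and the second is the GLU-gated feedforward followed by the
## depthwise-separable convolution.  The decoder is a single learned query
## token cross-attending over the encoder output, topped by a scalar
## sigmoid risk head.

block_params <- function(params, prefix) {
  keys <- c("wq", "wk", "wv", "wo", "ln1_g", "ln1_b", "ffn_w1", "ffn_b1",
            "ffn_w2", "ffn_b2", "glu_w", "glu_b", "conv_dw", "conv_pw",
            "conv_b", "ln2_g", "ln2_b")
  setNames(params[paste0(prefix, "_", keys)], keys)
}

draw_mask <- function(nr, nc, dropout) {
  matrix((runif(nr * nc) >= dropout) / (1 - dropout), nr, nc)
}

## attention sublayer with cache; bias_table NULL disables positional bias
mha_fwd <- function(x_q, x_kv, pp, bias_table, cfg, training, dropout) {
  d <- cfg$d_model; nh <- cfg$n_heads; dk <- d %/% nh
  qp <- x_q %*% pp$wq
  kp <- x_kv %*% pp$wk
  vp <- x_kv %*% pp$wv
  nq <- nrow(x_q); nk <- nrow(x_kv)
  heads <- vector("list", nh); weights <- vector("list", nh)
  masks <- vector("list", nh)
  for (h in seq_len(nh)) {
    idx <- ((h - 1) * dk + 1):(h * dk)
    bmat <- if (!is.null(bias_table)) {
      rel_bias_matrix(bias_table[h, ], seq_len(nq), seq_len(nk),
                      cfg$max_relative_distance)
    } else NULL
    s <- qp[, idx, drop = FALSE] %*% t(kp[, idx, drop = FALSE])
    if (!is.null(bmat)) s <- s + bmat
    w <- softmax_rows(s / sqrt(dk))
    wd <- w
    if (training && dropout > 0) {
      masks[[h]] <- draw_mask(nq, nk, dropout)
      wd <- w * masks[[h]]
    }
    heads[[h]] <- wd %*% vp[, idx, drop = FALSE]
    weights[[h]] <- w
  }
  concat <- do.call(cbind, heads)
  list(out = concat %*% pp$wo,
       cache = list(qp = qp, kp = kp, vp = vp, weights = weights,
                    masks = masks, concat = concat, x_q = x_q, x_kv = x_kv,
                    has_bias = !is.null(bias_table)))
}

ffn_conv_fwd <- function(h1, pp, cfg, training, dropout) {
  u1 <- sweep(h1 %*% pp$ffn_w1, 2, pp$ffn_b1, "+")
  u2 <- gelu(u1)
  mask <- NULL
  u2d <- u2
  if (training && dropout > 0) {
    mask <- draw_mask(nrow(u2), ncol(u2), dropout)
    u2d <- u2 * mask
  }
  f <- sweep(u2d %*% pp$ffn_w2, 2, pp$ffn_b2, "+")
  a <- sweep(f %*% pp$glu_w, 2, pp$glu_b, "+")
  s <- sigmoid(a)
  g <- f * s
  y <- depthwise_conv(g, pp$conv_dw)
  z <- sweep(y %*% pp$conv_pw, 2, pp$conv_b, "+")
  list(out = z,
       cache = list(h1 = h1, u1 = u1, u2 = u2, mask = mask, u2d = u2d,
                    f = f, s = s, g = g, y = y))
}

block_fwd <- function(x_q, x_kv, pp, bias_table, cfg, training, dropout) {
  att <- mha_fwd(x_q, x_kv, pp, bias_table, cfg, training, dropout)
  r1 <- x_q + att$out
  ln1 <- adaln_fwd(r1, pp$ln1_g, pp$ln1_b, cfg$layernorm_eps)
  h1 <- ln1$out
  ffn <- ffn_conv_fwd(h1, pp, cfg, training, dropout)
  r2 <- h1 + ffn$out
  ln2 <- adaln_fwd(r2, pp$ln2_g, pp$ln2_b, cfg$layernorm_eps)
  list(out = ln2$out,
       cache = list(att = att$cache, ln1 = ln1, ffn = ffn$cache, ln2 = ln2))
}

#' Forward pass of the risk model
#'
#' Embeds the per-wave feature sequence with its learnable positional table,
#' runs the encoder stack (relative-position multi-head self-attention and
#' GLU-gated feedforward + depthwise-separable convolution sublayers, each
#' residually wrapped in adaptive layer normalisation), lets a single
#' learned decoder query attend over the encoder output, and maps the
#' decoder state through a linear + sigmoid head to the next-wave MCI risk.
#'
#' @param x Feature-sequence matrix (waves x features), e.g. one element of
#'   the `features` list column of [build_windows()].
#' @param params Parameter list from [init_transformer_params()] or a
#'   trained fit.
#' @param config The matching [model_config()].
#' @param training Apply dropout? (default `FALSE`: inference is
#'   deterministic).
#' @param keep_cache Keep intermediate activations for the backward pass?
#' @return A list with `prob` (risk in (0, 1)), `logit`, and, if requested,
#'   `cache`.
#' @export
forward_predict <- function(x, params, config, training = FALSE,
                            keep_cache = FALSE) {
  if (is.null(params$w_in)) abort("Parameters are not initialised.")
  dropout <- if (training) config$dropout else 0
  h0 <- embed_sequence(x, params$w_in, params$b_in, params$pe)
  h <- h0
  enc_caches <- vector("list", config$n_encoder_layers)
  for (l in seq_len(config$n_encoder_layers)) {
    blk <- block_fwd(h, h, block_params(params, paste0("enc", l)),
                     params$b_rel, config, training, dropout)
    enc_caches[[l]] <- blk$cache
    h <- blk$out
  }
  enc_out <- h
  dec_caches <- vector("list", config$n_decoder_layers)
  dq <- params$dec_query
  for (l in seq_len(config$n_decoder_layers)) {
    blk <- block_fwd(dq, enc_out, block_params(params, paste0("dec", l)),
                     NULL, config, training, dropout)
    dec_caches[[l]] <- blk$cache
    dq <- blk$out
  }
  logit <- as.numeric(dq %*% params$head_w + params$head_b)
  prob <- sigmoid(logit)
  out <- list(prob = prob, logit = logit)
  if (keep_cache) {
    out$cache <- list(x = x, h0 = h0, enc = enc_caches, enc_out = enc_out,
                      dec = dec_caches, dec_out = dq)
  }
  out
}

#' Risk probabilities for a set of windows
#'
#' @param windows A window tibble from [build_windows()].
#' @param params,config As in [forward_predict()].
#' @param scaler Optional standardisation (list with `centre`, `scale`)
#'   applied to each feature column before the forward pass.
#' @return Numeric vector of probabilities.
#' @export
predict_windows <- function(windows, params, config, scaler = NULL) {
  vapply(windows$features, function(m) {
    if (!is.null(scaler)) m <- scale_features(m, scaler)
    forward_predict(m, params, config)$prob
  }, numeric(1))
}

scale_features <- function(m, scaler) {
  sweep(sweep(m, 2, scaler$centre, "-"), 2, scaler$scale, "/")
}
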