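## Reverse-mode gradients of the forward pass.  Each *_bwd mirrors its
## forward counterpart in model-forward.R and returns gradients for the
## block inputs and a named list of parameter gradients.  Correctness is
## checked against central finite differences in the test suite.

mha_bwd <- function(dout, cache, pp, cfg, bias_table, dropout) {
  d <- cfg$d_model; nh <- cfg$n_heads; dk <- d %/% nh
  nq <- nrow(cache$x_q); nk <- nrow(cache$x_kv)
  dconcat <- dout %*% t(pp$wo)
  dwo <- t(cache$concat) %*% dout
  dqp <- matrix(0, nq, d); dkp <- matrix(0, nk, d); dvp <- matrix(0, nk, d)
  db_rel <- if (cache$has_bias) {
    matrix(0, nh, 2 * cfg$max_relative_distance + 1)
  } else NULL
  for (h in seq_len(nh)) {
    idx <- ((h - 1) * dk + 1):(h * dk)
    w <- cache$weights[[h]]
    vph <- cache$vp[, idx, drop = FALSE]
    dch <- dconcat[, idx, drop = FALSE]
    if (!is.null(cache$masks[[h]])) {
      wd <- w * cache$masks[[h]]
      dwd <- dch %*% t(vph)
      dvp[, idx] <- t(wd) %*% dch
      dw <- dwd * cache$masks[[h]]
    } else {
      dw <- dch %*% t(vph)
      dvp[, idx] <- t(w) %*% dch
    }
    ds <- w * (dw - rowSums(dw * w))        # softmax backward, per row
    dlogit <- ds / sqrt(dk)
    dqp[, idx] <- dlogit %*% cache$kp[, idx, drop = FALSE]
    dkp[, idx] <- t(dlogit) %*% cache$qp[, idx, drop = FALSE]
    if (cache$has_bias) {
      mx <- cfg$max_relative_distance
      for (i in seq_len(nq)) {
        for (j in seq_len(nk)) {
          pos <- max(min(j - i, mx), -mx) + mx + 1
          db_rel[h, pos] <- db_rel[h, pos] + dlogit[i, j]
        }
      }
    }
  }
  list(dx_q = dqp %*% t(pp$wq),
       dx_kv = dkp %*% t(pp$wk) + dvp %*% t(pp$wv),
       grads = list(wq = t(cache$x_q) %*% dqp,
                    wk = t(cache$x_kv) %*% dkp,
                    wv = t(cache$x_kv) %*% dvp,
                    wo = dwo),
       db_rel = db_rel)
}

ffn_conv_bwd <- function(dz, cache, pp, dropout) {
  ## pointwise then depthwise convolution
  dy <- dz %*% t(pp$conv_pw)
  dconv_pw <- t(cache$y) %*% dz
  dconv_b <- colSums(dz)
  k <- nrow(pp$conv_dw); pad <- (k - 1) %/% 2
  tlen <- nrow(cache$g); d <- ncol(cache$g)
  gp <- rbind(matrix(0, pad, d), cache$g, matrix(0, pad, d))
  dconv_dw <- matrix(0, k, d)
  dgp <- matrix(0, tlen + 2 * pad, d)
  for (j in seq_len(k)) {
    rows <- (j - 1) + seq_len(tlen)
    dconv_dw[j, ] <- colSums(dy * gp[rows, , drop = FALSE])
    dgp[rows, ] <- dgp[rows, ] +
      dy * matrix(pp$conv_dw[j, ], tlen, d, byrow = TRUE)
  }
  dg <- dgp[pad + seq_len(tlen), , drop = FALSE]
  ## GLU gate
  da <- dg * cache$f * cache$s * (1 - cache$s)
  df <- dg * cache$s + da %*% t(pp$glu_w)
  dglu_w <- t(cache$f) %*% da
  dglu_b <- colSums(da)
  ## feedforward maps with GELU and dropout
  du2d <- df %*% t(pp$ffn_w2)
  dffn_w2 <- t(cache$u2d) %*% df
  dffn_b2 <- colSums(df)
  du2 <- if (!is.null(cache$mask)) du2d * cache$mask else du2d
  du1 <- du2 * gelu_grad(cache$u1)
  dh1 <- du1 %*% t(pp$ffn_w1)
  dffn_w1 <- t(cache$h1) %*% du1
  dffn_b1 <- colSums(du1)
  list(dh1 = dh1,
       grads = list(ffn_w1 = dffn_w1, ffn_b1 = dffn_b1,
                    ffn_w2 = dffn_w2, ffn_b2 = dffn_b2,
                    glu_w = dglu_w, glu_b = dglu_b,
                    conv_dw = dconv_dw, conv_pw = dconv_pw,
                    conv_b = dconv_b))
}

block_bwd <- function(dout, cache, pp, cfg, bias_table, dropout) {
  ln2 <- adaln_bwd(dout, cache$ln2, pp$ln2_g)
  dr2 <- ln2$dx
  ffn <- ffn_conv_bwd(dr2, cache$ffn, pp, dropout)
  dh1 <- dr2 + ffn$dh1
  ln1 <- adaln_bwd(dh1, cache$ln1, pp$ln1_g)
  dr1 <- ln1$dx
  att <- mha_bwd(dr1, cache$att, pp, cfg, bias_table, dropout)
  grads <- c(att$grads, ffn$grads,
             list(ln1_g = ln1$dgamma, ln1_b = ln1$dbeta,
                  ln2_g = ln2$dgamma, ln2_b = ln2$dbeta))
  list(dx_q = dr1 + att$dx_q, dx_kv = att$dx_kv, grads = grads,
       db_rel = att$db_rel)
}

#' Gradients of the loss with respect to all model parameters
#'
#' Backpropagates `dlogit` (the derivative of the loss at the pre-sigmoid
#' head output; for binary cross-entropy this is `prob - label`) through the
#' cached forward pass of [forward_predict()].
#'
#' @param cache Cache from `forward_predict(..., keep_cache = TRUE)`.
#' @param params,config As in [forward_predict()].
#' @param dlogit Scalar upstream gradient at the head logit.
#' @return Named list of gradient arrays matching `params`.
#' @export
backward_predict <- function(cache, params, config, dlogit) {
  grads <- lapply(params, function(p) array(0, dim = dim(p) %||% length(p)))
  for (nm in names(params)) {
    if (is.null(dim(params[[nm]]))) grads[[nm]] <- rep(0, length(params[[nm]]))
    else grads[[nm]] <- matrix(0, nrow(params[[nm]]), ncol(params[[nm]]))
  }
  ## head
  grads$head_w <- t(cache$dec_out) * dlogit
  grads$head_b <- dlogit
  ddq <- dlogit * t(params$head_w)
  denc_out <- matrix(0, nrow(cache$enc_out), ncol(cache$enc_out))
  for (l in rev(seq_len(config$n_decoder_layers))) {
    prefix <- paste0("dec", l)
    pp <- block_params(params, prefix)
    bk <- block_bwd(ddq, cache$dec[[l]], pp, config, NULL, config$dropout)
    for (k in names(bk$grads)) {
      grads[[paste0(prefix, "_", k)]] <- grads[[paste0(prefix, "_", k)]] +
        bk$grads[[k]]
    }
    denc_out <- denc_out + bk$dx_kv
    ddq <- bk$dx_q
  }
  grads$dec_query <- grads$dec_query + ddq
  dh <- denc_out
  for (l in rev(seq_len(config$n_encoder_layers))) {
    prefix <- paste0("enc", l)
    pp <- block_params(params, prefix)
    bk <- block_bwd(dh, cache$enc[[l]], pp, config, params$b_rel,
                    config$dropout)
    for (k in names(bk$grads)) {
      grads[[paste0(prefix, "_", k)]] <- grads[[paste0(prefix, "_", k)]] +
        bk$grads[[k]]
    }
    if (!is.null(bk$db_rel)) grads$b_rel <- grads$b_rel + bk$db_rel
    dh <- bk$dx_q + bk$dx_kv  # self-attention: query and key/value coincide
  }
  ## embedding
  tlen <- nrow(cache$x)
  grads$pe[seq_len(tlen), ] <- grads$pe[seq_len(tlen), , drop = FALSE] + dh
  grads$w_in <- unname(grads$w_in + t(cache$x) %*% dh)
  grads$b_in <- grads$b_in + colSums(dh)
  grads
}
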