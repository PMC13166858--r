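#' Numerically stable row-wise softmax
#'
#' @param x A numeric matrix; softmax is taken over each row.
#' @return A matrix of the same shape with non-negative rows summing to 1.
#' @export
softmax_rows <- function(x) {
  x <- x - apply(x, 1, max)
  e <- exp(x)
  e / rowSums(e)
}

#' Gaussian error linear unit
#'
#' Exact formulation `x * pnorm(x)`.
#'
#' @param x Numeric vector or matrix.
#' @return Same shape as `x`.
#' @export
gelu <- function(x) x * pnorm(x)

gelu_grad <- function(x) pnorm(x) + x * dnorm(x)

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Embed a feature sequence with a learnable positional table
#'
#' `hidden[pos, ] = x[pos, ] %*% w + b + pe[pos, ]`: a linear projection of
#' the per-wave feature vector plus the learnable (dynamic) positional
#' embedding for that position.
#'
#' @param x Sequence matrix (positions x features).
#' @param w Projection matrix (features x d_model).
#' @param b Bias vector (length d_model).
#' @param pe Positional table (max_len x d_model).
#' @return Hidden sequence (positions x d_model).
#' @export
embed_sequence <- function(x, w, b, pe) {
  if (nrow(x) > nrow(pe)) {
    abort(sprintf("Sequence length %d exceeds the positional table (%d).",
                  nrow(x), nrow(pe)))
  }
  h <- x %*% w
  sweep(h, 2, b, "+") + pe[seq_len(nrow(x)), , drop = FALSE]
}

#' Scaled dot-product attention with an additive relative positional bias
#'
#' `softmax((Q K' + B) / sqrt(d_k)) V`.  Rows of the weight matrix are
#' non-negative and sum to 1.
#'
#' @param q,k,v Query, key and value matrices (`n_q x d_k`, `n_k x d_k`,
#'   `n_k x d_v`).
#' @param b Additive logit bias matrix (`n_q x n_k`), or `NULL` for none.
#' @param d_k Key dimensionality used in the `1/sqrt(d_k)` scaling.
#' @return A list with `context` (`n_q x d_v`) and `weights` (`n_q x n_k`).
#' @export
#' @examples
#' out <- relative_attention(matrix(1), matrix(c(1, 0), 2), matrix(c(1, 0), 2),
#'                           d_k = 1)
#' out$weights  # exp(1)/(exp(1)+1), 1/(exp(1)+1)
relative_attention <- function(q, k, v, b = NULL, d_k = ncol(q)) {
  if (d_k <= 0) abort("`d_k` must be positive.")
  s <- q %*% t(k)
  if (!is.null(b)) s <- s + b
  w <- softmax_rows(s / sqrt(d_k))
  list(context = w %*% v, weights = w)
}

## bias matrix for query positions qpos and key positions kpos from one
## head's learnable table over clipped relative distances
rel_bias_matrix <- function(table_row, qpos, kpos, max_rel) {
  d <- outer(kpos, qpos, function(k, q) k - q)   # distance j - i, kpos x qpos
  d <- pmax(pmin(d, max_rel), -max_rel)
  matrix(table_row[t(d) + max_rel + 1], nrow = length(qpos))
}

#' Multi-head attention with relative positional bias
#'
#' Projects queries, keys and values into `n_heads` subspaces, runs
#' [relative_attention()] per head with that head's learnable bias over
#' clipped relative distances, concatenates the head contexts and mixes them
#' with the output matrix.
#'
#' @param q,k,v Input matrices (`n_q x d_model`, `n_k x d_model`).
#' @param params List with `wq`, `wk`, `wv`, `wo` (`d_model x d_model`) and
#'   optionally `bias` (`n_heads x (2 * max_rel + 1)` table; `NULL` for no
#'   positional bias, e.g. cross-attention from a position-free query).
#' @param n_heads Number of heads; `d_model` must be divisible by it.
#' @param max_rel Clipping range of the relative distance.
#' @param qpos,kpos Integer positions of the query/key tokens (defaults
#'   `1:n_q`, `1:n_k`).
#' @return A list with `output` (`n_q x d_model`), per-head `weights`, and
#'   internals used by the training backward pass.
#' @export
multi_head <- function(q, k, v, params, n_heads, max_rel = 8,
                       qpos = seq_len(nrow(q)), kpos = seq_len(nrow(k))) {
  d <- ncol(q)
  if (d %% n_heads != 0) abort("`d_model` must be divisible by `n_heads`.")
  dk <- d %/% n_heads
  qp <- q %*% params$wq
  kp <- k %*% params$wk
  vp <- v %*% params$wv
  heads <- vector("list", n_heads)
  weights <- vector("list", n_heads)
  for (h in seq_len(n_heads)) {
    idx <- ((h - 1) * dk + 1):(h * dk)
    bmat <- if (!is.null(params$bias)) {
      rel_bias_matrix(params$bias[h, ], qpos, kpos, max_rel)
    } else NULL
    att <- relative_attention(qp[, idx, drop = FALSE],
                              kp[, idx, drop = FALSE],
                              vp[, idx, drop = FALSE], bmat, dk)
    heads[[h]] <- att$context
    weights[[h]] <- att$weights
  }
  concat <- do.call(cbind, heads)
  list(output = concat %*% params$wo, weights = weights,
       qp = qp, kp = kp, vp = vp, concat = concat)
}

#' Gated linear unit
#'
#' `GLU(x) = x * sigmoid(W x + b)` elementwise: one path carries the raw
#' features, the other produces sigmoid weighting coefficients that select
#' feature dimensions adaptively.
#'
#' @param x Input matrix (tokens x d).
#' @param w Gate weight matrix (d x d).
#' @param b Gate bias (length d).
#' @return Gated matrix, same shape as `x`.
#' @export
#' @examples
#' glu_gate(matrix(1), matrix(0), 0)  # 0.5
glu_gate <- function(x, w, b) {
  x * sigmoid(sweep(x %*% w, 2, b, "+"))
}

#' Depthwise-separable convolution over the sequence axis
#'
#' A depthwise convolution filters each channel independently along the
#' (zero-padded, same-length) sequence axis; a pointwise 1x1 convolution
#' then mixes channels.
#'
#' @param x Input sequence (tokens x channels).
#' @param depthwise Kernel matrix (kernel_size x channels), one column per
#'   channel; kernel size must be odd.
#' @param pointwise Channel-mixing matrix (channels x channels).
#' @param bias Output bias (length channels); default zeros.
#' @return Filtered sequence, same shape as `x`.
#' @export
ds_conv <- function(x, depthwise, pointwise, bias = rep(0, ncol(x))) {
  k <- nrow(depthwise)
  if (k %% 2 != 1) abort("Depthwise kernel size must be odd.")
  y <- depthwise_conv(x, depthwise)
  sweep(y %*% pointwise, 2, bias, "+")
}

depthwise_conv <- function(x, depthwise) {
  k <- nrow(depthwise)
  pad <- (k - 1) %/% 2
  tlen <- nrow(x)
  xp <- rbind(matrix(0, pad, ncol(x)), x, matrix(0, pad, ncol(x)))
  y <- matrix(0, tlen, ncol(x))
  for (j in seq_len(k)) {
    y <- y + xp[(j - 1) + seq_len(tlen), , drop = FALSE] *
      matrix(depthwise[j, ], tlen, ncol(x), byrow = TRUE)
  }
  y
}

#' Adaptive layer normalisation
#'
#' Standard per-token layer normalisation (mean and population variance over
#' the feature axis, epsilon for stability) followed by a learnable scale
#' `gamma` and shift `beta`: `AdaLN(x) = gamma * LayerNorm(x) + beta`.  With
#' `gamma = 1`, `beta = 0` this reduces to plain layer normalisation.
#'
#' @param x Input matrix (tokens x d).
#' @param gamma,beta Learnable scale and shift vectors (length d).
#' @param eps Stability constant (default 1e-12).
#' @return Normalised matrix, same shape as `x`.
#' @export
#' @examples
#' ada_layer_norm(matrix(c(1, 3), 1), gamma = c(1, 1), beta = c(0, 0))  # -1 1
ada_layer_norm <- function(x, gamma, beta, eps = 1e-12) {
  adaln_fwd(x, gamma, beta, eps)$out
}

adaln_fwd <- function(x, gamma, beta, eps) {
  mu <- rowMeans(x)
  xc <- x - mu
  v <- rowMeans(xc^2)            # population variance
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  out <- sweep(xhat * matrix(gamma, nrow(x), ncol(x), byrow = TRUE),
               2, beta, "+")
  list(out = out, xhat = xhat, inv = inv)
}

adaln_bwd <- function(dout, cache, gamma) {
  xhat <- cache$xhat
  dgamma <- colSums(dout * xhat)
  dbeta <- colSums(dout)
  dxhat <- dout * matrix(gamma, nrow(dout), ncol(dout), byrow = TRUE)
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * xhat)
  dx <- (dxhat - m1 - xhat * m2) * cache$inv
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}
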