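test_that("embedding is projection plus positional rows", {
  pe <- matrix(rnorm(8), 4, 2)
  x <- matrix(0, 2, 3)
  w0 <- matrix(0, 3, 2)
  ## zero features and projection: hidden equals the positional rows alone
  expect_equal(embed_sequence(x, w0, c(0, 0), pe), pe[1:2, ])
  ## zero positional table: embedding equals the projection output
  x2 <- matrix(rnorm(6), 2, 3)
  w <- matrix(rnorm(6), 3, 2)
  expect_equal(embed_sequence(x2, w, c(0, 0), pe * 0), x2 %*% w)
  ## permuting positions changes the output when positional rows differ
  h12 <- embed_sequence(x2, w, c(0, 0), pe)
  h21 <- embed_sequence(x2[2:1, ], w, c(0, 0), pe)
  expect_false(isTRUE(all.equal(h12, h21[2:1, ])))
  expect_error(embed_sequence(matrix(0, 5, 3), w, c(0, 0), pe), "exceeds")
})

test_that("attention weights are a proper softmax of biased scaled scores", {
  ## equal logits, no bias: uniform weights, output = mean of values
  q <- matrix(0, 1, 2)
  k <- matrix(0, 2, 2)
  v <- matrix(c(1, 3), 2, 1)
  out <- relative_attention(q, k, v, d_k = 2)
  expect_equal(as.numeric(out$weights), c(0.5, 0.5))
  expect_equal(as.numeric(out$context), 2)
  ## hand-computed softmax at d_k = 1
  out2 <- relative_attention(matrix(1), matrix(c(1, 0), 2, 1),
                             matrix(c(1, 0), 2, 1), d_k = 1)
  expect_equal(as.numeric(out2$weights),
               c(exp(1) / (exp(1) + 1), 1 / (exp(1) + 1)),
               tolerance = 1e-10)
  expect_equal(as.numeric(out2$context), 0.7311, tolerance = 1e-4)
  ## shift invariance: adding a constant to every logit changes nothing
  b <- matrix(5, 1, 2)
  out3 <- relative_attention(matrix(1), matrix(c(1, 0), 2, 1),
                             matrix(c(1, 0), 2, 1), b = b, d_k = 1)
  expect_equal(out3$weights, out2$weights)
  expect_error(relative_attention(q, k, v, d_k = 0), "positive")
})

test_that("attention weight rows always sum to one", {
  withr::with_seed(14, {
    for (i in 1:20) {
      nq <- sample(1:5, 1); nk <- sample(1:5, 1); dk <- sample(1:4, 1)
      out <- relative_attention(matrix(rnorm(nq * dk), nq),
                                matrix(rnorm(nk * dk), nk),
                                matrix(rnorm(nk * 2), nk),
                                b = matrix(rnorm(nq * nk), nq), d_k = dk)
      expect_true(all(out$weights >= 0))
      expect_equal(rowSums(out$weights), rep(1, nq), tolerance = 1e-6)
    }
  })
})

test_that("multi-head attention equals a per-head loop oracle", {
  withr::with_seed(5, {
    for (i in 1:20) {
      nh <- sample(c(1, 2, 4), 1)
      dk <- sample(1:3, 1)
      d <- nh * dk
      tlen <- sample(2:4, 1)
      q <- matrix(rnorm(tlen * d), tlen)
      params <- list(wq = matrix(rnorm(d * d), d), wk = matrix(rnorm(d * d), d),
                     wv = matrix(rnorm(d * d), d), wo = matrix(rnorm(d * d), d),
                     bias = matrix(rnorm(nh * 5), nh))
      got <- multi_head(q, q, q, params, nh, max_rel = 2)
      ## oracle: explicit loop over heads, concatenate, then mix
      qp <- q %*% params$wq; kp <- q %*% params$wk; vp <- q %*% params$wv
      heads <- lapply(seq_len(nh), function(h) {
        idx <- ((h - 1) * dk + 1):(h * dk)
        bmat <- matrix(0, tlen, tlen)
        for (a in seq_len(tlen)) for (b in seq_len(tlen)) {
          bmat[a, b] <- params$bias[h, max(min(b - a, 2), -2) + 3]
        }
        s <- (qp[, idx, drop = FALSE] %*% t(kp[, idx, drop = FALSE]) + bmat) /
          sqrt(dk)
        e <- exp(s - apply(s, 1, max))
        (e / rowSums(e)) %*% vp[, idx, drop = FALSE]
      })
      expect_equal(got$output, do.call(cbind, heads) %*% params$wo,
                   tolerance = 1e-6)
    }
  })
})

test_that("single-head attention degenerates to relative_attention + output mix", {
  withr::with_seed(6, {
    d <- 4
    q <- matrix(rnorm(3 * d), 3)
    params <- list(wq = diag(d), wk = diag(d), wv = diag(d),
                   wo = matrix(rnorm(d * d), d), bias = NULL)
    got <- multi_head(q, q, q, params, n_heads = 1)
    ref <- relative_attention(q, q, q, d_k = d)$context %*% params$wo
    expect_equal(got$output, ref, tolerance = 1e-10)
    ## zero value projections give zero output
    params$wv <- matrix(0, d, d)
    expect_equal(multi_head(q, q, q, params, 1)$output, matrix(0, 3, d))
  })
})

test_that("the GLU gate is x times sigmoid of its linear map", {
  expect_equal(glu_gate(matrix(1), matrix(0), 0), matrix(0.5))
  expect_equal(as.numeric(glu_gate(matrix(1), matrix(1), 0)),
               plogis(1), tolerance = 1e-10)
  expect_equal(as.numeric(glu_gate(matrix(1), matrix(1), 0)), 0.7311,
               tolerance = 1e-4)
  ## saturated-open gate passes the input through
  x <- matrix(rnorm(6), 2, 3)
  expect_equal(glu_gate(x, matrix(0, 3, 3), rep(100, 3)), x, tolerance = 1e-8)
})

test_that("depthwise-separable convolution honours identity, padding and an oracle", {
  x <- matrix(rnorm(8), 4, 2)
  ident_dw <- matrix(c(0, 1, 0), 3, 2)
  expect_equal(ds_conv(x, ident_dw, diag(2)), x)
  ## length-1 sequence: only the centre tap survives zero padding
  x1 <- matrix(c(2, -1), 1, 2)
  dw <- matrix(rnorm(6), 3, 2)
  expect_equal(ds_conv(x1, dw, diag(2)), x1 * dw[2, , drop = FALSE])
  expect_error(ds_conv(x, matrix(0, 2, 2), diag(2)), "odd")
  ## brute-force nested-loop oracle
  withr::with_seed(9, {
    for (i in 1:10) {
      tlen <- sample(1:5, 1); d <- sample(1:3, 1); k <- 3
      x <- matrix(rnorm(tlen * d), tlen)
      dw <- matrix(rnorm(k * d), k)
      pw <- matrix(rnorm(d * d), d)
      b <- rnorm(d)
      got <- ds_conv(x, dw, pw, b)
      ref_dw <- matrix(0, tlen, d)
      for (t in seq_len(tlen)) for (c in seq_len(d)) for (j in seq_len(k)) {
        src <- t + j - 2
        if (src >= 1 && src <= tlen) {
          ref_dw[t, c] <- ref_dw[t, c] + dw[j, c] * x[src, c]
        }
      }
      ref <- ref_dw %*% pw
      for (c in seq_len(d)) ref[, c] <- ref[, c] + b[c]
      expect_equal(got, ref, tolerance = 1e-10)
    }
  })
})

test_that("adaptive layer norm standardises then scales and shifts", {
  ## hand-computed: mean 2, population SD 1
  expect_equal(ada_layer_norm(matrix(c(1, 3), 1), c(1, 1), c(0, 0)),
               matrix(c(-1, 1), 1))
  ## constant input with zero shift collapses to zero
  expect_equal(ada_layer_norm(matrix(5, 1, 4), rep(2, 4), rep(0, 4)),
               matrix(0, 1, 4))
  ## gamma = 1, beta = 0 is plain layer normalisation
  x <- matrix(rnorm(12), 3, 4)
  plain <- t(apply(x, 1, function(r) (r - mean(r)) /
                     sqrt(mean((r - mean(r))^2) + 1e-12)))
  expect_equal(ada_layer_norm(x, rep(1, 4), rep(0, 4)), plain,
               tolerance = 1e-8)
  ## gamma and beta act per dimension
  g <- c(2, 1, 1, 1); b <- c(0, 3, 0, 0)
  scaled <- sweep(plain * matrix(g, 3, 4, byrow = TRUE), 2, b, "+")
  expect_equal(ada_layer_norm(x, g, b), scaled, tolerance = 1e-8)
})
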