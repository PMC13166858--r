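## Shared fixtures: small simulated cohorts and ready-made window sets.

tiny_model_config <- function(...) {
  defaults <- list(d_model = 8, n_heads = 2, n_encoder_layers = 1,
                   n_decoder_layers = 1, d_ffn = 16, dropout = 0,
                   conv_kernel = 3, max_relative_distance = 2, max_len = 4)
  do.call(model_config, utils::modifyList(defaults, list(...)))
}

make_windows <- function(n_participants = 120, effect_size = 2.5, seed = 7,
                         missing_rate = 0) {
  cohort <- simulate_cohort(cohort_config(
    n_participants = n_participants, effect_size = effect_size,
    missing_rate = missing_rate, seed = seed))
  enc <- suppressWarnings(encode_cohort(score_cohort(cohort)))
  feats <- screen_features(compute_feature_meta(enc, feature_declarations(enc)))
  if (missing_rate > 0) {
    enc <- impute_mi_mean(enc, m = 3, iters = 3, seed = seed + 1, cols = feats)
  }
  build_windows(enc, feats)
}

## straight-line independent re-implementation of the AdamW recursions,
## used as the oracle for adamw_step
adamw_oracle <- function(theta, gs, alpha = 3e-4, beta1 = 0.9, beta2 = 0.999,
                        lambda = 0.01, eps = 1e-8) {
  m <- 0; v <- 0
  for (t in seq_along(gs)) {
    g <- gs[[t]]
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    m_hat <- m / (1 - beta1^t)
    v_hat <- v / (1 - beta2^t)
    theta <- theta - alpha * m_hat / (sqrt(v_hat) + eps) - lambda * theta
  }
  theta
}

## pairwise-concordance AUC oracle (Mann-Whitney with tie correction)
auc_concordance <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}
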