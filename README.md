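# mcirisk

Dynamic prediction of mild cognitive impairment (MCI) risk in older adults
with depressive symptoms, from longitudinal panel data.

Depression in later life is a strong, modifiable precursor of cognitive
decline, but most risk models score a single visit and ignore how symptoms
*move*. `mcirisk` implements an end-to-end dynamic pipeline for wave-indexed
cohort tables (one row per participant per wave, as collected by large
ageing surveys) and is aimed at biostatisticians and epidemiologists who
want a fully inspectable, dependency-light reference implementation:

* **Instrument scoring** — CESD-10 (ten items scored 0–3, total 0–30,
  depressive symptoms at total ≥ 10) and a 0–31 cognitive composite
  (immediate + delayed 10-word recall 0–20; orientation 0–5, serial
  subtraction 0–5, pentagon copy 0–1).
* **Age-normed MCI labels** — within 5-year age strata from 60 (85+ open),
  MCI ⇔ composite < stratum mean − 1 SD (sample SD, strict inequality).
* **Feature pipeline** — four-rule screening (outcome-derived /
  inconsistent measurement / missing rate > 20% / composite overlap),
  multiple-imputation-based mean completion, sliding (wave *t* → *t*+1)
  window construction restricted to participants depressed and not yet
  MCI at wave *t*, and participant-disjoint stratified splits.
* **A transformer risk classifier, written from scratch** — learnable
  positional embeddings, multi-head attention with logits
  softmax((QKᵀ + B)/√d_k) where B is a learnable relative-position bias,
  GLU-gated feedforward blocks (GLU(x) = x ⊙ σ(Wx + b)) with GELU,
  depthwise-separable convolutions, adaptive layer norm
  AdaLN(x) = γ·LayerNorm(x) + β (ε = 1e−12), residual wiring
  AdaLN(x + Sublayer(x)), a single-query generative decoder and a sigmoid
  risk head. Training uses hand-derived backpropagation, AdamW in the form
  θ_t = θ_{t−1} − α·m̂/(√v̂+ε) − λθ_{t−1} (α = 3e−4, β₁ = 0.9, β₂ = 0.999,
  λ = 0.01 defaults), 4-batch gradient accumulation, dropout and early
  stopping.
* **Evaluation and comparison** — accuracy, sensitivity, precision,
  specificity, F1 and trapezoidal AUC, XGBoost and radial-SVM baselines on
  identical splits, exhaustive grid tuning, and a feature × embedding
  attention-attribution heatmap.
* **A seeded synthetic cohort generator** — CHARLS-schema panels with a
  planted depression→MCI temporal effect (latent AR(1) severity; cognition
  declining faster under depressive worsening), so the whole pipeline runs
  and is testable without any restricted data.

## Worked example

```r
library(mcirisk)

cohort  <- simulate_cohort(cohort_config(n_participants = 2000, seed = 11))
prep    <- prepare_cohort_windows(cohort, seed = 12)   # score, screen, impute, window
splits  <- split_dataset(prep$windows, seed = 13)

fit <- fit_mci_transformer(
  splits$train, splits$validation,
  model_config(d_model = 64, n_heads = 8, d_ffn = 256,
               max_relative_distance = 2, max_len = 4),
  train_config(batch_size = 8, alpha = 1e-3, weight_decay = 1e-5,
               max_epochs = 12, patience = 3, seed = 14))

test <- predict(fit, splits$test)
compute_metrics(test$label, test$prob)
run_baselines(splits, seed = 14)[, c("model", "split", "auc")]
```

On this synthetic cohort (2,459 windows from 2,000 participants, 15.7%
next-wave MCI incidence among the depressed-and-unimpaired) a run of this
experiment prints test-split metrics of

```
accuracy 0.883   auc 0.836   (n = 376)
```

for the transformer, against test AUCs of 0.730 (XGBoost) and 0.832 (SVM);
on a second, independently simulated 2,500-window held-out cohort the
transformer's AUC is 0.797. With the planted effect switched off
(`effect_size = 0`) the same pipeline lands at AUC 0.487 — chance, as it
should. Numbers move slightly with the seed; interpretation: the model
recovers the planted temporal association between depressive worsening and
next-wave impairment, and the no-signal control confirms the pipeline
manufactures no spurious signal.

`autoplot(fit)` shows the training trajectory,
`autoplot(export_attention_heatmap(fit, splits$test))` the
attention-weighted input attribution map, and `tidy(fit)` / `glance(fit)`
give broom-style summaries.

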