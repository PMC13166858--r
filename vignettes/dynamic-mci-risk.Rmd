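---
title: "Dynamic MCI risk prediction from depressive symptom trajectories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic MCI risk prediction from depressive symptom trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mcirisk)
library(dplyr)
```

## The problem

Older adults with depressive symptoms are at markedly elevated risk of mild
cognitive impairment (MCI), and the *trajectory* of depressive symptoms --
not just their level at one visit -- carries predictive information about
who will convert.  `mcirisk` implements a complete dynamic-risk pipeline for
longitudinal panel data of the kind collected by large ageing surveys (waves
roughly two years apart, item-level depression scales, brief cognitive
batteries):

1. **Instrument scoring.** The 10-item CES-D short form (items 0--3, total
   0--30) with the conventional cutoff: a total $\ge 10$ classifies a
   participant as having depressive symptoms.  Cognition is a 0--31
   composite of episodic memory (immediate + delayed 10-word recall,
   0--20) and global mental status (temporal orientation 0--5, serial
   subtraction 0--5, pentagon copy 0--1).
2. **Age-normed MCI labelling.** Within 5-year age strata from 60 (85+
   open-ended), a record is labelled MCI when its cognitive composite falls
   strictly below the stratum mean minus one sample standard deviation.
   This norm-referenced rule avoids the subjective-report components of
   clinic-style criteria.
3. **Screening, imputation, windowing.** Features are screened by four
   declarative rules (outcome-derived, inconsistent measurement, missing
   rate > 20%, composite overlap), residual missingness is completed by a
   multiple-imputation-based mean, and the panel is cut into sliding
   (wave $t$ → wave $t{+}1$) windows: a window exists where the participant
   is depressed and *not* MCI at wave $t$, and its label is the MCI status
   at wave $t{+}1$.
4. **A transformer risk model** over the two-wave feature sequence, trained
   with AdamW, gradient accumulation and early stopping, evaluated with a
   six-metric suite, and compared against XGBoost and SVM baselines.

Because the motivating surveys are access-restricted, the package ships a
seeded synthetic cohort generator that emulates their schema and plants a
known depression→MCI temporal effect, so every stage is runnable and
testable offline.

## The synthetic cohort generator

`simulate_cohort()` draws, per participant:

* a latent **depressive severity** $s_t = \mu_i + z_t$, where
  $\mu_i = \pm 1.2$ splits the cohort into a symptomatic and a normal group
  (`depressed_fraction`, default 0.5) and $z_t$ is a stationary AR(1)
  deviation with persistence $\rho = 0.7$ and unit variance;
* a latent **cognition** $c_t = c_{t-1} - 0.15 -
  \texttt{effect\_size} \cdot \max(0, s_t - s_{t-1}) + \varepsilon_t$,
  $\varepsilon_t \sim N(0, 0.3^2)$ -- everyone drifts down slowly, and
  decline steepens when depressive severity worsens.  This is the planted
  signal: persistent depressive deterioration coupled to accelerating
  cognitive decline.

CESD-10 items are emitted from $s_t$ by a graded-response map (thresholds
$-0.5, 0.5, 1.5$ with logistic noise of scale 0.3).  The thresholds were
chosen so that the *expected* item total is about 10 when $s_t = 0$: the
conventional CESD-10 cutoff then coincides with the latent group boundary,
and at `depressed_fraction = 0.5` the observed prevalence of scores
$\ge 10$ matches the configured fraction.  Cognitive subtasks are linear
maps of $c_t$ rounded and clipped to their instrument ranges; demographics
follow configurable marginals whose defaults resemble a rural-majority,
low-formal-education ageing cohort.  Auxiliary covariates (default 6) are
missing completely at random at `missing_rate` (default 0.1); scale items
are always complete, mirroring the fact that imputation targets screened
covariates rather than outcome instruments.

The default `effect_size = 2.5` (in latent-cognition SD units per unit of
positive severity change) plants a strong, recoverable association: a
logistic-regression oracle on the flattened two-wave features reaches a
test AUC of about 0.80 at 2,000 participants.  What the generator does
*not* emulate: informative attrition (the optional `dropout_rate` is
uninformative), survey weights, measurement-tool changes across waves, and
item-level missingness in the scales.  Tests that pass on this generator
therefore certify the pipeline's mechanics and the model's ability to
recover a planted temporal effect -- not clinical performance on real
cohort data.

## The model

One token per wave.  Each per-wave feature vector is linearly projected to
`d_model` dimensions and a *learnable positional embedding* is added
(dynamic positional encoding).  Encoder blocks apply, in residually wrapped
sublayers `AdaLN(x + Sublayer(x))`:

1. multi-head self-attention with a learnable **relative positional bias**:
   per head, logits are $(QK^\top + B)/\sqrt{d_k}$ where $B$ is indexed by
   the clipped signed distance between positions (range
   `max_relative_distance`, table shared across layers);
2. a feedforward block: two linear maps with GELU between them, a **GLU
   gate** ($u \odot \sigma(Wu + b)$) that adaptively selects feature
   dimensions, then a **depthwise-separable convolution** along the
   sequence axis (depthwise kernel per channel, pointwise 1×1 mixing).

`AdaLN` is layer normalisation (per-token mean and population variance,
$\epsilon = 10^{-12}$) followed by learnable scale $\gamma$ and shift
$\beta$; with unconditioned $\gamma, \beta$ this is the standard affine
layer norm, and a conditioning hook would slot in where $\gamma, \beta$ are
read.  The decoder is a single learned query token cross-attending over the
encoder output (no positional bias: the query carries no position),
followed by the same feedforward sublayer and a linear + sigmoid risk head.
This is the minimal generative decoder consistent with a binary next-wave
outcome.  The reference configuration is `d_model = 512` with 8 heads;
the experiments in this vignette and in the test suite use `d_model = 64`
(8 heads, `d_ffn = 256`), which trains in minutes on one CPU core and is
ample for ~25 input features.

Dropout (default 0.1) is applied to attention weights and feedforward
activations during training only.  All gradients are hand-derived
reverse-mode matrix calculus, verified in the test suite against central
finite differences to $10^{-4}$ relative error.

## Training and optimisation

The loss is binary cross-entropy.  Its printed form is a sum over samples;
the trainer uses the mean-reduced variant so that averaging gradients over
`accumulation` equal mini-batches (default 4) before each optimizer step is
*exactly* one step on the pooled batch -- the equivalence is asserted to
$10^{-6}$ in the tests.

The optimizer is AdamW with the decoupled decay written directly as
$\theta_t = \theta_{t-1} - \alpha\,\hat m_t/(\sqrt{\hat v_t}+\epsilon)
- \lambda\,\theta_{t-1}$: note that $\lambda$ multiplies the previous
parameters *without* the learning rate.  Under this parameterisation the
stated constants ($\alpha = 3\times 10^{-4}$, $\beta_1 = 0.9$,
$\beta_2 = 0.999$, $\lambda = 0.01$, $\epsilon = 10^{-8}$) make each step
shrink every weight by 1%, which dominates learning in small-data regimes
where an epoch contains tens of steps: in our experiments validation AUC
peaked near 0.62 and then decayed as the weights collapsed.  These
constants remain the `adamw_step()`/`train_config()` defaults; the
experiments below follow the method's own prescription of calibrating
learning rate, weight decay and batch size (see `tune_grid()`) and use
batch size 8, $\alpha = 10^{-3}$, $\lambda = 10^{-5}$, under which the
planted signal is recovered comfortably.

Two further numerical choices matter.  Positional embeddings are
initialised at SD 0.3: at two-wave sequence length the tokens are otherwise
nearly indistinguishable at initialisation and optimisation stalls on the
order-invariant "average severity" solution (~0.63 AUC) instead of learning
the wave-to-wave *change* that drives the outcome.  Probabilities are
clamped at $10^{-12}$ inside the loss; degenerate strata (fewer than two
members) are labelled normal with a warning rather than erroring.

Early stopping monitors validation AUC (patience in epochs; `patience = 0`
stops at the first non-improving epoch) and restores the best checkpoint.
Initialisation, shuffling and dropout all derive from `train_config(seed)`,
so runs reproduce exactly.

## Design choices made where the design was open

* **Tokenisation.** One token per wave (the inputs are per-wave feature
  vectors); a feature-as-token mode is out of scope.  The
  feature-by-embedding-dimension heatmap of `export_attention_heatmap()` is
  served by a constructive attribution: input-projection weight magnitudes
  modulated by decoder attention mass and mean absolute feature values.  It
  is an interpretation aid, not a quantity the model optimises.
* **Relative bias parameterisation.** A per-head learnable table over
  clipped signed distances, shared across layers.
* **Window span.** Exactly the two waves of the window; windows are
  pairwise and disjoint.
* **Splitting.** By participant (all of a person's windows stay in one
  split), stratified on the participant-level outcome, with
  largest-remainder allocation: split sizes track the requested fractions
  to within one participant.  Proportions default to 70/15/15.
* **Screening semantics.** The four rules operate on *declared* metadata
  flags; which real-survey variables are outcome-derived or composite is a
  property of the source data dictionary, not reconstructible here.
  The missing-rate rule excludes strictly above 20%.
* **Imputation.** Chained per-feature linear regressions (5 cycles),
  stochastic residual draws, `m = 5` completions averaged into a
  conservative mean.  Observed cells are never modified.
* **Scoring conventions.** No reverse-coding of the two positively worded
  CESD-10 items by default (a `reverse_positive` switch exists); sample SD
  (n−1) and a strict `<` in the mean−1SD MCI rule; decision threshold 0.5
  for confusion-based metrics.
* **Hyperparameter search.** `tune_grid()` is exhaustive over its grid with
  ties broken by F1 then smaller learning rate; a Bayesian proposal step
  can be plugged in through `extra_configs` but is not part of the core.

## A complete run

```{r pipeline, eval = FALSE}
cohort <- simulate_cohort(cohort_config(n_participants = 2000, seed = 11))
scored <- encode_cohort(score_cohort(cohort))
meta   <- compute_feature_meta(scored, feature_declarations(scored))
feats  <- screen_features(meta)
scored <- impute_mi_mean(scored, seed = 12, cols = feats)
windows <- build_windows(scored, feats)
splits  <- split_dataset(windows, seed = 13)

fit <- fit_mci_transformer(
  splits$train, splits$validation,
  model_config(d_model = 64, n_heads = 8, d_ffn = 256,
               max_relative_distance = 2, max_len = 4),
  train_config(batch_size = 8, alpha = 1e-3, weight_decay = 1e-5,
               max_epochs = 12, patience = 3, seed = 14))

test_pred <- predict(fit, splits$test)
compute_metrics(test_pred$label, test_pred$prob)
run_baselines(splits, seed = 14)
autoplot(export_attention_heatmap(fit, splits$test))
```

At these problem sizes (about 2,500 windows from 2,000 participants; the
model above has ~180k parameters) the full pipeline runs in roughly ten
minutes on one CPU core; the same experiment, plus a no-signal
(`effect_size = 0`) control whose AUC should sit at chance, is what
`scripts/acceptance.R` re-runs end to end.  Evaluation there uses both the
internal test split and an independently simulated held-out cohort (same
configuration, different seed) -- the held-out cohort gives a much larger
evaluation set and correspondingly tighter AUC estimates.

## Known limitations

* The synthetic generator's realism claims are limited to marginals and the
  planted mechanism; no attempt is made to reproduce real exclusion-flow
  counts, sampling weights, or attrition structure.
* The MCI label is norm-referenced within the analysed sample, so labels
  depend (weakly, at these n) on cohort composition.
* With two-wave windows the architecture's long-range machinery (relative
  bias clipping, positional tables beyond length 2) is exercised but not
  stressed; the implementation supports longer sequences up to `max_len`.
* Training is plain R matrix code: comfortable at `d_model` 64 and a few
  thousand windows, slow at the reference width of 512.
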