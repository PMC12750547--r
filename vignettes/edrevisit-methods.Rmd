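---
title: "Methods: hybrid static-dynamic modelling of ED revisit risk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hybrid static-dynamic modelling of ED revisit risk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(edrevisit)
```

## The problem

Roughly 5-10% of emergency department (ED) patients return within 72
hours of discharge, and a small fraction of those returns are
catastrophic (ICU admission, cardiac arrest, emergency surgery).
`edrevisit` implements a prediction pipeline for both outcomes from the
two kinds of data a triage-to-discharge encounter produces:

* **static features** — 19 tabular triage variables (5 numeric, 14
  categorical) recorded once per visit;
* **dynamic features** — six vital signs (HR, SBP, DBP, SpO2, BT, RR)
  measured manually at irregular 3-4 hour intervals over stays whose
  median length is about two hours.

The combination of extreme class imbalance (about 4.42% general revisit,
about 0.11% high-risk), very short irregular series, and mixed data
types drives every design choice below.

## Preprocessing

**Outlier removal.** Manually entered values outside fixed physiological
ranges are nulled (not clipped): HR/SBP/DBP in [0, 300), RR in [0, 50),
BT in [0, 50), SpO2 in [0, 100] — the saturation bound is attainable,
hence inclusive. Only the dynamic channel is cleaned; implausible static
values are reported (`flag_static_anomalies()`) but never modified,
since no cleaning rule for them is part of the modelled procedure.

**Hourly division.** Measurements are averaged within one-hour bins.
Bins are anchored to discharge — bin *k* covers [-(k+1) h, -k h) — not
to clock hours: the whole pipeline is discharge-anchored, and anchoring
to the clock would make the final (most informative) bin cover a
variable fraction of an hour.

**Fixed length and λ.** Each grid is aligned to 24 steps before
discharge: shorter stays are padded on the *leading* (oldest) side so
real data always abut discharge; longer stays keep the most recent 24
hours. The unpadded valid length λ = min(24, span) is carried with the
sequence. λ is capped at 24 because the model never sees the truncated
history.

**Imputation.** Within the valid region each channel is forward-filled,
then leading gaps are backward-filled. Learned imputers are deliberately
avoided: with a median of two valid hours there is nothing for them to
learn from, and they can distort the very trends the model needs. A
channel never observed during a stay is filled with the
training-population channel mean — the only value that is neutral (0)
after z-scoring. Padding is likewise 0 *in normalized space*, i.e. the
channel mean, so padding injects no extreme values; whether the source
procedure pads before or after normalization is not stated, and this
convention is recorded in the encoding configuration.

**Encoding.** Categorical features get lexicographic integer
vocabularies with a reserved unknown index (unseen test categories can
never fail); numeric features and dynamic channels are z-scored with
mean and *population* standard deviation (divisor n) computed on the
training split only, preventing leakage. Triage level (ordinal 1-5) is
treated as the fifth numeric feature alongside age, ED length of stay,
household income and physician age; the judgement code is categorical.
Both choices are recorded in `static_feature_types()` and overridable.

## Augmentation (training split, positives only)

* **Window shifting** — the 24-hour window slides backward one hour at a
  time, up to 8 shifts (shift *k* covers [-(24+k) h, -k h)); each
  shifted window re-runs imputation, and a window containing zero
  observations is discarded rather than emitted as pure imputation.
* **Jitter** — Gaussian noise with sd 12% of the per-channel training sd
  (equal to 0.12 in normalized space, where the two scales coincide).
* **Scaling** — one factor per sequence drawn uniformly from
  [0.9, 1.1].
* **Oversampling** — complete positive samples (static + dynamic pair)
  are duplicated with replacement to a 1:1 ratio with negatives.

Jitter and scaling are applied independently with probability 0.5 to
each shifted window; the procedure's source describes them as a pool of
random transformations without composition rules, so the simplest
unbiased composition was chosen. Validation and test splits are never
augmented.

## The hybrid model

**Dynamic branch.** A temporal convolutional network: residual blocks of
causal dilated 1-D convolutions with dilations 1, 2, 4, ...; the
configuration must satisfy the receptive-field inequality
1 + 2(k-1)(2^L - 1) >= 24 so the last step sees the whole sequence. The
sequence embedding is the final (discharge-adjacent) step of the top
feature map. Padded steps enter as channel means; no masked convolution
is used because λ-gating is the architecture's mechanism for padding
robustness.

**Static branch.** A feature tokenizer plus transformer encoder:
categorical features are embedded by lookup, numeric features by a
per-feature linear map, a classification token is prepended, and the
classification token's final representation is the branch embedding. The
final layer's attention from the classification token to the 19 feature
tokens doubles as the global static importance measure.

**Summary indicators.** Alongside the learned embedding, the dynamic
branch contributes two explicit per-channel statistical indicators of
the valid region — the delta (last valid step minus first valid step)
and the within-stay standard deviation. Both are differentiable, enter
the fusion vector with the TCN embedding, are removed together with the
TCN under ablation, and participate in gradient saliency. They exist
because the discriminative content of a short ED stay is largely its
within-stay *change*: a convolutional embedding of absolute levels also
carries each patient's baseline offset, which is noise for the outcome,
whereas the delta isolates the change directly. Explicit delta and
standard-deviation indicators of the vital-sign series are part of the
modelled procedure's own feature design.

**Fusion.** The branch outputs (TCN embedding plus summary indicators,
and the classification-token embedding) are concatenated and scaled by a
single scalar gate w = sigmoid(a·λ/24 + b). Normalizing λ to [0, 1]
stabilizes the gate's operating range. One shared gate scales the whole
concatenation (not per-branch gates), and the gate acts on the
concatenation *before* the MLP head; the alternative reading (weighting
the model output) is architecturally possible but the scaled-
concatenation form is what the fusion diagram of the source describes.
The head is an MLP ending in a single logit with a logistic output —
equivalent to a two-class softmax and simpler under focal loss.

**Focal loss.** FL(p_t) = -α (1-p_t)^γ log(p_t) with α = 0.4, γ = 2,
p_t the predicted probability of the true class, probabilities clamped
at 1e-7, batch-mean reduction. α is applied uniformly to both classes,
exactly as the formula is printed. With α = 1, γ = 0 it reduces to
cross-entropy (tested to 1e-9).

**Sizes.** The source omits all architecture sizes. The package default
(`model_config()`) is TCN levels 4 / kernel 3 / 64 channels / dropout
0.2, tabular token dim 64 / depth 3 / 8 heads / dropout 0.1, head
128-64-1 — the smallest standard configuration satisfying the
receptive-field invariant. The simulation studies in the tests and the
acceptance script use a compact configuration (levels 3 / 12 channels /
dropout 0.3, token dim 12 / depth 1 / 2 heads / dropout 0.2, head
32-16, up to 20 epochs with patience 7) chosen for the package's
CPU-only simulation scale; every architectural mechanism is identical.
The heavier dropout reflects the far smaller cohorts: with a few
hundred unique positives heavily duplicated by augmentation and
oversampling, memorization is the dominant failure mode.

All layers, the backward passes, and the Adam optimizer are implemented
in vectorized base-R matrix code inside the package; the gradients are
verified against central finite differences through the entire network
in the test suite.

## Training and evaluation

Adam with batch size 32 and learning rate 5e-4 (no schedule), splits
70/15/15 stratified by outcome with largest-remainder apportionment
(sizes and per-split positives within one of exact). Training stops when
the validation AUPRC has not improved by at least 1e-6 for 5 consecutive
epochs, and the best-epoch weights are restored; the strict-improvement
rule avoids plateau stalls. AUPRC drives model selection because under
4% (let alone 0.1%) prevalence AUROC is nearly blind to the minority
class.

**Operating point.** Reports quote precision/recall/F1 at a fixed
sensitivity: the threshold is picked on the *validation* split as the
one whose achieved recall is closest to the target (default 0.60), ties
broken toward higher precision, then applied to test. A fixed-recall
comparison is an inference from the constant recall columns of the
reference results, not a stated procedure; it is recorded prominently as
an assumption.

**Baseline.** The static-only reference is a logistic regression on the
encoded static features plus the first recorded value of each vital
sign, fitted by Newton/IRLS with a small ridge penalty inside the
package, exposing the same probability contract as the hybrid model.

**Ablations.** `run_ablation()` trains four variants identically: full
model, minus the tabular branch, minus the TCN, minus the λ gate, and
reports metric deltas and parameter counts.

## Interpretation

Dynamic importance is gradient saliency: |d p / d x| averaged over a
sample's valid time steps (mask-aware — averaging over pad steps would
dilute scores by stay length), then over samples; gradients are taken
with respect to the probability (the logit is available behind a flag).
Static importance is the classification-token attention of the final
layer, averaged over heads then samples, renormalized over the 19
feature tokens. Per-visit reports (`explain_visit()`) combine both with
the imputed trajectories; `autoplot()` renders them.

## The synthetic cohort

No real ED data ship with the package; `generate_cohort()` emulates the
published summary statistics of the modelled cohort:

* prevalence 4.42% revisit / 0.11% high-risk, assigned by *quantile
  thresholding* of a latent risk score rather than Bernoulli draws — at
  0.11% prevalence binomial noise would make moderate-size cohorts
  unusable for testing;
* log-normal stay length with median 2 h (sdlog 1, clamped to
  0.5-72 h) — the spread is a calibration choice, recorded in
  `sim_config()`, since only the median is published;
* measurements of all six signs at arrival and then every 3-4 h
  (uniform) until discharge; 5% of measurements dropped at random;
* static signal, in two parts. Weak additive weights on age, major
  disease, ambulance arrival, triage level and stay length — weak
  because the reference study's static-only logistic baseline performs
  near chance on its test set, so a faithful emulation must not hand a
  linear model a strong clean additive signal. And two *interaction*
  components no additive model can represent (triage-presentation
  discordance: ambulance arrivals triaged low-acuity or walk-ins triaged
  high-acuity; and major chronic disease at age 70+): the reference
  study's attention branch beats logistic regression by a wide margin on
  the same static features, which is only possible when the static risk
  structure is non-additive. The small stay-length weight also reflects
  that observation time correlates with acuity, which is what makes the
  stay-length gate informative;
* dynamic signal: a sustained +15 beats/min heart-rate elevation for
  revisit positives (x1.5 for high-risk, who are nested within the
  positives) that *emerges after the arrival measurement* and persists
  to discharge. The arrival vital reflects the presenting state — the
  static-only baseline legitimately sees it — while the elevation that
  develops during the stay is exactly the kind of information only a
  temporal model can use. Because the shift is sustained, window
  shifting preserves it.

What the generator does **not** emulate: realistic marginal
distributions of the 19 static features beyond type and plausible
ranges, correlations between statics and stay length, nonstationary
measurement schedules, multi-modal deterioration patterns. Passing
tests on this cohort therefore demonstrate that the pipeline recovers
planted signal under the published prevalence/length/sampling
conditions — not clinical validity on real data.

## Numerical choices and degenerate inputs

* Probabilities clamped at 1e-7 in the loss; layer norm epsilon 1e-5.
* A visit with zero valid hours yields an all-pad sequence with λ = 0;
  the λ gate, not a special case, handles it. Such samples are excluded
  (with a warning) from saliency averages.
* Constant features are flagged and map to 0 rather than dividing by a
  zero sd.
* Threshold selection and splitting are fully deterministic given the
  seed; ties in threshold selection break toward higher precision, then
  higher threshold.
* Weight initialization: He-scaled for convolutions and MLP, 1/sqrt(d)
  for attention projections, N(0, 0.02) for embeddings.

## Problem sizes used in the shipped studies

The package's own simulation studies (test suite and
`scripts/acceptance.R`) use: n = 10,000 visits for the planted-signal
and null-calibration studies (the null model is trained on a 4,000-visit
null cohort and scored on a fresh 10,000-visit null cohort, which keeps
the chance-level check well conditioned: a fresh cohort has 442
positives against the 66 of a 15% test split); n = 3,000-4,000 for the
ablation-direction and saliency-ranking studies; up to 20-25 epochs with
patience 5. These sizes were chosen once as the package's standard
desk-scale study conditions.

## Known limitations

* The reference cohort's headline numbers are computed on private
  hospital data and are not reproducible here; all shipped studies are
  property-based on synthetic cohorts.
* Pure-R training is practical to tens of thousands of visits and
  compact architectures; the default (paper-scale) architecture trains,
  but slowly, on commodity CPUs.
* The fixed-sensitivity operating point is an assumption (see above).
* No calibration analysis, no k-fold cross-validation (the modelled
  procedure explicitly uses temporal/holdout validation), no
  GRU/LSTM/TabNet comparators, and no generative augmentation — all out
  of scope by design.
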