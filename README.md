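# edrevisit

Predicting 72-hour emergency department (ED) revisits — and the rare
high-risk revisits that end in ICU admission, cardiac arrest or
emergency surgery — from what an ED encounter actually produces: a
19-feature triage table recorded once, and six vital signs measured
irregularly over a stay whose median length is about two hours.

`edrevisit` implements the full pipeline as a tidyverse-style R
package:

* **Ingestion & cleaning** — long-format vitals with physiological
  plausibility ranges (out-of-range values are nulled, e.g. HR outside
  [0, 300), SpO2 outside [0, 100]);
* **Temporal preprocessing** — hourly binning anchored to discharge,
  alignment to a fixed 24-step window (leading-side padding, most recent
  24 h kept), forward/backward-fill imputation, and the valid length
  λ = min(24, span);
* **Encoding** — train-split-only z-scoring and label encoding with a
  reserved unknown index;
* **Positive-class augmentation** — backward window shifting (up to 8
  one-hour shifts), Gaussian jitter (sd = 12% of the channel sd),
  uniform scaling in [0.9, 1.1], and 1:1 oversampling;
* **The hybrid model** — a causal dilated temporal convolutional
  network over the vital-sign sequence, a feature-tokenizer attention
  encoder over the triage table, fused by a λ-driven sigmoid gate and
  classified by an MLP head under the focal loss
  FL(p_t) = −α(1−p_t)^γ log(p_t) (α = 0.4, γ = 2). All forward and
  backward passes are implemented in vectorized base-R matrix code and
  verified against finite differences;
* **Training & evaluation** — Adam (batch 32, lr 5e-4), AUPRC early
  stopping (patience 5), stratified 70/15/15 splits,
  fixed-sensitivity operating points, a static-only logistic baseline,
  and an ablation harness;
* **Interpretation** — gradient saliency per vital sign and
  classification-token attention per triage feature, globally or per
  visit, with `autoplot()` methods;
* **A synthetic cohort generator** — no real data ship with the
  package; `generate_cohort()` emulates the published cohort summary
  statistics (4.42% / 0.11% prevalence, 2 h median stay, 3–4 h
  measurement intervals) with planted, recoverable outcome signal.

## A worked example

```r
library(edrevisit)

coh <- generate_cohort(sim_config(n_visits = 2000, seed = 7))
coh
#> <ed_cohort> 2000 visits, 17573 vital measurements
#>   revisit positives: 88 (4.40%), high-risk: 2 (0.100%)

run <- run_revisit_pipeline(
  coh,
  model_config(tcn = list(levels = 3L, kernel = 3L, channels = 12L,
                          dropout = 0.3),
               tabular = list(token_dim = 12L, depth = 1L, heads = 2L,
                              dropout = 0.2),
               head = c(32L, 16L)),
  train_config(max_epochs = 10L, seed = 7),
  augment_config())
run$report
#> <ed_eval> AUROC 0.7454 | AUPRC 0.2897 (base rate 0.0433)
#>   at threshold 0.3154: precision 0.0769, recall 0.8462, F1 0.1410

bl <- run_static_baseline(coh, run$prep)
bl$report$auroc
#> [1] 0.7300992
```

The report's AUROC is the rank probability that a revisit case scores
above a non-revisit case; AUPRC is the area under the precision-recall
curve, to be read against the ~4.4% base rate; precision and recall are
quoted at the threshold chosen on validation to hit the target 60%
sensitivity. At a realistic scale (n = 10,000, 20 epochs — the settings
used by the acceptance script) the hybrid model's test AUROC exceeds
this static-only logistic baseline by a clear margin, reproducing the
qualitative contrast the architecture exists for.

Interpretation and plotting:

```r
imp <- importance_report(run$net, run$prep$test)
head(tidy(imp), 3)     # HR carries the planted dynamic signal
autoplot(imp)
ex <- explain_visit(run$net, run$prep$test,
                    run$prep$test$visit_id[1], run$state)
autoplot(ex)
```

A thin command-line wrapper over the same functions is installed at
`inst/cli/edrevisit.R` (`simulate`, `train`, `evaluate`, `explain`
subcommands).

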