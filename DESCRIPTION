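Package: edrevisit
Title: Hybrid Static-Dynamic Deep Learning for Emergency Department Revisit Risk
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts 72-hour emergency department revisits (general and
    high-risk) from irregular short vital-sign series and triage tables.
    Implements the full pipeline: ingestion and physiological-range cleaning
    of long-format vital streams, hourly binning, discharge-anchored
    alignment to 24-step sequences, forward/backward-fill imputation,
    train-split encoding and normalization, positive-class augmentation
    (window shifting, jitter, scaling, oversampling), a hybrid network
    combining a causal dilated temporal convolutional encoder with a
    feature-tokenizer attention encoder fused through a valid-length gate,
    focal-loss training with AUPRC early stopping, fixed-sensitivity
    evaluation, ablation harness, gradient-saliency and attention-based
    interpretation, and a synthetic cohort generator with planted,
    recoverable outcome signal.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    rlang,
    jsonlite,
    ggplot2,
    generics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
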