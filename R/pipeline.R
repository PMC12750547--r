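#' Preprocess a cohort into model tensors for each split
#'
#' Runs the full dynamic and static preprocessing path: outlier removal,
#' hourly division, discharge-anchored alignment, encoding fitted on the
#' training split only, then imputation and normalization applied to
#' every split with the training statistics.
#'
#' @param cohort An `ed_cohort` from [read_cohort()] or
#'   [generate_cohort()].
#' @param split Tibble from [stratified_split()], rows aligned with
#'   `cohort$static`.
#' @param L Fixed sequence length in hours (default 24).
#' @return List: `state` (`ed_encoding`), `train`/`val`/`test`
#'   (`ed_tensors`), `grids` (un-truncated hourly grids, for window
#'   shifting), `vitals_clean`.
#' @export
prepare_tensors <- function(cohort, split, L = 24L) {
  stopifnot(nrow(split) == nrow(cohort$static))
  vit <- remove_outliers(cohort$vitals)
  ids <- cohort$static$visit_id
  grids <- hourly_divide(vit, visit_ids = ids)
  seqs <- lapply(grids, align_fixed_length, L = L)

  pick <- function(s) {
    keep <- split$split == s
    list(static = cohort$static[keep, , drop = FALSE],
         seqs = seqs[ids[keep]])
  }
  tr <- pick("train")
  state <- fit_encoding(tr$static, tr$seqs)
  tens <- lapply(list(train = tr, val = pick("val"), test = pick("test")),
                 function(x) apply_encoding(state, x$static, x$seqs))
  list(state = state, train = tens$train, val = tens$val,
       test = tens$test, grids = grids, vitals_clean = vit)
}

#' Run the full hybrid pipeline on a cohort
#'
#' Stratified 70/15/15 split, preprocessing, positive-class augmentation
#' and oversampling on the training split only, focal-loss training with
#' AUPRC early stopping, threshold selection at the target sensitivity on
#' validation, and evaluation on the held-out test split. Fully
#' reproducible from the seeds in the configs.
#'
#' @param cohort An `ed_cohort`.
#' @param model_cfg A [model_config()].
#' @param train_cfg A [train_config()] (carries the task and seed).
#' @param augment_cfg An [augment_config()].
#' @param fractions Split fractions (default `c(0.70, 0.15, 0.15)`).
#' @param prep Optional precomputed result of [prepare_tensors()] with
#'   its `split`, to share preprocessing across runs (e.g. ablations).
#' @return List with `net`, `report` (`ed_eval` on test), `threshold`,
#'   `history`, `best_epoch`, `split`, `state`, `scores_test`, `prep`.
#' @export
run_revisit_pipeline <- function(cohort,
                                 model_cfg = model_config(),
                                 train_cfg = train_config(),
                                 augment_cfg = augment_config(),
                                 fractions = c(0.70, 0.15, 0.15),
                                 prep = NULL) {
  task <- train_cfg$task
  if (is.null(prep)) {
    split <- stratified_split(cohort$static, fractions,
                              seed = train_cfg$seed, task = task)
    prep <- prepare_tensors(cohort, split)
    prep$split <- split
  }
  if (is.null(augment_cfg$seed)) augment_cfg$seed <- train_cfg$seed
  aug <- augment_positive_set(prep$train, prep$grids, prep$state,
                              augment_cfg, task = task)
  idx <- oversample_indices(task_labels(aug, task),
                            augment_cfg$oversample_target_ratio)
  train_tensors <- subset_tensors(aug, idx)

  net <- init_revisit_net(model_cfg, prep$state, seed = train_cfg$seed)
  fit <- train_revisit_net(net, train_tensors, prep$val, train_cfg)

  val_scores <- predict_proba(fit$net, prep$val)
  thr <- choose_threshold_at_recall(val_scores,
                                    task_labels(prep$val, task),
                                    train_cfg$target_recall)
  test_scores <- predict_proba(fit$net, prep$test)
  report <- compute_metrics(test_scores, task_labels(prep$test, task),
                            threshold = thr)
  list(net = fit$net, report = report, threshold = thr,
       history = fit$history, best_epoch = fit$best_epoch,
       split = prep$split, state = prep$state,
       scores_test = test_scores, prep = prep)
}

#' Fit and evaluate the static-only logistic baseline on the same split
#'
#' The reference model sees the triage features plus the first recorded
#' value of each vital sign; it is fitted on the raw (un-augmented)
#' training split and evaluated at the same fixed-sensitivity operating
#' point as the hybrid model.
#'
#' @param cohort An `ed_cohort`.
#' @param prep Result of [prepare_tensors()] with `split` attached.
#' @param task Prediction task.
#' @param target_recall Operating sensitivity (default 0.60).
#' @param l2 Ridge penalty for the solver.
#' @return List with `model`, `report` (`ed_eval` on test),
#'   `threshold`, `scores_test`.
#' @export
run_static_baseline <- function(cohort, prep,
                                task = c("general_revisit",
                                         "highrisk_revisit"),
                                target_recall = 0.60, l2 = 1e-4) {
  task <- match.arg(task)
  split <- prep$split
  ids <- cohort$static$visit_id
  fv_all <- first_vitals(prep$vitals_clean, ids)
  Xs <- lapply(c(train = "train", val = "val", test = "test"),
               function(s) {
    keep <- split$split == s
    baseline_features(prep$state, cohort$static[keep, , drop = FALSE],
                      fv_all[keep, , drop = FALSE])
  })
  lab <- function(s) {
    keep <- split$split == s
    if (task == "highrisk_revisit") cohort$static$label_highrisk[keep]
    else cohort$static$label_revisit[keep]
  }
  model <- fit_static_baseline(Xs$train, lab("train"), l2 = l2)
  thr <- choose_threshold_at_recall(predict_baseline(model, Xs$val),
                                    lab("val"), target_recall)
  scores <- predict_baseline(model, Xs$test)
  report <- compute_metrics(scores, lab("test"), threshold = thr)
  list(model = model, report = report, threshold = thr,
       scores_test = scores)
}

ablation_variants <- function(base_cfg) {
  list(
    ALL        = base_cfg,
    no_tabular = modify_cfg(base_cfg, use_tabular = FALSE),
    no_tcn     = modify_cfg(base_cfg, use_tcn = FALSE),
    no_lambda  = modify_cfg(base_cfg, use_lambda = FALSE)
  )
}

modify_cfg <- function(cfg, ...) {
  ch <- list(...)
  for (nm in names(ch)) cfg[[nm]] <- ch[[nm]]
  do.call(model_config, cfg[c("tcn", "tabular", "head", "use_tcn",
                              "use_tabular", "use_lambda")])
}

#' Architectural ablation harness
#'
#' Trains and evaluates four variants identically on one fixed cohort and
#' split: the full model, the model without the tabular attention branch,
#' without the temporal convolutional branch, and without the
#' valid-length fusion gate. Reports per-variant metrics, parameter
#' counts, and AUROC/AUPRC deltas against the full model.
#'
#' @param cohort An `ed_cohort`.
#' @param base_cfg The full-model [model_config()].
#' @param train_cfg A [train_config()].
#' @param augment_cfg An [augment_config()].
#' @param variants Character subset of
#'   `c("ALL", "no_tabular", "no_tcn", "no_lambda")`.
#' @return An `ed_ablation` tibble: one row per variant with metric
#'   columns, `n_params`, `delta_auroc`, `delta_auprc`.
#' @export
run_ablation <- function(cohort, base_cfg = model_config(),
                         train_cfg = train_config(),
                         augment_cfg = augment_config(),
                         variants = c("ALL", "no_tabular", "no_tcn",
                                      "no_lambda")) {
  cfgs <- ablation_variants(base_cfg)[variants]
  split <- stratified_split(cohort$static, seed = train_cfg$seed,
                            task = train_cfg$task)
  prep <- prepare_tensors(cohort, split)
  prep$split <- split
  rows <- purrr::imap(cfgs, function(cfg, nm) {
    run <- run_revisit_pipeline(cohort, cfg, train_cfg, augment_cfg,
                                prep = prep)
    r <- run$report
    tibble::tibble(variant = nm, auroc = r$auroc, auprc = r$auprc,
                   precision = r$precision, recall = r$recall,
                   f1 = r$f1, n_params = n_params(run$net))
  })
  out <- dplyr::bind_rows(rows)
  ref <- out[out$variant == variants[1], ]
  out$delta_auroc <- out$auroc - ref$auroc
  out$delta_auprc <- out$auprc - ref$auprc
  class(out) <- c("ed_ablation", class(out))
  out
}
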