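#' Training configuration
#'
#' Optimization uses the Adam adaptive-moment method with batch size 32
#' and learning rate 5e-4; training stops early when the validation AUPRC
#' has not improved (strictly, by at least `min_improve`) for `patience`
#' consecutive epochs, and the weights of the best validation-AUPRC epoch
#' are restored.
#'
#' @param batch_size Mini-batch size (default 32).
#' @param learning_rate Adam step size (default 5e-4).
#' @param patience Early-stopping patience in epochs (default 5).
#' @param max_epochs Hard cap on epochs (default 30).
#' @param seed Integer seed covering shuffling, dropout and
#'   initialization.
#' @param target_recall Operating sensitivity used when picking the alert
#'   threshold on validation (default 0.60).
#' @param task `"general_revisit"` or `"highrisk_revisit"`.
#' @param alpha,gamma Focal-loss parameters (defaults 0.4 and 2).
#' @param min_improve Minimum AUPRC gain counted as improvement.
#' @return A `train_config` list.
#' @export
train_config <- function(batch_size = 32L, learning_rate = 5e-4,
                         patience = 5L, max_epochs = 30L, seed = 1L,
                         target_recall = 0.60,
                         task = c("general_revisit", "highrisk_revisit"),
                         alpha = 0.4, gamma = 2, min_improve = 1e-6) {
  task <- match.arg(task)
  stopifnot(patience >= 1, target_recall > 0, target_recall <= 1)
  structure(list(batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 patience = as.integer(patience),
                 max_epochs = as.integer(max_epochs),
                 seed = as.integer(seed), target_recall = target_recall,
                 task = task, alpha = alpha, gamma = gamma,
                 min_improve = min_improve),
            class = "train_config")
}

#' Early-stopping bookkeeping over a metric sequence
#'
#' Given per-epoch validation metrics (higher is better), returns how
#' many epochs a patience-based rule runs and which epoch's weights are
#' kept: training stops after the first epoch that lies `patience`
#' epochs beyond the best one.
#'
#' @param metrics Numeric vector of per-epoch validation metrics.
#' @param patience Number of non-improving epochs tolerated.
#' @param min_improve Minimum gain counted as improvement.
#' @return List with `stopped_after` (epochs actually run) and
#'   `best_epoch`.
#' @examples
#' run_early_stopping(c(.2, .3, .3, .3, .3, .3, .3), patience = 5)
#' @export
run_early_stopping <- function(metrics, patience = 5L,
                               min_improve = 1e-6) {
  best <- -Inf
  best_epoch <- 0L
  for (e in seq_along(metrics)) {
    if (metrics[e] - best >= min_improve) {
      best <- metrics[e]
      best_epoch <- e
    }
    if (e - best_epoch >= patience) {
      return(list(stopped_after = e, best_epoch = best_epoch))
    }
  }
  list(stopped_after = length(metrics), best_epoch = best_epoch)
}

#' Stratified train/validation/test split
#'
#' Shuffles each outcome class independently (deterministically, from
#' `seed`) and apportions it across the splits by largest remainder, so
#' split sizes and per-split positive counts are within one visit of the
#' exact 70/15/15 proportions.
#'
#' @param static Static tibble with `visit_id` and the label columns.
#' @param fractions Train/validation/test fractions summing to 1.
#' @param seed Integer seed.
#' @param task Which label stratifies the split.
#' @return A tibble `visit_id`, `split` (`"train"`, `"val"`, `"test"`).
#' @export
stratified_split <- function(static, fractions = c(0.70, 0.15, 0.15),
                             seed = 1L,
                             task = c("general_revisit",
                                      "highrisk_revisit")) {
  task <- match.arg(task)
  stopifnot(abs(sum(fractions) - 1) < 1e-8)
  y <- if (task == "highrisk_revisit") static$label_highrisk else
    static$label_revisit
  if (length(unique(y)) < 2) {
    stop("cohort must contain both classes to stratify", call. = FALSE)
  }
  set.seed(seed)
  splits <- c("train", "val", "test")
  out <- lapply(unique(y), function(cls) {
    ids <- sample(static$visit_id[y == cls])
    n <- length(ids)
    base <- floor(n * fractions)
    rem <- n - sum(base)
    if (rem > 0) {
      frac_part <- n * fractions - base
      extra <- order(frac_part, decreasing = TRUE)[seq_len(rem)]
      base[extra] <- base[extra] + 1L
    }
    tibble::tibble(visit_id = ids,
                   split = rep(splits, times = base))
  })
  out <- dplyr::bind_rows(out)
  pos_per_split <- table(factor(out$split[out$visit_id %in%
                                            static$visit_id[y == 1]],
                                levels = splits))
  if (any(pos_per_split == 0)) {
    stop("a split received zero positives; use a larger cohort",
         call. = FALSE)
  }
  out[match(static$visit_id, out$visit_id), ]
}

#' Train the hybrid network with focal loss and AUPRC early stopping
#'
#' Minimizes the focal loss over the (augmented) training tensors with
#' Adam, records validation AUPRC each epoch, and returns the weights of
#' the best validation epoch. Augmented samples never enter validation.
#'
#' @param net An initialized `ed_net`.
#' @param tensors_train Training `ed_tensors` (augmentation already
#'   applied by the caller).
#' @param tensors_val Validation `ed_tensors` (untouched data).
#' @param cfg A [train_config()].
#' @return List: `net` (best-epoch weights), `history` tibble
#'   (`epoch`, `train_loss`, `val_auprc`), `best_epoch`.
#' @export
train_revisit_net <- function(net, tensors_train, tensors_val,
                              cfg = train_config()) {
  set.seed(cfg$seed)
  y_tr <- task_labels(tensors_train, cfg$task)
  y_val <- task_labels(tensors_val, cfg$task)
  n <- n_tensors(tensors_train)
  opt <- adam_init(net$params)
  best <- -Inf
  best_epoch <- 0L
  best_params <- net$params
  history <- list()

  for (epoch in seq_len(cfg$max_epochs)) {
    ord <- sample(n)
    starts <- seq(1L, n, by = cfg$batch_size)
    epoch_loss <- 0
    for (s in starts) {
      idx <- ord[s:min(s + cfg$batch_size - 1L, n)]
      batch <- tensors_batch(tensors_train, idx)
      fw <- net_forward(net, batch, training = TRUE)
      loss <- focal_loss(fw$p, y_tr[idx], cfg$alpha, cfg$gamma)
      if (!is.finite(loss)) {
        stop(sprintf("training diverged at epoch %d (non-finite loss)",
                     epoch), call. = FALSE)
      }
      epoch_loss <- epoch_loss + loss * length(idx)
      dlogit <- focal_loss_grad_logit(fw$p, y_tr[idx], cfg$alpha,
                                      cfg$gamma)
      bw <- net_backward(net, fw$cache, dlogit)
      step <- adam_step(net$params, bw$grads, opt,
                        lr = cfg$learning_rate)
      net$params <- step$params
      opt <- step$state
    }
    val_p <- predict_proba(net, tensors_val)
    val_auprc <- auprc(val_p, y_val)
    history[[epoch]] <- tibble::tibble(
      epoch = epoch, train_loss = epoch_loss / n, val_auprc = val_auprc)
    if (val_auprc - best >= cfg$min_improve) {
      best <- val_auprc
      best_epoch <- epoch
      best_params <- net$params
    }
    if (epoch - best_epoch >= cfg$patience) break
  }
  net$params <- best_params
  list(net = net, history = dplyr::bind_rows(history),
       best_epoch = best_epoch)
}
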