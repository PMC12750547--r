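#' Area under the ROC curve by the rank statistic
#'
#' Equivalent to the normalized Mann-Whitney U: the proportion of
#' (positive, negative) pairs ranked correctly, with ties given half
#' credit. Invariant under any strictly monotone transform of the scores.
#'
#' @param scores Numeric scores (higher = more positive).
#' @param labels Binary labels (0/1).
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(scores, labels) {
  check_two_classes(labels)
  r <- rank(scores)
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Area under the precision-recall curve by step integration
#'
#' Sweeps the threshold over the distinct score values in decreasing
#' order (tied scores enter together) and accumulates
#' `sum (R_i - R_(i-1)) * P_i` — the average-precision form of the PR
#' area. The base rate (positive prevalence) is its chance-level
#' reference.
#'
#' @inheritParams auroc
#' @return AUPRC in `(0, 1]`.
#' @export
auprc <- function(scores, labels) {
  check_two_classes(labels)
  o <- order(scores, decreasing = TRUE)
  y <- labels[o]
  s <- scores[o]
  # group tied scores so the curve steps once per distinct threshold
  last_of_group <- c(s[-1] != s[-length(s)], TRUE)
  tp <- cumsum(y == 1)[last_of_group]
  n_at <- seq_along(y)[last_of_group]
  n_pos <- sum(labels == 1)
  rec <- tp / n_pos
  prec <- tp / n_at
  sum(diff(c(0, rec)) * prec)
}

check_two_classes <- function(labels) {
  if (length(unique(labels)) < 2) {
    stop("labels contain a single class; metrics are undefined",
         call. = FALSE)
  }
  invisible(labels)
}

#' Evaluation report at a fixed operating point
#'
#' Threshold-free discrimination (AUROC, AUPRC) plus precision, recall
#' and F1 at the supplied threshold (score >= threshold raises an alert),
#' together with the confusion counts and the positive base rate.
#'
#' @inheritParams auroc
#' @param threshold Alert threshold on the score scale.
#' @return An `ed_eval` object; use [generics::tidy()] for a one-row
#'   tibble.
#' @export
compute_metrics <- function(scores, labels, threshold = 0.5) {
  check_two_classes(labels)
  alert <- scores >= threshold
  tp <- sum(alert & labels == 1)
  fp <- sum(alert & labels == 0)
  fn <- sum(!alert & labels == 1)
  tn <- sum(!alert & labels == 0)
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- tp / (tp + fn)
  f1 <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else 0
  structure(list(
    auroc = auroc(scores, labels), auprc = auprc(scores, labels),
    precision = precision, recall = recall, f1 = f1,
    threshold = threshold,
    base_rate = mean(labels == 1),
    n_pos = sum(labels == 1), n_neg = sum(labels == 0),
    tp = tp, fp = fp, fn = fn, tn = tn
  ), class = "ed_eval")
}

#' @export
print.ed_eval <- function(x, ...) {
  cat(sprintf(
    "<ed_eval> AUROC %.4f | AUPRC %.4f (base rate %.4f)\n",
    x$auroc, x$auprc, x$base_rate))
  cat(sprintf(
    "  at threshold %.4f: precision %.4f, recall %.4f, F1 %.4f\n",
    x$threshold, x$precision, x$recall, x$f1))
  invisible(x)
}

#' Choose the alert threshold matching a target sensitivity
#'
#' Models are compared at a fixed operating sensitivity: among the
#' achievable recalls (one per distinct score), pick the threshold whose
#' recall is closest to `target_recall`, breaking ties toward higher
#' precision and then toward the higher threshold. Deterministic.
#'
#' @inheritParams auroc
#' @param target_recall Target sensitivity in `(0, 1]` (default 0.60).
#' @return The chosen threshold.
#' @export
choose_threshold_at_recall <- function(scores, labels,
                                       target_recall = 0.60) {
  stopifnot(target_recall > 0, target_recall <= 1,
            sum(labels == 1) > 0)
  thr <- sort(unique(scores), decreasing = TRUE)
  n_pos <- sum(labels == 1)
  rec <- vapply(thr, function(t) sum(labels == 1 & scores >= t) / n_pos,
                numeric(1))
  prec <- vapply(thr, function(t) {
    a <- scores >= t
    sum(labels == 1 & a) / sum(a)
  }, numeric(1))
  d <- abs(rec - target_recall)
  best <- which(d == min(d))
  best <- best[prec[best] == max(prec[best])]
  best <- best[which.max(thr[best])]
  thr[best]
}
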