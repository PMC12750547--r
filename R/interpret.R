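#' Gradient saliency of the dynamic channels
#'
#' For each sample, backpropagates from the model output to the input
#' vital-sign sequence and takes the absolute gradient at each time step;
#' a sign's saliency for that sample is the mean absolute gradient over
#' its valid (unpadded) steps, and the global score averages over
#' samples. Samples with no valid step are excluded with a warning.
#'
#' @param net A trained `ed_net` with the dynamic branch enabled.
#' @param tensors An `ed_tensors` set.
#' @param on Differentiate the probability (default, matching
#'   backpropagation from the model output) or the raw logit.
#' @param batch_size Batch size for the saliency passes.
#' @return A tibble `sign`, `saliency` (non-negative), sorted by
#'   decreasing saliency.
#' @export
dynamic_saliency <- function(net, tensors, on = c("prob", "logit"),
                             batch_size = 256L) {
  on <- match.arg(on)
  if (!net$cfg$use_tcn) {
    stop("dynamic saliency is undefined when the TCN branch is ablated",
         call. = FALSE)
  }
  n <- n_tensors(tensors)
  if (any(tensors$lam == 0)) {
    warning(sprintf("excluding %d sample(s) with no valid time step",
                    sum(tensors$lam == 0)), call. = FALSE)
  }
  signs <- sign_catalogue()
  acc <- numeric(length(signs))
  n_used <- 0L
  for (s in seq(1L, n, by = batch_size)) {
    idx <- s:min(s + batch_size - 1L, n)
    batch <- tensors_batch(tensors, idx)
    fw <- net_forward(net, batch, training = FALSE)
    dlogit <- if (on == "prob") fw$p * (1 - fw$p) else rep(1, length(idx))
    bw <- net_backward(net, fw$cache, dlogit, need_input_grad = TRUE)
    g <- abs(bw$ddyn)  # B x T x 6
    T_len <- dim(g)[2]
    for (b in seq_along(idx)) {
      lam <- batch$lam[b]
      if (lam == 0) next
      rows <- (T_len - lam + 1):T_len
      slice <- matrix(g[b, rows, ], nrow = length(rows))
      acc <- acc + colMeans(slice)
      n_used <- n_used + 1L
    }
  }
  if (n_used == 0L) stop("no sample with a valid time step", call. = FALSE)
  tibble::tibble(sign = signs, saliency = acc / n_used) |>
    dplyr::arrange(dplyr::desc(.data$saliency))
}

#' Classification-token attention over static features
#'
#' Extracts the final attention layer's weights from the classification
#' token to each feature token, averages over heads and samples, and
#' renormalizes over the 19 feature tokens so the weights sum to 1.
#'
#' @param net A trained `ed_net` with the tabular branch enabled.
#' @param tensors An `ed_tensors` set.
#' @param batch_size Batch size for the forward passes.
#' @return A tibble `feature`, `weight` (summing to 1), sorted by
#'   decreasing weight.
#' @export
static_attention <- function(net, tensors, batch_size = 512L) {
  if (!net$cfg$use_tabular) {
    stop("static attention is undefined when the tabular branch is ablated",
         call. = FALSE)
  }
  n <- n_tensors(tensors)
  feats <- c(net$num_features, net$cat_features)
  acc <- numeric(length(feats))
  for (s in seq(1L, n, by = batch_size)) {
    idx <- s:min(s + batch_size - 1L, n)
    fw <- net_forward(net, tensors_batch(tensors, idx), training = FALSE)
    a <- fw$cache$attn[, -1, drop = FALSE]  # drop the CLS-to-CLS column
    acc <- acc + colSums(a)
  }
  w <- acc / sum(acc)
  tibble::tibble(feature = feats, weight = w) |>
    dplyr::arrange(dplyr::desc(.data$weight))
}

#' Global or per-visit importance report
#'
#' Combines gradient saliency over the dynamic channels with the
#' classification-token attention over the static features.
#'
#' @inheritParams dynamic_saliency
#' @param scope `"global"` or `"single_visit"` (metadata only).
#' @return An `ed_importance` object with tibbles `dynamic` and
#'   `static`, `scope` and `n_samples`.
#' @export
importance_report <- function(net, tensors, scope = "global",
                              on = "prob") {
  structure(list(
    dynamic = if (net$cfg$use_tcn) dynamic_saliency(net, tensors, on = on)
              else NULL,
    static = if (net$cfg$use_tabular) static_attention(net, tensors)
             else NULL,
    scope = scope, n_samples = n_tensors(tensors)
  ), class = "ed_importance")
}

#' @export
print.ed_importance <- function(x, ...) {
  cat(sprintf("<ed_importance> scope = %s, n = %d\n", x$scope,
              x$n_samples))
  if (!is.null(x$dynamic)) {
    cat("  top dynamic:", paste(utils::head(x$dynamic$sign, 3),
                                collapse = ", "), "\n")
  }
  if (!is.null(x$static)) {
    cat("  top static:", paste(utils::head(x$static$feature, 3),
                               collapse = ", "), "\n")
  }
  invisible(x)
}

#' Explain a single visit
#'
#' Per-visit saliency and attention plus the imputed vital-sign
#' trajectories (normalized and raw scale) for plotting, with the pad
#' region flagged.
#'
#' @param net A trained `ed_net`.
#' @param tensors An `ed_tensors` set.
#' @param visit_id The visit to explain (must be present in `tensors`).
#' @param state The fitted `ed_encoding` (to de-normalize the traces).
#' @return An `ed_explanation`: list with `prob`, `report`
#'   (`ed_importance`, scope `"single_visit"`), and `trace` tibble
#'   (`hour`, `sign`, `value`, `value_raw`, `pad`).
#' @export
explain_visit <- function(net, tensors, visit_id, state) {
  i <- match(as.character(visit_id), tensors$visit_id)
  if (is.na(i)) stop("visit_id not found in tensors", call. = FALSE)
  one <- subset_tensors(tensors, i)
  prob <- predict_proba(net, one)
  report <- importance_report(net, one, scope = "single_visit")
  T_len <- dim(one$dyn)[2]
  signs <- sign_catalogue()
  lam <- one$lam[1]
  trace <- tidyr::expand_grid(hour = seq_len(T_len) - T_len,
                              sign = signs)
  trace$value <- purrr::map2_dbl(trace$hour + T_len, trace$sign,
                                 function(t, s) one$dyn[1, t, s])
  trace$value_raw <- purrr::map2_dbl(
    trace$value, trace$sign,
    function(v, s) v * state$dyn_stats[[s]]$sd + state$dyn_stats[[s]]$mean)
  trace$pad <- (trace$hour + T_len) <= (T_len - lam)
  trace$value_raw[trace$pad] <- NA_real_
  structure(list(visit_id = as.character(visit_id), prob = prob,
                 report = report, trace = trace),
            class = "ed_explanation")
}

#' @export
print.ed_explanation <- function(x, ...) {
  cat(sprintf("<ed_explanation> visit %s: predicted probability %.4f\n",
              x$visit_id, x$prob))
  invisible(x)
}
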