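#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an evaluation report
#'
#' @param x An `ed_eval`.
#' @param ... Unused.
#' @return One-row tibble with the metric columns and confusion counts.
#' @method tidy ed_eval
#' @export
tidy.ed_eval <- function(x, ...) {
  tibble::tibble(auroc = x$auroc, auprc = x$auprc,
                 precision = x$precision, recall = x$recall, f1 = x$f1,
                 threshold = x$threshold, base_rate = x$base_rate,
                 n_pos = x$n_pos, n_neg = x$n_neg,
                 tp = x$tp, fp = x$fp, fn = x$fn, tn = x$tn)
}

#' Tidy the logistic baseline coefficients
#'
#' @param x An `ed_baseline`.
#' @param ... Unused.
#' @return Tibble `term`, `estimate`.
#' @method tidy ed_baseline
#' @export
tidy.ed_baseline <- function(x, ...) {
  tibble::tibble(term = names(x$coef), estimate = unname(x$coef))
}

#' @rdname tidy.ed_baseline
#' @method glance ed_baseline
#' @export
glance.ed_baseline <- function(x, ...) {
  tibble::tibble(n_coef = length(x$coef), converged = x$converged)
}

#' Tidy an importance report into one long tibble
#'
#' @param x An `ed_importance`.
#' @param ... Unused.
#' @return Tibble `channel` (`"dynamic"`/`"static"`), `feature`,
#'   `score`.
#' @method tidy ed_importance
#' @export
tidy.ed_importance <- function(x, ...) {
  dplyr::bind_rows(
    if (!is.null(x$dynamic)) {
      tibble::tibble(channel = "dynamic", feature = x$dynamic$sign,
                     score = x$dynamic$saliency)
    },
    if (!is.null(x$static)) {
      tibble::tibble(channel = "static", feature = x$static$feature,
                     score = x$static$weight)
    }
  )
}
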