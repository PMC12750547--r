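#' Vital-sign catalogue
#'
#' The six dynamic features recorded during an ED stay, by their conventional
#' abbreviations: heart rate (HR, beats/min), diastolic blood pressure (DBP,
#' mmHg), oxygen saturation (SpO2, %), body temperature (BT, deg C),
#' respiratory rate (RR, breaths/min), systolic blood pressure (SBP, mmHg).
#'
#' @return Character vector of the six sign codes.
#' @export
sign_catalogue <- function() {
  c("HR", "DBP", "SpO2", "BT", "RR", "SBP")
}

#' Default physiological plausibility ranges
#'
#' Manually entered vital signs occasionally contain implausible values; any
#' value outside these ranges is treated as abnormal and nulled before
#' imputation. All lower bounds are inclusive at 0. Upper bounds are
#' exclusive except for oxygen saturation, where 100% is attainable and the
#' interval is closed.
#'
#' @return A tibble with columns `sign`, `lower`, `upper`,
#'   `upper_inclusive`.
#' @examples
#' default_ranges()
#' @export
default_ranges <- function() {
  tibble::tibble(
    sign            = c("HR", "RR", "SpO2", "DBP", "BT", "SBP"),
    lower           = 0,
    upper           = c(300, 50, 100, 300, 50, 300),
    upper_inclusive = c(FALSE, FALSE, TRUE, FALSE, FALSE, FALSE)
  )
}

validate_ranges <- function(ranges) {
  req <- c("sign", "lower", "upper", "upper_inclusive")
  miss <- setdiff(req, names(ranges))
  if (length(miss) > 0) {
    stop("plausibility ranges are missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if (any(ranges$lower >= ranges$upper)) {
    stop("each plausibility range must have lower < upper", call. = FALSE)
  }
  invisible(ranges)
}

#' Null physiologically implausible vital-sign values
#'
#' Replaces out-of-range values in a long-format vitals table with `NA`;
#' in-range values pass through bit-identically and the number of rows is
#' unchanged. Missing values are left untouched, so the operation is
#' idempotent.
#'
#' @param vitals A data frame with at least `sign` and `value` columns
#'   (long format, one measurement per row).
#' @param ranges Plausibility ranges as returned by [default_ranges()];
#'   must cover every sign present in `vitals`.
#' @return `vitals` with out-of-range `value`s set to `NA`.
#' @examples
#' v <- tibble::tibble(sign = c("HR", "SpO2"), value = c(350, 100))
#' remove_outliers(v)$value  # HR nulled, SpO2 retained
#' @export
remove_outliers <- function(vitals, ranges = default_ranges()) {
  validate_ranges(ranges)
  unknown <- setdiff(unique(vitals$sign), ranges$sign)
  if (length(unknown) > 0) {
    stop("no plausibility range for sign(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  idx <- match(vitals$sign, ranges$sign)
  lo <- ranges$lower[idx]
  hi <- ranges$upper[idx]
  hi_inc <- ranges$upper_inclusive[idx]
  v <- vitals$value
  bad <- !is.na(v) & (v < lo | v > hi | (!hi_inc & v == hi))
  vitals$value[bad] <- NA_real_
  vitals
}

#' Flag implausible static values without modifying them
#'
#' Cleaning is defined only for the dynamic channel; static anomalies (for
#' example a negative age or a negative length of stay) are reported for
#' review but never altered.
#'
#' @param static A static table with one row per visit.
#' @return A tibble with columns `visit_id`, `feature`, `value`, `issue`;
#'   zero rows when nothing is flagged.
#' @export
flag_static_anomalies <- function(static) {
  checks <- list(
    age            = function(x) !is.na(x) & (x < 0 | x > 120),
    ed_los_hours   = function(x) !is.na(x) & (x <= 0 | x > 24 * 30),
    physician_age  = function(x) !is.na(x) & (x < 20 | x > 90),
    household_income = function(x) !is.na(x) & x < 0
  )
  out <- purrr::imap(checks, function(fn, col) {
    if (!col %in% names(static)) return(NULL)
    bad <- fn(static[[col]])
    if (!any(bad)) return(NULL)
    tibble::tibble(
      visit_id = as.character(static$visit_id[bad]),
      feature  = col,
      value    = as.numeric(static[[col]][bad]),
      issue    = "outside plausible range"
    )
  })
  out <- purrr::compact(out)
  if (length(out) == 0) {
    return(tibble::tibble(visit_id = character(), feature = character(),
                          value = numeric(), issue = character()))
  }
  dplyr::bind_rows(out)
}
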