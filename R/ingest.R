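#' Names and types of the triage (static) features
#'
#' Nineteen features are recorded once per visit at triage. Five are numeric
#' (age, triage level, ED length of stay, household income, treating
#' physician's age); the remaining fourteen are categorical. Triage level is
#' ordinal on the five-level Taiwan Triage and Acuity Scale and is treated
#' as numeric; the judgement code is treated as categorical. Both choices
#' are recorded here so they can be overridden when fitting an encoding.
#'
#' @return A tibble with columns `feature` and `type`
#'   (`"numeric"`/`"categorical"`).
#' @export
static_feature_types <- function() {
  tibble::tibble(
    feature = c(
      "age", "weekend_triage", "department", "ambulance", "sex", "season",
      "dayzone", "dayzone_discharge", "weekend_discharge", "triage_level",
      "ed_los_hours", "household_income", "major_disease", "judgement_code",
      "marital_status", "employment_status", "nationality", "physician_sex",
      "physician_age"
    ),
    type = c(
      "numeric", "categorical", "categorical", "categorical", "categorical",
      "categorical", "categorical", "categorical", "categorical", "numeric",
      "numeric", "numeric", "categorical", "categorical", "categorical",
      "categorical", "categorical", "categorical", "numeric"
    )
  )
}

static_required_cols <- function() {
  c("visit_id", "discharge_time", "label_revisit", "label_highrisk")
}

#' Read a cohort from a static CSV and a long-format vitals CSV
#'
#' The static file holds one row per visit: `visit_id`, the triage features
#' (see [static_feature_types()]), a `discharge_time` ISO-8601 datetime and
#' the binary outcome labels `label_revisit` and `label_highrisk`. The
#' vitals file is long format — `visit_id`, `timestamp` (ISO-8601), `sign`,
#' `value` — and is converted internally to minutes before discharge
#' (`time_min` less than or equal to 0). Every visit in the static table gets a (possibly
#' empty) vital stream; vital rows whose `visit_id` is absent from the
#' static table are dropped with a warning reporting the count.
#'
#' @param static_path Path to the static CSV.
#' @param vitals_path Path to the vitals CSV.
#' @return An object of class `ed_cohort`: a list with tibbles `static`
#'   (discharge time parsed to POSIXct) and `vitals`
#'   (`visit_id`, `time_min`, `sign`, `value`), plus `n_dropped`.
#' @export
read_cohort <- function(static_path, vitals_path) {
  static <- readr::read_csv(static_path, show_col_types = FALSE,
                            progress = FALSE)
  vitals <- readr::read_csv(vitals_path, show_col_types = FALSE,
                            progress = FALSE,
                            col_types = readr::cols(
                              visit_id = readr::col_character(),
                              .default = readr::col_guess()))

  miss <- setdiff(static_required_cols(), names(static))
  if (length(miss) > 0) {
    stop("static table is missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  miss_v <- setdiff(c("visit_id", "timestamp", "sign", "value"), names(vitals))
  if (length(miss_v) > 0) {
    stop("vitals table is missing required column(s): ",
         paste(miss_v, collapse = ", "), call. = FALSE)
  }
  static$visit_id <- as.character(static$visit_id)
  if (anyDuplicated(static$visit_id)) {
    stop("static table must have exactly one row per visit_id", call. = FALSE)
  }
  bad_sign <- setdiff(unique(vitals$sign), sign_catalogue())
  if (length(bad_sign) > 0) {
    stop("unknown vital sign(s) in vitals file: ",
         paste(bad_sign, collapse = ", "), call. = FALSE)
  }
  if (any(static$label_highrisk == 1 & static$label_revisit != 1)) {
    stop("label_highrisk = 1 requires label_revisit = 1", call. = FALSE)
  }

  orphan <- !(vitals$visit_id %in% static$visit_id)
  n_dropped <- sum(orphan)
  if (n_dropped > 0) {
    warning(sprintf("dropped %d vital row(s) with unknown visit_id",
                    n_dropped), call. = FALSE)
    vitals <- vitals[!orphan, , drop = FALSE]
  }

  static$discharge_time <- as.POSIXct(static$discharge_time, tz = "UTC")
  ts <- as.POSIXct(vitals$timestamp, tz = "UTC")
  dis <- static$discharge_time[match(vitals$visit_id, static$visit_id)]
  time_min <- as.numeric(difftime(ts, dis, units = "mins"))
  late <- time_min > 0
  if (any(late)) {
    warning(sprintf("dropped %d vital row(s) timestamped after discharge",
                    sum(late)), call. = FALSE)
  }
  vitals <- tibble::tibble(
    visit_id = vitals$visit_id,
    time_min = time_min,
    sign     = vitals$sign,
    value    = as.numeric(vitals$value)
  )[!late, , drop = FALSE]
  vitals <- dplyr::arrange(vitals, .data$visit_id, .data$time_min)

  structure(list(static = tibble::as_tibble(static), vitals = vitals,
                 n_dropped = n_dropped),
            class = "ed_cohort")
}

#' @export
print.ed_cohort <- function(x, ...) {
  cat(sprintf("<ed_cohort> %d visits, %d vital measurements\n",
              nrow(x$static), nrow(x$vitals)))
  cat(sprintf("  revisit positives: %d (%.2f%%), high-risk: %d (%.3f%%)\n",
              sum(x$static$label_revisit),
              100 * mean(x$static$label_revisit),
              sum(x$static$label_highrisk),
              100 * mean(x$static$label_highrisk)))
  invisible(x)
}

# Internal: turn an ed_cohort back into the on-disk dialect (used by
# write_cohort and by the round-trip property tests).
cohort_to_files <- function(cohort, static_path, vitals_path) {
  st <- cohort$static
  st$discharge_time <- format(st$discharge_time, "%Y-%m-%dT%H:%M:%S",
                              tz = "UTC")
  readr::write_csv(st, static_path, progress = FALSE)
  dis <- cohort$static$discharge_time[
    match(cohort$vitals$visit_id, cohort$static$visit_id)]
  vt <- tibble::tibble(
    visit_id  = cohort$vitals$visit_id,
    timestamp = format(dis + 60 * cohort$vitals$time_min,
                       "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
    sign      = cohort$vitals$sign,
    value     = cohort$vitals$value
  )
  readr::write_csv(vt, vitals_path, progress = FALSE)
  invisible(c(static_path, vitals_path))
}
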