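#' Synthetic cohort configuration
#'
#' Defaults emulate the published summary statistics of a large tertiary
#' ED cohort: ~4.42% 72-hour revisit prevalence, ~0.11% high-risk
#' prevalence, a median stay of about 2 hours (log-normal length of stay,
#' clamped to 0.5-72 h) and vital signs measured at 3-4 hour intervals
#' starting at arrival. Outcome signal is planted in both channels: a
#' configurable log-odds-style weight on a documented subset of static
#' features, and a sustained heart-rate elevation that emerges after the
#' arrival measurement and persists to discharge for revisit positives
#' (stronger, by `highrisk_boost`, for high-risk positives). Labels are
#' assigned by thresholding the latent risk score at the quantile
#' matching the configured rates, so positive counts are exact rather
#' than binomially noisy.
#'
#' @param n_visits Number of visits (>= 100).
#' @param revisit_rate,highrisk_rate Positive prevalences
#'   (defaults 0.0442 and 0.0011; `highrisk_rate` less than or equal to
#'   `revisit_rate`).
#' @param los_meanlog,los_sdlog Log-normal stay-length parameters in
#'   hours (median `exp(los_meanlog)` = 2 h).
#' @param los_min,los_max Stay clamp in hours.
#' @param interval_range Hours between successive measurements
#'   (uniform; default `c(3, 4)`).
#' @param effect_dynamic Named per-sign sustained shift for positives
#'   (default `c(HR = 15)` beats/min).
#' @param effect_static Named weights of the planted additive static
#'   signal.
#' @param effect_static_nonlinear Named weights of planted interaction
#'   (non-additive) static risk components that a linear model cannot
#'   represent: `discordance` (mismatch between arrival mode and triage
#'   acuity) and `elderly_comorbid` (major disease at age 70+).
#' @param highrisk_boost Multiplier on the dynamic shift for high-risk
#'   positives.
#' @param noise_sd,between_sd Named per-sign within-visit measurement
#'   noise and between-visit offset standard deviations.
#' @param missing_extra_rate Fraction of measurements dropped at random.
#' @param seed Integer seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_visits = 10000L,
                       revisit_rate = 0.0442, highrisk_rate = 0.0011,
                       los_meanlog = log(2), los_sdlog = 1,
                       los_min = 0.5, los_max = 72,
                       interval_range = c(3, 4),
                       effect_dynamic = c(HR = 15),
                       effect_static = c(age = 0.1, major_disease = 0.25,
                                         ambulance = 0.2,
                                         triage_level = -0.1,
                                         ed_los_hours = 0.1),
                       effect_static_nonlinear = c(discordance = 0.6,
                                                   elderly_comorbid = 0.5),
                       highrisk_boost = 1.5,
                       noise_sd = c(HR = 3, DBP = 4, SpO2 = 0.8,
                                    BT = 0.15, RR = 1, SBP = 5),
                       between_sd = c(HR = 12, DBP = 10, SpO2 = 1.5,
                                      BT = 0.4, RR = 3, SBP = 15),
                       missing_extra_rate = 0.05, seed = 1L) {
  stopifnot(n_visits >= 100, highrisk_rate >= 0,
            highrisk_rate <= revisit_rate, revisit_rate <= 1,
            los_min > 0, los_min < los_max,
            interval_range[1] <= interval_range[2])
  structure(as.list(environment()), class = "sim_config")
}

sign_pop_means <- function() {
  c(HR = 80, DBP = 75, SpO2 = 97, BT = 36.8, RR = 17, SBP = 125)
}

# clamp comfortably inside the physiological plausibility ranges
sign_clamp <- function() {
  list(lo = c(HR = 20, DBP = 20, SpO2 = 50, BT = 33, RR = 4, SBP = 40),
       hi = c(HR = 250, DBP = 200, SpO2 = 100, BT = 43, RR = 45,
              SBP = 260))
}

# Planted static signal: standardized numeric contribution per weighted
# feature. Binary yes/no features contribute their indicator.
static_signal <- function(static, effects) {
  if (length(effects) == 0) return(numeric(nrow(static)))
  contrib <- vapply(names(effects), function(f) {
    x <- static[[f]]
    v <- if (is.numeric(x)) {
      s <- stats::sd(x)
      if (s == 0) rep(0, length(x)) else (x - mean(x)) / s
    } else {
      as.numeric(x == "yes")
    }
    effects[[f]] * v
  }, numeric(nrow(static)))
  rowSums(contrib)
}

# Nonlinear (interaction) static signal components. These emulate risk
# structure an additive linear model cannot represent but a
# feature-interaction learner can:
#   discordance      - mismatch between arrival mode and assigned acuity
#                      (ambulance arrival triaged low-acuity, or walk-in
#                      triaged high-acuity): classic under/over-triage
#   elderly_comorbid - major chronic disease in patients aged 70+
static_signal_nonlinear <- function(static, effects) {
  out <- numeric(nrow(static))
  if (length(effects) == 0) return(out)
  if ("discordance" %in% names(effects)) {
    amb <- static$ambulance == "yes"
    disc <- (amb & static$triage_level >= 4) |
      (!amb & static$triage_level <= 2)
    out <- out + effects[["discordance"]] * as.numeric(disc)
  }
  if ("elderly_comorbid" %in% names(effects)) {
    out <- out + effects[["elderly_comorbid"]] *
      as.numeric(static$age >= 70 & static$major_disease == "yes")
  }
  out
}

#' Generate a synthetic ED cohort with planted, recoverable signal
#'
#' @param cfg A [sim_config()].
#' @return An `ed_cohort` (static table with labels and discharge times,
#'   long-format vitals in minutes before discharge) with an extra
#'   `truth` tibble holding the latent risk score and planted-effect
#'   flags.
#' @examples
#' coh <- generate_cohort(sim_config(n_visits = 500, seed = 7))
#' sum(coh$static$label_revisit)  # exactly round(500 * 0.0442)
#' @export
generate_cohort <- function(cfg = sim_config()) {
  set.seed(cfg$seed)
  n <- cfg$n_visits
  ids <- sprintf("V%06d", seq_len(n))
  yn <- function(p) sample(c("yes", "no"), n, TRUE, c(p, 1 - p))

  los <- pmin(cfg$los_max,
              pmax(cfg$los_min,
                   stats::rlnorm(n, cfg$los_meanlog, cfg$los_sdlog)))
  static <- tibble::tibble(
    visit_id = ids,
    age = round(pmin(100, pmax(18, stats::rnorm(n, 52, 20)))),
    weekend_triage = yn(0.28),
    department = sample(c("internal", "surgery", "pediatrics", "trauma"),
                        n, TRUE, c(0.50, 0.25, 0.15, 0.10)),
    ambulance = yn(0.15),
    sex = sample(c("F", "M"), n, TRUE),
    season = sample(c("spring", "summer", "autumn", "winter"), n, TRUE),
    dayzone = sample(c("day", "evening", "night"), n, TRUE,
                     c(0.45, 0.35, 0.20)),
    dayzone_discharge = sample(c("day", "evening", "night"), n, TRUE,
                               c(0.40, 0.35, 0.25)),
    weekend_discharge = yn(0.30),
    triage_level = sample(1:5, n, TRUE, c(0.05, 0.25, 0.45, 0.20, 0.05)),
    ed_los_hours = round(los, 2),
    household_income = round(stats::rlnorm(n, log(3e4), 0.5)),
    major_disease = yn(0.25),
    judgement_code = sample(sprintf("JC%02d", 1:8), n, TRUE),
    marital_status = sample(c("single", "married", "widowed", "divorced"),
                            n, TRUE, c(0.35, 0.45, 0.10, 0.10)),
    employment_status = sample(c("employed", "unemployed", "retired",
                                 "student"), n, TRUE,
                               c(0.50, 0.15, 0.25, 0.10)),
    nationality = sample(c("domestic", "foreign"), n, TRUE,
                         c(0.95, 0.05)),
    physician_sex = sample(c("F", "M"), n, TRUE, c(0.4, 0.6)),
    physician_age = round(stats::runif(n, 28, 65))
  )

  latent <- static_signal(static, cfg$effect_static) +
    static_signal_nonlinear(static, cfg$effect_static_nonlinear) +
    stats::rnorm(n)
  n_pos <- round(n * cfg$revisit_rate)
  n_hr <- round(n * cfg$highrisk_rate)
  ord <- order(latent, decreasing = TRUE)
  label_revisit <- integer(n)
  label_revisit[ord[seq_len(n_pos)]] <- 1L
  label_highrisk <- integer(n)
  if (n_hr > 0) label_highrisk[ord[seq_len(n_hr)]] <- 1L
  static$label_revisit <- label_revisit
  static$label_highrisk <- label_highrisk
  static$discharge_time <-
    as.POSIXct("2018-01-01 00:00:00", tz = "UTC") +
    round(stats::runif(n, 0, 365 * 24 * 3600))

  signs <- sign_catalogue()
  mu <- sign_pop_means()
  clamp <- sign_clamp()
  offsets <- matrix(stats::rnorm(n * length(signs)), n,
                    dimnames = list(NULL, signs))
  offsets <- sweep(offsets, 2, cfg$between_sd[signs], `*`)

  per_visit <- lapply(seq_len(n), function(i) {
    t0 <- -los[i] * 3600  # seconds before discharge
    times <- t0
    repeat {
      nxt <- times[length(times)] +
        stats::runif(1, cfg$interval_range[1], cfg$interval_range[2]) * 3600
      if (nxt >= 0) break
      times <- c(times, nxt)
    }
    times <- round(times)
    k <- length(times)
    shift <- numeric(length(signs))
    names(shift) <- signs
    if (label_revisit[i] == 1 && length(cfg$effect_dynamic) > 0) {
      shift[names(cfg$effect_dynamic)] <- cfg$effect_dynamic *
        (if (label_highrisk[i] == 1) cfg$highrisk_boost else 1)
    }
    vals <- lapply(signs, function(s) {
      v <- mu[[s]] + offsets[i, s] +
        stats::rnorm(k, sd = cfg$noise_sd[[s]])
      # sustained deterioration: the shift emerges after the arrival
      # (triage) measurement and persists to discharge
      if (k > 1 && shift[[s]] != 0) v[-1] <- v[-1] + shift[[s]]
      pmin(clamp$hi[[s]], pmax(clamp$lo[[s]], v))
    })
    tibble::tibble(
      visit_id = ids[i],
      time_min = rep(times / 60, length(signs)),
      sign = rep(signs, each = k),
      value = unlist(vals)
    )
  })
  vitals <- dplyr::bind_rows(per_visit)
  if (cfg$missing_extra_rate > 0) {
    n_drop <- round(cfg$missing_extra_rate * nrow(vitals))
    if (n_drop > 0) {
      vitals <- vitals[-sample(nrow(vitals), n_drop), , drop = FALSE]
    }
  }
  vitals <- dplyr::arrange(vitals, .data$visit_id, .data$time_min)

  truth <- tibble::tibble(
    visit_id = ids, latent = latent,
    label_revisit = label_revisit, label_highrisk = label_highrisk,
    dynamic_effect = label_revisit == 1 & length(cfg$effect_dynamic) > 0,
    static_effect = length(cfg$effect_static) > 0
  )
  structure(list(static = static, vitals = vitals, truth = truth,
                 config = cfg),
            class = "ed_cohort")
}

#' Corrupt a fraction of measurements with implausible values
#'
#' Replaces an exact count (`round(rate * n)`) of randomly chosen
#' measurements with out-of-range values (e.g. HR 999, SpO2 150) so the
#' outlier-removal stage can be exercised end to end.
#'
#' @param vitals Long-format vitals tibble.
#' @param rate Fraction in `[0, 0.1]`.
#' @param seed Integer seed.
#' @return `vitals` with corrupted values; the affected row indices are
#'   attached as attribute `"corrupted_rows"`.
#' @export
inject_anomalies <- function(vitals, rate = 0.01, seed = 1L) {
  stopifnot(rate >= 0, rate <= 0.1)
  if (rate == 0) {
    attr(vitals, "corrupted_rows") <- integer(0)
    return(vitals)
  }
  set.seed(seed)
  bad_vals <- c(HR = 999, RR = 99, SpO2 = 150, DBP = 999, BT = 99,
                SBP = 999)
  m <- round(rate * nrow(vitals))
  rows <- sort(sample(nrow(vitals), m))
  vitals$value[rows] <- bad_vals[vitals$sign[rows]]
  attr(vitals, "corrupted_rows") <- rows
  vitals
}

#' Write a cohort to the package's on-disk dialect
#'
#' Emits `static.csv`, `vitals.csv` (ISO-8601 timestamps), a
#' `ground_truth.json` when the cohort is synthetic, and a
#' `manifest.json` recording the sign catalogue, plausibility ranges and
#' feature types. [read_cohort()] on the written pair reproduces the
#' cohort.
#'
#' @param cohort An `ed_cohort`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the directory path.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cohort_to_files(cohort, file.path(dir, "static.csv"),
                  file.path(dir, "vitals.csv"))
  if (!is.null(cohort$truth)) {
    jsonlite::write_json(cohort$truth, file.path(dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  manifest <- list(signs = sign_catalogue(),
                   ranges = default_ranges(),
                   feature_types = static_feature_types())
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
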