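#' Positive-class augmentation configuration
#'
#' Settings for the training-time expansion of the rare positive class:
#' backward window shifting of the 24-hour sequence (up to
#' `max_shift_hours` one-hour shifts), Gaussian jitter with standard
#' deviation `noise_frac` of the per-channel training standard deviation,
#' multiplicative scaling by a factor drawn from
#' `[scale_low, scale_high]`, and oversampling of complete positive
#' samples to `oversample_target_ratio` positives per negative. Jitter and
#' scaling are each applied independently with probability
#' `transform_prob` to every shifted window.
#'
#' @param max_shift_hours Maximum backward shift in hours (default 8).
#' @param noise_frac Jitter sd as a fraction of the channel sd
#'   (default 0.12).
#' @param scale_low,scale_high Bounds of the multiplicative factor
#'   (default 0.9 / 1.1).
#' @param oversample_target_ratio Target positives:negatives ratio
#'   (default 1, i.e. balanced).
#' @param transform_prob Per-transform application probability for shifted
#'   windows (default 0.5).
#' @param seed Optional integer seed making augmentation reproducible.
#' @return An `augment_config` list.
#' @export
augment_config <- function(max_shift_hours = 8L, noise_frac = 0.12,
                           scale_low = 0.9, scale_high = 1.1,
                           oversample_target_ratio = 1,
                           transform_prob = 0.5, seed = NULL) {
  stopifnot(max_shift_hours >= 0, noise_frac >= 0,
            scale_low >= 0, scale_low <= scale_high,
            oversample_target_ratio > 0)
  structure(list(max_shift_hours = as.integer(max_shift_hours),
                 noise_frac = noise_frac, scale_low = scale_low,
                 scale_high = scale_high,
                 oversample_target_ratio = oversample_target_ratio,
                 transform_prob = transform_prob, seed = seed),
            class = "augment_config")
}

#' Extract a backward-shifted 24-hour window from an hourly grid
#'
#' Shift `k` moves the window `k` hours earlier relative to discharge: it
#' covers hours `[-(L+k), -k)`, so `k = 1` spans t = -25 h to t = -1 h.
#' The valid length is recomputed for the shifted window
#' (`lam = min(L, H - k)` for a grid spanning `H` hours). A window whose
#' span is empty or that contains no observed value carries no temporal
#' information and is discarded (returns `NULL`).
#'
#' @param grid Un-truncated hourly grid from [hourly_divide()].
#' @param k Integer shift in hours; `k = 0` reproduces
#'   [align_fixed_length()].
#' @param L Window length (default 24).
#' @return An `ed_seq` (pre-imputation, raw scale) or `NULL`.
#' @export
window_shift <- function(grid, k, L = 24L) {
  stopifnot(k >= 0)
  if (k == 0) return(align_fixed_length(grid, L))
  H <- nrow(grid)
  lam <- min(L, H - k)
  if (lam <= 0) return(NULL)
  mat <- matrix(NA_real_, nrow = L, ncol = ncol(grid),
                dimnames = list(NULL, colnames(grid)))
  # window row j (oldest first) holds bin (k + L - j); grid row for bin b
  # is H - b
  bins <- (k + lam - 1):k
  mat[(L - lam + 1):L, ] <- grid[H - bins, , drop = FALSE]
  if (all(is.na(mat))) return(NULL)
  new_ed_seq(mat, lam)
}

#' Add Gaussian jitter to the valid region of a normalized sequence
#'
#' Perturbs valid cells with zero-mean Gaussian noise of standard
#' deviation `noise_frac` (the sequence is in normalized space, where the
#' per-channel training sd is 1, so `noise_frac` of the channel sd equals
#' `noise_frac`). Pad cells and `lam` are untouched. Draws from the
#' current RNG stream.
#'
#' @param seq A normalized sequence: list with `mat` (L x 6) and `lam`.
#' @param noise_frac Noise sd in channel-sd units.
#' @return The jittered sequence.
#' @export
jitter_noise <- function(seq, noise_frac = 0.12) {
  if (noise_frac == 0 || seq$lam == 0) return(seq)
  L <- nrow(seq$mat)
  rows <- (L - seq$lam + 1):L
  nc <- ncol(seq$mat)
  seq$mat[rows, ] <- seq$mat[rows, ] +
    matrix(stats::rnorm(length(rows) * nc, sd = noise_frac),
           nrow = length(rows))
  seq
}

#' Scale the valid region of a sequence by one random factor
#'
#' Draws a single factor uniformly from `[low, high]` and multiplies every
#' valid cell by it, emulating patients whose overall vital-sign level is
#' systematically higher or lower. Pad cells are untouched.
#'
#' @param seq A normalized sequence (list with `mat`, `lam`).
#' @param low,high Bounds of the factor.
#' @return The scaled sequence, with the drawn factor attached as
#'   attribute `"scale_factor"`.
#' @export
scale_series <- function(seq, low = 0.9, high = 1.1) {
  stopifnot(low <= high)
  f <- stats::runif(1, low, high)
  if (seq$lam > 0) {
    L <- nrow(seq$mat)
    rows <- (L - seq$lam + 1):L
    seq$mat[rows, ] <- seq$mat[rows, ] * f
  }
  attr(seq, "scale_factor") <- f
  seq
}

# Internal: shuffled index vector that duplicates positives (sampling with
# replacement) until positives:negatives reaches target_ratio.
oversample_indices <- function(y, target_ratio = 1) {
  pos <- which(y == 1)
  neg <- which(y == 0)
  if (length(pos) == 0) {
    stop("training split has no positive samples; cannot oversample",
         call. = FALSE)
  }
  target_pos <- ceiling(length(neg) * target_ratio)
  extra <- max(0L, target_pos - length(pos))
  idx <- c(pos, neg,
           if (extra > 0) sample(pos, extra, replace = TRUE) else integer(0))
  sample(idx, length(idx))
}

#' Oversample positive rows of a labelled table
#'
#' Duplicates positive rows (sampling with replacement) until the
#' positives:negatives ratio reaches `target_ratio`; negatives are
#' untouched; the result is shuffled.
#'
#' @param records A data frame.
#' @param label_col Name of the 0/1 label column.
#' @param target_ratio Target positives per negative (default 1).
#' @return The expanded, shuffled tibble.
#' @examples
#' df <- tibble::tibble(x = 1:100, y = rep(c(1, 0), c(10, 90)))
#' table(oversample_static(df, "y")$y)  # 90 / 90
#' @export
oversample_static <- function(records, label_col = "label_revisit",
                              target_ratio = 1) {
  idx <- oversample_indices(records[[label_col]], target_ratio)
  tibble::as_tibble(records[idx, , drop = FALSE])
}

#' Expand the positive class of a training tensor set
#'
#' For every positive visit, emits the original 24-hour window plus up to
#' `max_shift_hours` backward-shifted windows (empty windows are
#' discarded). Each shifted window is re-imputed and normalized through
#' the full preprocessing path and is then independently jittered and/or
#' scaled, each with probability `transform_prob`. Every augmented
#' sequence is paired with a copy of the visit's static record and labels.
#' Negatives pass through once, byte-identical. Oversampling to the
#' configured ratio is a separate step applied by the training loop.
#'
#' @param tensors Training-split `ed_tensors` (originals, already encoded).
#' @param grids Named list of un-truncated hourly grids covering at least
#'   the positive visits (names are visit ids).
#' @param state The fitted `ed_encoding`.
#' @param cfg An [augment_config()].
#' @param task `"general_revisit"` or `"highrisk_revisit"`; selects which
#'   label defines the positive class.
#' @return An `ed_tensors` with the augmented samples appended.
#' @export
augment_positive_set <- function(tensors, grids, state, cfg = augment_config(),
                                 task = c("general_revisit",
                                          "highrisk_revisit")) {
  task <- match.arg(task)
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  y <- task_labels(tensors, task)
  pos <- which(y == 1)
  if (length(pos) == 0 || cfg$max_shift_hours == 0) return(tensors)

  L <- dim(tensors$dyn)[2]
  new_dyn <- list(); new_lam <- integer(0); new_idx <- integer(0)
  for (i in pos) {
    g <- grids[[tensors$visit_id[i]]]
    if (is.null(g)) next
    for (k in seq_len(cfg$max_shift_hours)) {
      w <- window_shift(g, k, L)
      if (is.null(w)) next
      ns <- normalize_sequence(state, w)
      if (stats::runif(1) < cfg$transform_prob) {
        ns <- jitter_noise(ns, cfg$noise_frac)
      }
      if (stats::runif(1) < cfg$transform_prob) {
        ns <- scale_series(ns, cfg$scale_low, cfg$scale_high)
      }
      new_dyn[[length(new_dyn) + 1L]] <- ns$mat
      new_lam <- c(new_lam, ns$lam)
      new_idx <- c(new_idx, i)
    }
  }
  if (length(new_idx) == 0) return(tensors)

  extra <- subset_tensors(tensors, new_idx)
  d <- array(0, dim = c(length(new_idx), L, dim(tensors$dyn)[3]),
             dimnames = dimnames(tensors$dyn))
  for (j in seq_along(new_idx)) d[j, , ] <- new_dyn[[j]]
  extra$dyn <- d
  extra$lam <- new_lam
  bind_tensors(tensors, extra)
}

task_labels <- function(tensors, task) {
  if (task == "highrisk_revisit") tensors$y_highrisk else tensors$y_revisit
}
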