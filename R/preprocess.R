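#' Bin irregular vital-sign measurements into one-hour intervals
#'
#' Hour bins are anchored to discharge: bin `k` covers the half-open
#' interval `[-(k+1) h, -k h)` before discharge (a measurement at the
#' discharge instant falls in bin 0). Multiple measurements of the same
#' sign inside one bin are averaged; bins with no measurement are missing.
#' The grid spans from the hour of the earliest measurement up to the
#' discharge hour.
#'
#' @param vitals Long-format vitals tibble (`visit_id`, `time_min` less than or
#'   equal to 0, `sign`, `value`), already cleaned by [remove_outliers()].
#' @param visit_ids Optional character vector of visits that must appear in
#'   the result even when they have no measurements (their grid has zero
#'   rows).
#' @return A named list of hourly grids, one per visit: a numeric matrix
#'   with `H` rows (oldest hour first, discharge hour last) and one column
#'   per sign in [sign_catalogue()] order.
#' @export
hourly_divide <- function(vitals, visit_ids = NULL) {
  signs <- sign_catalogue()
  obs <- vitals[!is.na(vitals$value), , drop = FALSE]
  obs$bin <- pmax(0, floor(-obs$time_min / 60))
  agg <- dplyr::summarise(
    dplyr::group_by(obs, .data$visit_id, .data$sign, .data$bin),
    value = mean(.data$value), .groups = "drop")

  ids <- visit_ids
  if (is.null(ids)) ids <- unique(vitals$visit_id)
  ids <- as.character(ids)

  by_visit <- split(agg, factor(agg$visit_id, levels = ids))
  grids <- lapply(ids, function(id) {
    g <- by_visit[[id]]
    if (is.null(g) || nrow(g) == 0) {
      m <- matrix(NA_real_, nrow = 0, ncol = length(signs),
                  dimnames = list(NULL, signs))
      return(m)
    }
    H <- max(g$bin) + 1L
    m <- matrix(NA_real_, nrow = H, ncol = length(signs),
                dimnames = list(NULL, signs))
    # row i holds bin (H - i): oldest hour first, discharge hour last
    m[cbind(H - g$bin, match(g$sign, signs))] <- g$value
    m
  })
  names(grids) <- ids
  grids
}

new_ed_seq <- function(mat, lam) {
  L <- nrow(mat)
  structure(list(mat = mat, lam = as.integer(lam),
                 mask = c(rep(FALSE, L - lam), rep(TRUE, lam))),
            class = "ed_seq")
}

#' Align an hourly grid to a fixed-length discharge-anchored sequence
#'
#' Grids shorter than `L` hours are padded on the leading (oldest) side so
#' the observed data always abut discharge; grids longer than `L` hours are
#' truncated to the most recent `L` hours. The unpadded valid length
#' `lam = min(L, H)` is carried alongside the matrix and later gates the
#' fusion of the model's branches.
#'
#' @param grid An hourly grid matrix from [hourly_divide()].
#' @param L Fixed sequence length in hours (default 24).
#' @return An `ed_seq`: list with `mat` (`L` x 6, pad cells `NA` until
#'   normalization), `lam`, and logical `mask` marking the `lam` trailing
#'   valid steps.
#' @export
align_fixed_length <- function(grid, L = 24L) {
  stopifnot(L >= 1)
  signs <- colnames(grid)
  H <- nrow(grid)
  lam <- min(L, H)
  mat <- matrix(NA_real_, nrow = L, ncol = ncol(grid),
                dimnames = list(NULL, signs))
  if (H > 0) {
    mat[(L - lam + 1):L, ] <- grid[(H - lam + 1):H, , drop = FALSE]
  }
  new_ed_seq(mat, lam)
}

#' Impute a fixed-length sequence by forward- then backward-filling
#'
#' Within the valid region each channel is forward-filled in time order and
#' remaining leading gaps are backward-filled. A channel with no
#' observation at all in the valid region is filled with the training-
#' population channel mean, which is neutral (0) after z-scoring. The pad
#' region is untouched.
#'
#' @param seq An `ed_seq` from [align_fixed_length()].
#' @param channel_means Named numeric vector of per-sign fallback means on
#'   the raw scale (training population).
#' @return The imputed `ed_seq`; no missing cell remains in the valid
#'   region.
#' @export
impute_sequence <- function(seq, channel_means) {
  lam <- seq$lam
  if (lam == 0) return(seq)
  L <- nrow(seq$mat)
  rows <- (L - lam + 1):L
  for (j in seq_len(ncol(seq$mat))) {
    v <- seq$mat[rows, j]
    if (all(is.na(v))) {
      seq$mat[rows, j] <- channel_means[[colnames(seq$mat)[j]]]
      next
    }
    v <- ffill(v)
    v <- rev(ffill(rev(v)))
    seq$mat[rows, j] <- v
  }
  seq
}

ffill <- function(v) {
  ok <- !is.na(v)
  if (!any(ok)) return(v)
  idx <- cumsum(ok)
  filled <- v[ok][pmax(idx, 1)]
  filled[idx == 0] <- NA_real_
  filled
}
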