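#' Fit encoding and normalization statistics on the training split
#'
#' Categorical features get deterministic vocabularies (lexicographic
#' order, integer codes 0..n-1, with the reserved code n for categories
#' unseen at training time). Numeric static features and dynamic channels
#' get z-scoring statistics: mean and population standard deviation
#' (divisor n) computed on training data only, so no information leaks from
#' validation or test. A constant feature is flagged and mapped to 0.
#'
#' @param static_train Training-split static tibble.
#' @param seqs_train List of pre-imputation `ed_seq` objects for the same
#'   split; dynamic statistics use the observed (valid, non-missing) cells.
#' @param feature_types Tibble mapping feature to `"numeric"` or
#'   `"categorical"`; defaults to [static_feature_types()].
#' @return An `ed_encoding` object with `vocab`, `num_stats`, `dyn_stats`.
#' @export
fit_encoding <- function(static_train, seqs_train,
                         feature_types = static_feature_types()) {
  types <- feature_types
  miss <- setdiff(types$feature, names(static_train))
  if (length(miss) > 0) {
    stop("static table is missing feature column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  cat_feats <- types$feature[types$type == "categorical"]
  num_feats <- types$feature[types$type == "numeric"]

  vocab <- lapply(cat_feats, function(f) {
    sort(unique(as.character(static_train[[f]])), method = "radix")
  })
  names(vocab) <- cat_feats

  num_stats <- lapply(num_feats, function(f) {
    x <- as.numeric(static_train[[f]])
    x <- x[!is.na(x)]
    m <- mean(x)
    s <- sqrt(mean((x - m)^2))  # population convention
    list(mean = m, sd = s, constant = s == 0)
  })
  names(num_stats) <- num_feats

  signs <- sign_catalogue()
  pooled <- lapply(signs, function(s) numeric(0))
  names(pooled) <- signs
  for (sq in seqs_train) {
    if (sq$lam == 0) next
    m <- sq$mat[sq$mask, , drop = FALSE]
    for (s in signs) {
      v <- m[, s]
      pooled[[s]] <- c(pooled[[s]], v[!is.na(v)])
    }
  }
  dyn_stats <- lapply(pooled, function(v) {
    if (length(v) == 0) return(list(mean = 0, sd = 1, constant = TRUE))
    m <- mean(v)
    s <- sqrt(mean((v - m)^2))
    list(mean = m, sd = s, constant = s == 0)
  })

  structure(list(vocab = vocab, num_stats = num_stats,
                 dyn_stats = dyn_stats,
                 cat_features = cat_feats, num_features = num_feats),
            class = "ed_encoding")
}

#' @export
print.ed_encoding <- function(x, ...) {
  cat(sprintf("<ed_encoding> %d categorical, %d numeric static features, %d dynamic channels\n",
              length(x$cat_features), length(x$num_features),
              length(x$dyn_stats)))
  invisible(x)
}

encode_value <- function(x, stats) {
  if (stats$constant || stats$sd == 0) return(rep(0, length(x)))
  (x - stats$mean) / stats$sd
}

#' Apply a fitted encoding to static rows and aligned sequences
#'
#' Numeric features and dynamic channels are z-scored with the training
#' statistics; categoricals are integer-encoded with unseen categories
#' mapped to the reserved unknown index; sequences are imputed (forward /
#' backward fill with training-mean fallback) and their pad cells set to 0,
#' the channel mean in normalized space.
#'
#' @param state An `ed_encoding` from [fit_encoding()].
#' @param static Static tibble for any split.
#' @param seqs List of pre-imputation `ed_seq` objects, same order as
#'   `static` rows.
#' @return An `ed_tensors` list: `num` (n x n_num matrix), `cat`
#'   (n x n_cat integer matrix, 0-based codes), `dyn` (n x 24 x 6 array),
#'   `lam` (integer vector), `y_revisit`, `y_highrisk`, `visit_id`.
#' @export
apply_encoding <- function(state, static, seqs) {
  stopifnot(inherits(state, "ed_encoding"), nrow(static) == length(seqs))
  n <- nrow(static)
  signs <- sign_catalogue()

  num <- matrix(0, n, length(state$num_features),
                dimnames = list(NULL, state$num_features))
  for (f in state$num_features) {
    x <- as.numeric(static[[f]])
    x[is.na(x)] <- state$num_stats[[f]]$mean
    num[, f] <- encode_value(x, state$num_stats[[f]])
  }

  cat_m <- matrix(0L, n, length(state$cat_features),
                  dimnames = list(NULL, state$cat_features))
  for (f in state$cat_features) {
    voc <- state$vocab[[f]]
    idx <- match(as.character(static[[f]]), voc) - 1L
    idx[is.na(idx)] <- length(voc)  # reserved unknown index
    cat_m[, f] <- idx
  }

  L <- if (length(seqs) > 0) nrow(seqs[[1]]$mat) else 24L
  dyn <- array(0, dim = c(n, L, length(signs)),
               dimnames = list(NULL, NULL, signs))
  lam <- integer(n)
  for (i in seq_len(n)) {
    ns <- normalize_sequence(state, seqs[[i]])
    dyn[i, , ] <- ns$mat
    lam[i] <- ns$lam
  }

  structure(list(
    num = num, cat = cat_m, dyn = dyn, lam = lam,
    y_revisit  = as.integer(static$label_revisit),
    y_highrisk = as.integer(static$label_highrisk),
    visit_id   = as.character(static$visit_id)
  ), class = "ed_tensors")
}

#' Serialize an encoding to JSON (and back)
#'
#' Inference must reuse training statistics bit-exactly, so the fitted
#' encoding round-trips through JSON with full numeric precision.
#'
#' @param state An `ed_encoding`.
#' @param path File path to write to / read from.
#' @return `encoding_from_json()` returns the restored `ed_encoding`.
#' @export
encoding_to_json <- function(state, path) {
  writeLines(jsonlite::serializeJSON(unclass(state), digits = I(17)),
             path)
  invisible(path)
}

#' @rdname encoding_to_json
#' @export
encoding_from_json <- function(path) {
  x <- jsonlite::unserializeJSON(paste(readLines(path), collapse = "\n"))
  structure(x, class = "ed_encoding")
}

# Internal: impute one pre-imputation ed_seq with training channel means,
# z-score each channel, and set pad cells to 0 (the channel mean in
# normalized space).
normalize_sequence <- function(state, seq) {
  signs <- sign_catalogue()
  chan_means <- vapply(state$dyn_stats, function(s) s$mean, numeric(1))
  sq <- impute_sequence(seq, chan_means)
  m <- sq$mat
  for (j in seq_along(signs)) {
    m[, j] <- encode_value(m[, j], state$dyn_stats[[signs[j]]])
  }
  m[is.na(m)] <- 0
  L <- nrow(m)
  if (sq$lam < L) m[seq_len(L - sq$lam), ] <- 0
  list(mat = m, lam = sq$lam)
}

n_tensors <- function(tensors) length(tensors$lam)

subset_tensors <- function(tensors, idx) {
  structure(list(
    num = tensors$num[idx, , drop = FALSE],
    cat = tensors$cat[idx, , drop = FALSE],
    dyn = tensors$dyn[idx, , , drop = FALSE],
    lam = tensors$lam[idx],
    y_revisit  = tensors$y_revisit[idx],
    y_highrisk = tensors$y_highrisk[idx],
    visit_id   = tensors$visit_id[idx]
  ), class = "ed_tensors")
}

bind_tensors <- function(a, b) {
  structure(list(
    num = rbind(a$num, b$num),
    cat = rbind(a$cat, b$cat),
    dyn = {
      d <- array(0, dim = c(dim(a$dyn)[1] + dim(b$dyn)[1], dim(a$dyn)[2],
                            dim(a$dyn)[3]), dimnames = dimnames(a$dyn))
      d[seq_len(dim(a$dyn)[1]), , ] <- a$dyn
      d[dim(a$dyn)[1] + seq_len(dim(b$dyn)[1]), , ] <- b$dyn
      d
    },
    lam = c(a$lam, b$lam),
    y_revisit  = c(a$y_revisit, b$y_revisit),
    y_highrisk = c(a$y_highrisk, b$y_highrisk),
    visit_id   = c(a$visit_id, b$visit_id)
  ), class = "ed_tensors")
}
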