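# Shared fixtures and independent oracles. Oracles are deliberately
# written as plain loops, independent of the package's vectorized paths.

# small encoding state for driving the network directly
make_state <- function(n_num = 2, n_cat = 2, vocab_sizes = c(3, 4)) {
  num_f <- paste0("n", seq_len(n_num))
  cat_f <- paste0("c", seq_len(n_cat))
  state <- list(
    vocab = lapply(stats::setNames(seq_len(n_cat), cat_f),
                   function(i) letters[seq_len(vocab_sizes[i])]),
    num_stats = lapply(stats::setNames(seq_len(n_num), num_f),
                       function(i) list(mean = 0, sd = 1,
                                        constant = FALSE)),
    dyn_stats = lapply(stats::setNames(seq_along(sign_catalogue()),
                                       sign_catalogue()),
                       function(i) list(mean = 0, sd = 1,
                                        constant = FALSE)),
    cat_features = cat_f, num_features = num_f
  )
  class(state) <- "ed_encoding"
  state
}

tiny_model_config <- function(...) {
  model_config(tcn = list(levels = 3L, kernel = 3L, channels = 5L,
                          dropout = 0),
               tabular = list(token_dim = 6L, depth = 1L, heads = 2L,
                              dropout = 0),
               head = c(8L), ...)
}

small_model_config <- function(...) {
  model_config(tcn = list(levels = 3L, kernel = 3L, channels = 12L,
                          dropout = 0.1),
               tabular = list(token_dim = 8L, depth = 1L, heads = 2L,
                              dropout = 0.1),
               head = c(32L, 16L), ...)
}

random_batch <- function(state, B, seed = 1, lam = NULL) {
  set.seed(seed)
  vs <- vapply(state$vocab, length, integer(1))
  list(dyn = array(stats::rnorm(B * 24 * 6), c(B, 24, 6)),
       num = matrix(stats::rnorm(B * length(state$num_features)), B),
       cat = vapply(vs, function(v) sample(0:v, B, TRUE),
                    integer(B)) |> matrix(nrow = B),
       lam = if (is.null(lam)) sample(0:24, B, TRUE) else lam)
}

# random irregular vital stream for one visit (long tibble)
random_stream <- function(seed, max_span_h = 40, p_missing = 0.15) {
  set.seed(seed)
  n <- sample(0:12, 1)
  if (n == 0) {
    return(tibble::tibble(visit_id = "v", time_min = numeric(0),
                          sign = character(0), value = numeric(0)))
  }
  signs <- sample(sign_catalogue(), n, TRUE)
  t <- -stats::runif(n, 0, max_span_h * 60)
  v <- stats::rnorm(n, 80, 20)
  v[stats::runif(n) < p_missing] <- NA_real_
  tibble::tibble(visit_id = "v", time_min = t, sign = signs, value = v)
}

# Brute-force reference for hourly division -> fixed-length alignment ->
# forward/backward-fill imputation, written with explicit loops.
ref_align_impute <- function(stream, channel_means, L = 24) {
  signs <- sign_catalogue()
  obs <- stream[!is.na(stream$value), , drop = FALSE]
  if (nrow(obs) == 0) {
    return(list(mat = matrix(NA_real_, L, 6,
                             dimnames = list(NULL, signs)), lam = 0L))
  }
  bins <- floor(-obs$time_min / 60)
  bins[obs$time_min == 0] <- 0
  H <- max(bins) + 1
  grid <- matrix(NA_real_, H, 6, dimnames = list(NULL, signs))
  for (b in 0:(H - 1)) {
    for (s in signs) {
      sel <- bins == b & obs$sign == s
      if (any(sel)) grid[H - b, s] <- mean(obs$value[sel])
    }
  }
  lam <- min(L, H)
  mat <- matrix(NA_real_, L, 6, dimnames = list(NULL, signs))
  for (r in 1:lam) mat[L - lam + r, ] <- grid[H - lam + r, ]
  # imputation inside valid region
  for (s in signs) {
    col <- mat[(L - lam + 1):L, s]
    if (all(is.na(col))) {
      col[] <- channel_means[[s]]
    } else {
      for (i in seq_along(col)) {
        if (is.na(col[i]) && i > 1) col[i] <- col[i - 1]
      }
      for (i in rev(seq_along(col))) {
        if (is.na(col[i]) && i < length(col)) col[i] <- col[i + 1]
      }
    }
    mat[(L - lam + 1):L, s] <- col
  }
  list(mat = mat, lam = as.integer(lam))
}

# package path for the same composition
pkg_align_impute <- function(stream, channel_means, L = 24) {
  g <- hourly_divide(stream, visit_ids = "v")[["v"]]
  sq <- align_fixed_length(g, L)
  sq <- impute_sequence(sq, channel_means)
  list(mat = sq$mat, lam = sq$lam)
}

# all-pairs AUROC oracle with half credit for ties
auroc_pairs <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) {
    for (q in neg) {
      tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
    }
  }
  tot / (length(pos) * length(neg))
}

# step-integrated precision-recall oracle: explicit loop over distinct
# thresholds in decreasing order
auprc_loop <- function(scores, labels) {
  thr <- sort(unique(scores), decreasing = TRUE)
  n_pos <- sum(labels == 1)
  area <- 0
  prev_rec <- 0
  for (t in thr) {
    alert <- scores >= t
    rec <- sum(labels == 1 & alert) / n_pos
    prec <- sum(labels == 1 & alert) / sum(alert)
    area <- area + (rec - prev_rec) * prec
    prev_rec <- rec
  }
  area
}

# small cohort with long positive stays (every shifted window non-empty)
long_stay_cohort <- function(n = 40, n_pos = 5, seed = 2) {
  cfg <- sim_config(n_visits = 100, seed = seed)
  coh <- generate_cohort(cfg)
  coh
}
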