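# Low-level building blocks for the hybrid network. All layers operate on
# flat matrices with an explicit "group-major" row layout: a batch of B
# samples with T positions is stored as a (B*T) x C matrix whose rows
# b + (t-1)*B hold position t of sample b. Shifting in time (causal
# convolution) and per-token operations then reduce to row-block slicing,
# which keeps everything vectorized.

rmat <- function(nr, nc, sd) {
  matrix(stats::rnorm(nr * nc, sd = sd), nr, nc)
}

he_init <- function(nr, nc) rmat(nr, nc, sqrt(2 / nr))

sigmoid <- function(x) 1 / (1 + exp(-x))

relu <- function(x) (x > 0) * x

add_bias <- function(m, b) {
  m + matrix(b, nrow(m), length(b), byrow = TRUE)
}

# Inverted dropout; returns list(out, mask). mask is NULL in eval mode.
dropout_fwd <- function(x, p, training) {
  if (!training || p <= 0) return(list(out = x, mask = NULL))
  mask <- (matrix(stats::runif(length(x)), nrow(x)) >= p) / (1 - p)
  list(out = x * mask, mask = mask)
}

dropout_bwd <- function(dout, mask) {
  if (is.null(mask)) dout else dout * mask
}

layernorm_fwd <- function(x, g, b, eps = 1e-5) {
  mu <- rowMeans(x)
  xc <- x - mu
  inv <- 1 / sqrt(rowMeans(xc * xc) + eps)
  xhat <- xc * inv
  out <- add_bias(xhat * matrix(g, nrow(x), length(g), byrow = TRUE), b)
  list(out = out, xhat = xhat, inv = inv)
}

layernorm_bwd <- function(dout, cache, g) {
  xhat <- cache$xhat
  dxhat <- dout * matrix(g, nrow(dout), length(g), byrow = TRUE)
  dx <- cache$inv *
    (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat))
  list(dx = dx, dg = colSums(dout * xhat), db = colSums(dout))
}

# Row-wise softmax with max subtraction for stability.
softmax_rows <- function(s) {
  mx <- s[cbind(seq_len(nrow(s)), max.col(s, ties.method = "first"))]
  e <- exp(s - mx)
  e / rowSums(e)
}

softmax_rows_bwd <- function(dp, p) {
  p * (dp - rowSums(dp * p))
}

#' Focal loss for imbalanced binary classification
#'
#' The objective `FL(p_t) = -alpha * (1 - p_t)^gamma * log(p_t)`, where
#' `p_t` is the predicted probability of the true class. The modulating
#' factor `(1 - p_t)^gamma` down-weights well-classified examples so
#' training concentrates on hard, rare positives. With `alpha = 1`,
#' `gamma = 0` it reduces to binary cross-entropy. Probabilities are
#' clamped to `[eps, 1 - eps]` so the log is always finite.
#'
#' @param p Predicted probabilities in `[0, 1]`.
#' @param y Binary labels (0/1), same length as `p`.
#' @param alpha Weighting factor in `(0, 1]` (default 0.4).
#' @param gamma Focusing exponent `>= 0` (default 2).
#' @param eps Clamping constant (default 1e-7).
#' @param reduce If `TRUE` (default) return the batch mean, else the
#'   per-sample losses.
#' @return Loss value(s).
#' @examples
#' focal_loss(0.5, 1, alpha = 0.4, gamma = 2)  # 0.4 * 0.25 * log(2)
#' @export
focal_loss <- function(p, y, alpha = 0.4, gamma = 2, eps = 1e-7,
                       reduce = TRUE) {
  stopifnot(alpha > 0, alpha <= 1, gamma >= 0)
  pt <- ifelse(y == 1, p, 1 - p)
  pt <- pmin(pmax(pt, eps), 1 - eps)
  l <- -alpha * (1 - pt)^gamma * log(pt)
  if (reduce) mean(l) else l
}

# d(mean focal loss)/d(logit). Derived from pt = y*p + (1-y)*(1-p),
# dp/dlogit = p(1-p), dpt/dp = 2y - 1.
focal_loss_grad_logit <- function(p, y, alpha = 0.4, gamma = 2,
                                  eps = 1e-7) {
  pt <- ifelse(y == 1, p, 1 - p)
  pt <- pmin(pmax(pt, eps), 1 - eps)
  dl_dpt <- -alpha * (-gamma * (1 - pt)^(gamma - 1) * log(pt) +
                        (1 - pt)^gamma / pt)
  dl_dpt * (2 * y - 1) * p * (1 - p) / length(p)
}

# ---- Adam ------------------------------------------------------------

# Parameters are nested lists of numeric arrays; the optimizer state
# mirrors that structure.
adam_init <- function(params) {
  walk <- function(p) {
    if (is.list(p)) return(lapply(p, walk))
    if (is.numeric(p)) return(list(m = p * 0, v = p * 0))
    NULL
  }
  list(mv = walk(params), t = 0L)
}

adam_step <- function(params, grads, state, lr = 5e-4, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  c1 <- 1 - beta1^t
  c2 <- 1 - beta2^t
  walk <- function(p, g, mv) {
    if (is.numeric(p)) {
      mv$m <- beta1 * mv$m + (1 - beta1) * g
      mv$v <- beta2 * mv$v + (1 - beta2) * g * g
      p <- p - lr * (mv$m / c1) / (sqrt(mv$v / c2) + eps)
      return(list(p = p, mv = mv))
    }
    keys <- if (!is.null(names(p)) && all(names(p) != "")) {
      names(p)
    } else {
      seq_along(p)
    }
    for (i in keys) {
      gi <- if (is.character(i) && !i %in% names(g)) NULL else g[[i]]
      if (is.null(p[[i]]) || is.null(gi)) next
      res <- walk(p[[i]], gi, mv[[i]])
      p[[i]] <- res$p
      mv[[i]] <- res$mv
    }
    list(p = p, mv = mv)
  }
  res <- walk(params, grads, state$mv)
  list(params = res$p, state = list(mv = res$mv, t = t))
}

# Sum of squared gradient leaves (diagnostics / divergence checks).
grad_norm <- function(grads) {
  s <- 0
  walk <- function(g) {
    if (is.list(g)) { lapply(g, walk); return(invisible()) }
    if (is.numeric(g)) s <<- s + sum(g * g)
    invisible()
  }
  walk(grads)
  sqrt(s)
}
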