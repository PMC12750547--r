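#' Configuration of the hybrid revisit network
#'
#' The model has two branches: a temporal convolutional encoder over the
#' 24 x 6 vital-sign sequence and a feature-tokenizer attention encoder
#' over the 19 triage features. Their embeddings are concatenated, scaled
#' by a gate driven by the unpadded valid length lambda, and classified by
#' an MLP head ending in a single logit. The dilated stack's receptive
#' field `1 + 2*(kernel - 1)*(2^levels - 1)` must cover the 24-step
#' sequence. `use_tcn`, `use_tabular` and `use_lambda` are the ablation
#' switches; at least one branch must stay enabled.
#'
#' @param tcn List: `levels`, `kernel`, `channels`, `dropout`.
#' @param tabular List: `token_dim`, `depth`, `heads`, `dropout`.
#' @param head Integer vector of MLP hidden sizes.
#' @param use_tcn,use_tabular,use_lambda Ablation switches.
#' @return A validated `model_config` list.
#' @export
model_config <- function(tcn = list(levels = 4L, kernel = 3L,
                                    channels = 64L, dropout = 0.2),
                         tabular = list(token_dim = 64L, depth = 3L,
                                        heads = 8L, dropout = 0.1),
                         head = c(128L, 64L),
                         use_tcn = TRUE, use_tabular = TRUE,
                         use_lambda = TRUE) {
  if (!use_tcn && !use_tabular) {
    stop("at least one branch (TCN or tabular) must be enabled",
         call. = FALSE)
  }
  if (use_tcn) {
    rf <- tcn_receptive_field(tcn$levels, tcn$kernel)
    if (rf < 24) {
      stop(sprintf(paste0("receptive field %d < 24: increase levels or ",
                          "kernel so the stack sees the whole sequence"),
                   rf), call. = FALSE)
    }
  }
  if (use_tabular && tabular$token_dim %% tabular$heads != 0) {
    stop("token_dim must be divisible by heads", call. = FALSE)
  }
  structure(list(tcn = tcn, tabular = tabular, head = as.integer(head),
                 use_tcn = use_tcn, use_tabular = use_tabular,
                 use_lambda = use_lambda),
            class = "model_config")
}

#' Initialize a hybrid revisit network
#'
#' @param cfg A [model_config()].
#' @param state The fitted `ed_encoding` (supplies vocabulary sizes and
#'   feature counts).
#' @param seed Integer seed for weight initialization.
#' @return An `ed_net` object holding the config, the encoding reference
#'   and the parameter list.
#' @export
init_revisit_net <- function(cfg, state, seed = 1L) {
  set.seed(seed)
  d_concat <- 0L
  params <- list()
  if (cfg$use_tcn) {
    params$tcn <- tcn_init(length(sign_catalogue()), cfg$tcn)
    # TCN embedding plus per-channel delta and sd summary indicators
    d_concat <- d_concat + cfg$tcn$channels + 2L * length(sign_catalogue())
  }
  if (cfg$use_tabular) {
    params$ft <- ft_init(state, cfg$tabular)
    d_concat <- d_concat + cfg$tabular$token_dim
  }
  if (cfg$use_lambda) {
    params$gate <- list(a = 1, b = 0)
  }
  sizes <- c(d_concat, cfg$head, 1L)
  n_lay <- length(sizes) - 1L
  params$head <- lapply(seq_len(n_lay), function(i) {
    # near-zero final layer: initial logits start around 0 instead of in
    # a saturated tail of the logistic
    W <- if (i == n_lay) rmat(sizes[i], sizes[i + 1L], 0.01)
         else he_init(sizes[i], sizes[i + 1L])
    list(W = W, b = numeric(sizes[i + 1L]))
  })
  structure(list(cfg = cfg, params = params,
                 num_features = state$num_features,
                 cat_features = state$cat_features),
            class = "ed_net")
}

#' Count trainable parameters of a network
#' @param net An `ed_net`.
#' @return Integer parameter count.
#' @export
n_params <- function(net) {
  s <- 0L
  walk <- function(p) {
    if (is.numeric(p)) { s <<- s + length(p); return(invisible()) }
    if (is.list(p)) lapply(p, walk)
    invisible()
  }
  walk(net$params)
  s
}

#' @export
print.ed_net <- function(x, ...) {
  branches <- c(if (x$cfg$use_tcn) "TCN", if (x$cfg$use_tabular) "FT",
                if (x$cfg$use_lambda) "lambda-gate")
  cat(sprintf("<ed_net> %s | %s parameters\n",
              paste(branches, collapse = " + "),
              format(n_params(x), big.mark = ",")))
  invisible(x)
}

# Differentiable per-channel summary indicators of the valid region:
# delta (last valid step minus first valid step) and standard deviation.
# They join the dynamic branch embedding at fusion.
dyn_summary_fwd <- function(dyn, lam) {
  B <- dim(dyn)[1]
  T_len <- dim(dyn)[2]
  C <- dim(dyn)[3]
  delta <- matrix(0, B, C)
  sdev <- matrix(0, B, C)
  first <- pmin(T_len, pmax(1L, T_len - lam + 1L))
  mu <- matrix(0, B, C)
  for (c in seq_len(C)) {
    x <- dyn[, , c, drop = TRUE]
    if (is.null(dim(x))) x <- matrix(x, nrow = B)
    delta[, c] <- ifelse(lam >= 2, x[cbind(seq_len(B), rep(T_len, B))] -
                           x[cbind(seq_len(B), first)], 0)
    # masked moments over the valid region
    mask <- outer(rep(1, B), seq_len(T_len))
    mask <- mask > (T_len - lam)  # B x T valid indicator
    s1 <- rowSums(x * mask)
    m <- ifelse(lam > 0, s1 / pmax(lam, 1L), 0)
    v <- rowSums((x - m)^2 * mask) / pmax(lam, 1L)
    mu[, c] <- m
    sdev[, c] <- ifelse(lam >= 2, sqrt(v), 0)
  }
  list(S = cbind(delta, sdev), mu = mu, sdev = sdev, first = first)
}

dyn_summary_bwd <- function(dS, dyn, lam, cache_s) {
  B <- dim(dyn)[1]
  T_len <- dim(dyn)[2]
  C <- dim(dyn)[3]
  g <- array(0, dim(dyn))
  first <- cache_s$first
  mask_t <- outer(rep(1, B), seq_len(T_len)) > (T_len - lam)
  for (c in seq_len(C)) {
    gd <- dS[, c]
    gs <- dS[, C + c]
    ok <- lam >= 2
    # delta: +g at the last step, -g at the first valid step
    g[cbind(seq_len(B), rep(T_len, B), rep(c, B))] <-
      g[cbind(seq_len(B), rep(T_len, B), rep(c, B))] + gd * ok
    g[cbind(seq_len(B), first, rep(c, B))] <-
      g[cbind(seq_len(B), first, rep(c, B))] - gd * ok
    # sd: d sd / d x_t = (x_t - mean) / (lam * sd) on valid steps
    x <- matrix(dyn[, , c], nrow = B)
    denom <- pmax(lam, 1L) * pmax(cache_s$sdev[, c], 1e-8)
    gsd <- (x - cache_s$mu[, c]) / denom * (gs * ok)
    g[, , c] <- g[, , c] + gsd * mask_t
  }
  g
}

# batch: list(dyn B x T x 6 array, num, cat, lam). Returns p, logit, cache.
net_forward <- function(net, batch, training = FALSE) {
  cfg <- net$cfg
  p <- net$params
  B <- length(batch$lam)
  parts <- list()
  cache <- list(B = B)

  if (cfg$use_tcn) {
    T_len <- dim(batch$dyn)[2]
    m0 <- matrix(batch$dyn, nrow = B * T_len)  # time-major (B*T) x 6
    tf <- tcn_fwd(p$tcn, m0, B, T_len, cfg$tcn$dropout, training)
    sm <- dyn_summary_fwd(batch$dyn, batch$lam)
    parts$dyn <- cbind(tf$emb, sm$S)
    cache$tcn <- tf$caches
    cache$m0 <- m0
    cache$T_len <- T_len
    cache$summary <- sm
    cache$n_tcn <- ncol(tf$emb)
    cache$dyn_in <- batch$dyn
    cache$lam <- batch$lam
  }
  if (cfg$use_tabular) {
    ff <- ft_fwd(p$ft, batch$num, batch$cat, cfg$tabular, training)
    parts$stat <- ff$emb
    cache$ft <- ff$cache
    cache$attn <- ff$attn
  }
  Z <- do.call(cbind, parts)
  cache$Z <- Z
  cache$d_dyn <- if (cfg$use_tcn) ncol(parts$dyn) else 0L

  if (cfg$use_lambda) {
    ln <- batch$lam / 24
    w <- sigmoid(p$gate$a * ln + p$gate$b)
    Zs <- Z * w
    cache$gate <- list(ln = ln, w = w)
  } else {
    Zs <- Z
  }

  h <- Zs
  hs <- list()
  for (i in seq_along(p$head)) {
    a <- add_bias(h %*% p$head[[i]]$W, p$head[[i]]$b)
    if (i < length(p$head)) a <- relu(a)
    hs[[i]] <- list(input = h, act = a)
    h <- a
  }
  logit <- as.numeric(h)
  prob <- sigmoid(logit)
  cache$head <- hs
  cache$Zs <- Zs
  list(p = prob, logit = logit, cache = cache,
       fusion_weight = if (cfg$use_lambda) cache$gate$w else NULL)
}

# dlogit: numeric(B). Returns grads mirroring net$params; optionally the
# gradient w.r.t. the dynamic input as a B x T x 6 array.
net_backward <- function(net, cache, dlogit, need_input_grad = FALSE) {
  cfg <- net$cfg
  p <- net$params
  B <- cache$B
  grads <- list()

  d <- matrix(dlogit, ncol = 1)
  g_head <- vector("list", length(p$head))
  for (i in rev(seq_along(p$head))) {
    layer <- cache$head[[i]]
    if (i < length(p$head)) d <- d * (layer$act > 0)
    g_head[[i]] <- list(W = crossprod(layer$input, d),
                        b = colSums(d))
    d <- d %*% t(p$head[[i]]$W)
  }
  grads$head <- g_head
  dZs <- d

  if (cfg$use_lambda) {
    gt <- cache$gate
    dZ <- dZs * gt$w
    dw <- rowSums(dZs * cache$Z)
    ds <- dw * gt$w * (1 - gt$w)
    grads$gate <- list(a = sum(ds * gt$ln), b = sum(ds))
  } else {
    dZ <- dZs
  }

  ddyn_arr <- NULL
  if (cfg$use_tcn) {
    d_dyn <- dZ[, seq_len(cache$d_dyn), drop = FALSE]
    d_emb <- d_dyn[, seq_len(cache$n_tcn), drop = FALSE]
    d_sum <- d_dyn[, cache$n_tcn + seq_len(ncol(d_dyn) - cache$n_tcn),
                   drop = FALSE]
    tb <- tcn_bwd(p$tcn, cache$tcn, d_emb, B, cache$T_len)
    grads$tcn <- tb$grads
    if (need_input_grad) {
      ddyn_arr <- array(tb$dinput,
                        dim = c(B, cache$T_len, ncol(cache$m0))) +
        dyn_summary_bwd(d_sum, cache$dyn_in, cache$lam, cache$summary)
    }
  }
  if (cfg$use_tabular) {
    d_stat <- dZ[, cache$d_dyn + seq_len(ncol(dZ) - cache$d_dyn),
                 drop = FALSE]
    grads$ft <- ft_bwd(p$ft, cfg$tabular, cache$ft, d_stat)
  }
  list(grads = grads, ddyn = ddyn_arr)
}

tensors_batch <- function(tensors, idx) {
  list(dyn = tensors$dyn[idx, , , drop = FALSE],
       num = tensors$num[idx, , drop = FALSE],
       cat = tensors$cat[idx, , drop = FALSE],
       lam = tensors$lam[idx])
}

#' Predict revisit probabilities for a tensor set
#'
#' Runs the network in evaluation mode (dropout off): deterministic and
#' batching-invariant — single-item and batched inference agree to within
#' numerical tolerance.
#'
#' @param net A trained `ed_net`.
#' @param tensors An `ed_tensors` set.
#' @param batch_size Inference batch size (default 512).
#' @return Numeric vector of probabilities in `[0, 1]`.
#' @export
predict_proba <- function(net, tensors, batch_size = 512L) {
  n <- n_tensors(tensors)
  if (dim(tensors$dyn)[2] != 24 && net$cfg$use_tcn) {
    stop("dynamic input must have 24 time steps", call. = FALSE)
  }
  if (ncol(tensors$num) != length(net$num_features) ||
      ncol(tensors$cat) != length(net$cat_features)) {
    stop("static feature count does not match the fitted network",
         call. = FALSE)
  }
  out <- numeric(n)
  starts <- seq(1L, n, by = batch_size)
  for (s in starts) {
    idx <- s:min(s + batch_size - 1L, n)
    out[idx] <- net_forward(net, tensors_batch(tensors, idx),
                            training = FALSE)$p
  }
  out
}
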