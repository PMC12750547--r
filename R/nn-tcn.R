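# Temporal convolutional encoder for the dynamic branch: a stack of
# residual blocks of causal dilated 1-D convolutions (dilations 1, 2, 4,
# ..., 2^(levels-1)). Causality means position t only ever sees positions
# <= t; the receptive field of the stack is
# 1 + 2*(kernel-1)*(2^levels - 1) and must cover the 24-step sequence.
# The sequence embedding is read from the final (discharge-adjacent) step.

tcn_receptive_field <- function(levels, kernel) {
  1 + 2 * (kernel - 1) * (2^levels - 1)
}

tcn_init <- function(c_in, cfg_tcn) {
  k <- cfg_tcn$kernel
  C <- cfg_tcn$channels
  lapply(seq_len(cfg_tcn$levels), function(l) {
    cin <- if (l == 1) c_in else C
    # He scaling over the full conv fan-in (cin * kernel taps); the
    # residual sum then grows activation variance only mildly per level
    list(
      W1 = lapply(seq_len(k), function(j) rmat(cin, C, sqrt(2 / (cin * k)))),
      b1 = numeric(C),
      W2 = lapply(seq_len(k), function(j) rmat(C, C, sqrt(2 / (C * k)))),
      b2 = numeric(C),
      Wd = if (cin != C) rmat(cin, C, sqrt(1 / cin)) else NULL
    )
  })
}

# m: (B*T) x Cin time-major. Returns (B*T) x Cout.
causal_conv_fwd <- function(m, W, b, dil, B, T) {
  out <- matrix(b, B * T, length(b), byrow = TRUE)
  for (j in seq_along(W)) {
    s <- (j - 1L) * dil
    if (s >= T) next
    keep <- (T - s) * B
    out[(s * B + 1L):(T * B), ] <-
      out[(s * B + 1L):(T * B), ] + m[1L:keep, , drop = FALSE] %*% W[[j]]
  }
  out
}

causal_conv_bwd <- function(dout, m, W, dil, B, T) {
  dm <- matrix(0, nrow(m), ncol(m))
  dW <- vector("list", length(W))
  for (j in seq_along(W)) {
    s <- (j - 1L) * dil
    if (s >= T) { dW[[j]] <- W[[j]] * 0; next }
    keep <- (T - s) * B
    d_hi <- dout[(s * B + 1L):(T * B), , drop = FALSE]
    m_lo <- m[1L:keep, , drop = FALSE]
    dW[[j]] <- crossprod(m_lo, d_hi)
    dm[1L:keep, ] <- dm[1L:keep, ] + d_hi %*% t(W[[j]])
  }
  list(dm = dm, dW = dW, db = colSums(dout))
}

tcn_fwd <- function(params, m, B, T, dropout_p, training) {
  caches <- vector("list", length(params))
  for (l in seq_along(params)) {
    pl <- params[[l]]
    dil <- 2L^(l - 1L)
    a1 <- causal_conv_fwd(m, pl$W1, pl$b1, dil, B, T)
    r1 <- relu(a1)
    d1 <- dropout_fwd(r1, dropout_p, training)
    a2 <- causal_conv_fwd(d1$out, pl$W2, pl$b2, dil, B, T)
    r2 <- relu(a2)
    d2 <- dropout_fwd(r2, dropout_p, training)
    res <- if (is.null(pl$Wd)) m else m %*% pl$Wd
    out <- relu(d2$out + res)
    caches[[l]] <- list(m_in = m, a1 = a1, mask1 = d1$mask, d1 = d1$out,
                        a2 = a2, mask2 = d2$mask, d2 = d2$out,
                        res = res, out = out)
    m <- out
  }
  # embedding = final time step of the top feature map
  last_rows <- (T - 1L) * B + seq_len(B)
  list(emb = m[last_rows, , drop = FALSE], caches = caches)
}

tcn_bwd <- function(params, caches, demb, B, T) {
  C_top <- ncol(demb)
  dm <- matrix(0, B * T, C_top)
  dm[(T - 1L) * B + seq_len(B), ] <- demb
  grads <- vector("list", length(params))
  for (l in rev(seq_along(params))) {
    pl <- params[[l]]
    cc <- caches[[l]]
    dil <- 2L^(l - 1L)
    dsum <- dm * (cc$out > 0)
    dres <- dsum
    dd2 <- dropout_bwd(dsum, cc$mask2)
    da2 <- dd2 * (cc$a2 > 0)
    bw2 <- causal_conv_bwd(da2, cc$d1, pl$W2, dil, B, T)
    dd1 <- dropout_bwd(bw2$dm, cc$mask1)
    da1 <- dd1 * (cc$a1 > 0)
    bw1 <- causal_conv_bwd(da1, cc$m_in, pl$W1, dil, B, T)
    dm_in <- bw1$dm
    gWd <- NULL
    if (is.null(pl$Wd)) {
      dm_in <- dm_in + dres
    } else {
      gWd <- crossprod(cc$m_in, dres)
      dm_in <- dm_in + dres %*% t(pl$Wd)
    }
    grads[[l]] <- list(W1 = bw1$dW, b1 = bw1$db,
                       W2 = bw2$dW, b2 = bw2$db, Wd = gWd)
    dm <- dm_in
  }
  list(grads = grads, dinput = dm)
}
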