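# Feature-tokenizer attention encoder for the static branch. Every triage
# feature becomes one token in a d-dimensional space: categorical features
# through a per-feature lookup table (with a trailing row reserved for the
# unknown category), numeric features through a per-feature linear
# embedding (value * weight + bias). A learned classification token is
# prepended; after `depth` pre-norm transformer layers its representation
# is the branch embedding, and the final layer's attention from the
# classification token to the feature tokens is kept for interpretation.
#
# Token layout mirrors the TCN's time-major trick: a batch of B samples
# with ntok tokens is a (B*ntok) x d matrix whose rows b + (i-1)*B hold
# token i of sample b; token 1 is the classification token.

ft_init <- function(state, cfg_tab) {
  d <- cfg_tab$token_dim
  dff <- 2L * d
  voc_sizes <- vapply(state$vocab, length, integer(1)) + 1L  # + unknown
  layers <- lapply(seq_len(cfg_tab$depth), function(l) {
    list(
      g1 = rep(1, d), o1 = numeric(d),
      Wq = rmat(d, d, 1 / sqrt(d)), bq = numeric(d),
      Wk = rmat(d, d, 1 / sqrt(d)), bk = numeric(d),
      Wv = rmat(d, d, 1 / sqrt(d)), bv = numeric(d),
      Wo = rmat(d, d, 1 / sqrt(d)), bo = numeric(d),
      g2 = rep(1, d), o2 = numeric(d),
      Wf1 = he_init(d, dff), bf1 = numeric(dff),
      Wf2 = rmat(dff, d, 1 / sqrt(dff)), bf2 = numeric(d)
    )
  })
  list(
    cls = stats::rnorm(d, sd = 0.02),
    Ecat = lapply(voc_sizes, function(v) rmat(v, d, 0.02)),
    Wnum = lapply(state$num_features, function(f) stats::rnorm(d, sd = 0.02)),
    Bnum = lapply(state$num_features, function(f) stats::rnorm(d, sd = 0.02)),
    layers = layers,
    gf = rep(1, d), of = numeric(d)
  )
}

ft_token_features <- function(state) {
  c(state$num_features, state$cat_features)
}

# num: B x n_num, cat: B x n_cat (0-based codes). Builds (B*ntok) x d.
ft_tokenize <- function(params, num, cat_m, d) {
  B <- nrow(num)
  ntok <- 1L + ncol(num) + ncol(cat_m)
  H <- matrix(0, B * ntok, d)
  H[seq_len(B), ] <- matrix(params$cls, B, d, byrow = TRUE)
  tok <- 1L
  for (j in seq_len(ncol(num))) {
    tok <- tok + 1L
    rows <- (tok - 1L) * B + seq_len(B)
    H[rows, ] <- outer(num[, j], params$Wnum[[j]]) +
      matrix(params$Bnum[[j]], B, d, byrow = TRUE)
  }
  for (j in seq_len(ncol(cat_m))) {
    tok <- tok + 1L
    rows <- (tok - 1L) * B + seq_len(B)
    E <- params$Ecat[[j]]
    idx <- cat_m[, j] + 1L
    if (any(idx > nrow(E))) {
      stop("categorical code exceeds vocabulary size (+ unknown slot)",
           call. = FALSE)
    }
    H[rows, ] <- E[idx, , drop = FALSE]
  }
  H
}

# Attention works on the token-major layout (rows b + (i-1)*B). All inner
# loops run over the per-head dimension dh (small), never over tokens or
# samples: expanding a per-token column to all query rows is one indexing
# op, and summing a (B*ntok) x ntok matrix over the query index reduces
# to a single matrix product with a 0/1 reduction matrix.

# Column k of Xh rearranged to B x ntok ([b, j] = Xh[b + (j-1)B, k]) and
# expanded to all (b, i) rows.
tok_expand <- function(col, B, ntok, rep_idx) {
  matrix(col, B, ntok)[rep_idx, , drop = FALSE]
}

# reduction matrix: (ntok*ntok) x ntok, maps vec(B x ntok x ntok) summed
# over the middle (query) index onto B x ntok
tok_reduce_mat <- function(ntok) {
  R <- matrix(0, ntok * ntok, ntok)
  R[cbind(seq_len(ntok * ntok), rep(seq_len(ntok), each = ntok))] <- 1
  R
}

mha_fwd <- function(Q, K, V, B, ntok, heads) {
  d <- ncol(Q)
  dh <- d %/% heads
  rep_idx <- rep(seq_len(B), ntok)
  O <- matrix(0, nrow(Q), d)
  P_list <- vector("list", heads)
  for (h in seq_len(heads)) {
    cols <- (h - 1L) * dh + seq_len(dh)
    Qh <- Q[, cols, drop = FALSE] / sqrt(dh)
    Kh <- K[, cols, drop = FALSE]
    Vh <- V[, cols, drop = FALSE]
    S <- matrix(0, nrow(Q), ntok)
    for (k in seq_len(dh)) {
      S <- S + Qh[, k] * tok_expand(Kh[, k], B, ntok, rep_idx)
    }
    P <- softmax_rows(S)
    Oh <- matrix(0, nrow(Q), dh)
    for (k in seq_len(dh)) {
      Oh[, k] <- rowSums(P * tok_expand(Vh[, k], B, ntok, rep_idx))
    }
    O[, cols] <- Oh
    P_list[[h]] <- P
  }
  list(O = O, P = P_list)
}

mha_bwd <- function(dO, Q, K, V, P_list, B, ntok, heads) {
  d <- ncol(Q)
  dh <- d %/% heads
  rep_idx <- rep(seq_len(B), ntok)
  Rmat <- tok_reduce_mat(ntok)
  dQ <- matrix(0, nrow(Q), d)
  dK <- matrix(0, nrow(Q), d)
  dV <- matrix(0, nrow(Q), d)
  for (h in seq_len(heads)) {
    cols <- (h - 1L) * dh + seq_len(dh)
    Qh <- Q[, cols, drop = FALSE] / sqrt(dh)
    Kh <- K[, cols, drop = FALSE]
    Vh <- V[, cols, drop = FALSE]
    P <- P_list[[h]]
    dOh <- dO[, cols, drop = FALSE]
    dP <- matrix(0, nrow(Q), ntok)
    for (k in seq_len(dh)) {
      dP <- dP + dOh[, k] * tok_expand(Vh[, k], B, ntok, rep_idx)
    }
    dS <- softmax_rows_bwd(dP, P)
    dQh <- matrix(0, nrow(Q), dh)
    dKh <- matrix(0, nrow(Q), dh)
    dVh <- matrix(0, nrow(Q), dh)
    for (k in seq_len(dh)) {
      dQh[, k] <- rowSums(dS * tok_expand(Kh[, k], B, ntok, rep_idx))
      # sum over the query index i: result[b, j] -> rows b + (j-1)B
      dKh[, k] <- matrix(dS * Qh[, k], nrow = B) %*% Rmat
      dVh[, k] <- matrix(P * dOh[, k], nrow = B) %*% Rmat
    }
    dQ[, cols] <- dQh / sqrt(dh)
    dK[, cols] <- dKh
    dV[, cols] <- dVh
  }
  list(dQ = dQ, dK = dK, dV = dV)
}

ft_fwd <- function(params, num, cat_m, cfg_tab, training) {
  d <- cfg_tab$token_dim
  heads <- cfg_tab$heads
  p_drop <- cfg_tab$dropout
  B <- nrow(num)
  ntok <- 1L + ncol(num) + ncol(cat_m)
  H <- ft_tokenize(params, num, cat_m, d)
  caches <- vector("list", length(params$layers))
  attn_last <- NULL
  for (l in seq_along(params$layers)) {
    pl <- params$layers[[l]]
    ln1 <- layernorm_fwd(H, pl$g1, pl$o1)
    Q <- add_bias(ln1$out %*% pl$Wq, pl$bq)
    K <- add_bias(ln1$out %*% pl$Wk, pl$bk)
    V <- add_bias(ln1$out %*% pl$Wv, pl$bv)
    att <- mha_fwd(Q, K, V, B, ntok, heads)
    A <- add_bias(att$O %*% pl$Wo, pl$bo)
    dA <- dropout_fwd(A, p_drop, training)
    H1 <- H + dA$out
    ln2 <- layernorm_fwd(H1, pl$g2, pl$o2)
    F1 <- add_bias(ln2$out %*% pl$Wf1, pl$bf1)
    R1 <- relu(F1)
    F2 <- add_bias(R1 %*% pl$Wf2, pl$bf2)
    dF <- dropout_fwd(F2, p_drop, training)
    H2 <- H1 + dF$out
    caches[[l]] <- list(H = H, ln1 = ln1, Q = Q, K = K, V = V, att = att,
                        maskA = dA$mask, H1 = H1, ln2 = ln2, F1 = F1,
                        R1 = R1, maskF = dF$mask)
    H <- H2
    if (l == length(params$layers)) {
      # classification-token attention, averaged over heads: B x ntok
      cls_rows <- seq_len(B)
      attn_last <- Reduce(`+`, lapply(att$P, function(P) {
        P[cls_rows, , drop = FALSE]
      })) / heads
    }
  }
  lnf <- layernorm_fwd(H, params$gf, params$of)
  emb <- lnf$out[seq_len(B), , drop = FALSE]
  list(emb = emb, attn = attn_last,
        cache = list(caches = caches, lnf = lnf, H_top = H, B = B,
                     ntok = ntok, num = num, cat_m = cat_m))
}

ft_bwd <- function(params, cfg_tab, cache, demb) {
  B <- cache$B
  ntok <- cache$ntok
  heads <- cfg_tab$heads
  dlnf_out <- matrix(0, B * ntok, cfg_tab$token_dim)
  dlnf_out[seq_len(B), ] <- demb
  bwf <- layernorm_bwd(dlnf_out, cache$lnf, params$gf)
  dH <- bwf$dx
  g_lnf <- list(gf = bwf$dg, of = bwf$db)

  g_layers <- vector("list", length(params$layers))
  for (l in rev(seq_along(params$layers))) {
    pl <- params$layers[[l]]
    cc <- cache$caches[[l]]
    # FFN sublayer
    dF2 <- dropout_bwd(dH, cc$maskF)
    dR1 <- dF2 %*% t(pl$Wf2)
    gWf2 <- crossprod(cc$R1, dF2)
    gbf2 <- colSums(dF2)
    dF1 <- dR1 * (cc$F1 > 0)
    gWf1 <- crossprod(cc$ln2$out, dF1)
    gbf1 <- colSums(dF1)
    dln2_out <- dF1 %*% t(pl$Wf1)
    bw2 <- layernorm_bwd(dln2_out, cc$ln2, pl$g2)
    dH1 <- dH + bw2$dx
    # attention sublayer
    dA <- dropout_bwd(dH1, cc$maskA)
    dO <- dA %*% t(pl$Wo)
    gWo <- crossprod(cc$att$O, dA)
    gbo <- colSums(dA)
    datt <- mha_bwd(dO, cc$Q, cc$K, cc$V, cc$att$P, B, ntok, heads)
    dln1_out <- datt$dQ %*% t(pl$Wq) + datt$dK %*% t(pl$Wk) +
      datt$dV %*% t(pl$Wv)
    gWq <- crossprod(cc$ln1$out, datt$dQ)
    gWk <- crossprod(cc$ln1$out, datt$dK)
    gWv <- crossprod(cc$ln1$out, datt$dV)
    bw1 <- layernorm_bwd(dln1_out, cc$ln1, pl$g1)
    dH <- dH1 + bw1$dx
    g_layers[[l]] <- list(
      g1 = bw1$dg, o1 = bw1$db,
      Wq = gWq, bq = colSums(datt$dQ),
      Wk = gWk, bk = colSums(datt$dK),
      Wv = gWv, bv = colSums(datt$dV),
      Wo = gWo, bo = gbo,
      g2 = bw2$dg, o2 = bw2$db,
      Wf1 = gWf1, bf1 = gbf1, Wf2 = gWf2, bf2 = gbf2
    )
  }

  # token embedding gradients
  num <- cache$num
  cat_m <- cache$cat_m
  d <- cfg_tab$token_dim
  dcls <- colSums(dH[seq_len(B), , drop = FALSE])
  gWnum <- vector("list", ncol(num))
  gBnum <- vector("list", ncol(num))
  tok <- 1L
  for (j in seq_len(ncol(num))) {
    tok <- tok + 1L
    rows <- (tok - 1L) * B + seq_len(B)
    dtok <- dH[rows, , drop = FALSE]
    gWnum[[j]] <- colSums(num[, j] * dtok)
    gBnum[[j]] <- colSums(dtok)
  }
  gEcat <- vector("list", ncol(cat_m))
  for (j in seq_len(ncol(cat_m))) {
    tok <- tok + 1L
    rows <- (tok - 1L) * B + seq_len(B)
    dtok <- dH[rows, , drop = FALSE]
    E <- params$Ecat[[j]]
    gE <- matrix(0, nrow(E), ncol(E))
    idx <- cat_m[, j] + 1L
    acc <- rowsum(dtok, group = idx, reorder = FALSE)
    gE[as.integer(rownames(acc)), ] <- acc
    gEcat[[j]] <- gE
  }

  list(cls = dcls, Ecat = gEcat, Wnum = gWnum, Bnum = gBnum,
       layers = g_layers, gf = g_lnf$gf, of = g_lnf$of)
}
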