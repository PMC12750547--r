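test_that("focal loss matches its closed form and limiting cases", {
  # alpha = 0.4, gamma = 2, p_t = 0.5 -> 0.4 * 0.25 * ln 2
  expect_equal(focal_loss(0.5, 1), 0.4 * 0.25 * log(2), tolerance = 1e-12)
  expect_equal(focal_loss(0.5, 1), 0.069315, tolerance = 1e-5)
  # perfectly classified -> (numerically) zero
  expect_lt(focal_loss(1, 1), 1e-9)
  expect_lt(focal_loss(0, 0), 1e-9)
  # strictly decreasing in p_t, nonnegative
  pt <- seq(0.01, 0.99, length.out = 200)
  l <- vapply(pt, function(p) focal_loss(p, 1), numeric(1))
  expect_true(all(l >= 0))
  expect_true(all(diff(l) < 0))
})

test_that("with gamma 0 and alpha 1 focal loss is cross-entropy on a grid", {
  set.seed(20)
  p <- stats::runif(1000, 1e-6, 1 - 1e-6)
  y <- stats::rbinom(1000, 1, 0.5)
  fl <- focal_loss(p, y, alpha = 1, gamma = 0, reduce = FALSE)
  bce <- -(y * log(p) + (1 - y) * log(1 - p))
  expect_true(max(abs(fl - bce)) < 1e-9)
})

test_that("the focal-loss logit gradient matches finite differences", {
  set.seed(21)
  for (r in 1:20) {
    logit <- stats::rnorm(1, sd = 2)
    y <- stats::rbinom(1, 1, 0.5)
    eps <- 1e-6
    num <- (focal_loss(edrevisit:::sigmoid(logit + eps), y) -
              focal_loss(edrevisit:::sigmoid(logit - eps), y)) / (2 * eps)
    ana <- focal_loss_grad_logit(edrevisit:::sigmoid(logit), y)
    expect_equal(ana, num, tolerance = 1e-5)
  }
})

test_that("receptive-field arithmetic gates the configuration", {
  # levels 4, kernel 3: 1 + 2*2*(1+2+4+8) = 61
  expect_equal(edrevisit:::tcn_receptive_field(4, 3), 61)
  expect_no_error(model_config(tcn = list(levels = 4L, kernel = 3L,
                                          channels = 8L, dropout = 0)))
  expect_error(model_config(tcn = list(levels = 2L, kernel = 3L,
                                       channels = 8L, dropout = 0)),
               "receptive field")
  expect_error(model_config(use_tcn = FALSE, use_tabular = FALSE),
               "at least one branch")
})

test_that("the convolutional stack is causal", {
  state <- make_state()
  net <- init_revisit_net(tiny_model_config(), state, seed = 31)
  set.seed(32)
  B <- 2
  m0 <- matrix(stats::rnorm(B * 24 * 6), B * 24, 6)
  base <- edrevisit:::tcn_fwd(net$params$tcn, m0, B, 24,
                              dropout_p = 0, training = FALSE)
  top <- function(fw) fw$caches[[length(fw$caches)]]$out
  for (t in c(5L, 12L, 20L)) {
    m1 <- m0
    m1[(t - 1) * B + 1, ] <- m1[(t - 1) * B + 1, ] + 5  # perturb step t
    pert <- edrevisit:::tcn_fwd(net$params$tcn, m1, B, 24,
                                dropout_p = 0, training = FALSE)
    before <- seq_len((t - 1) * B)
    expect_identical(top(pert)[before, ], top(base)[before, ])
    # and the perturbation does reach the final step
    expect_false(isTRUE(all.equal(top(pert)[23 * B + 1, ],
                                  top(base)[23 * B + 1, ])))
  }
})

test_that("evaluation-mode inference is deterministic, batched consistently, and bounded", {
  state <- make_state()
  net <- init_revisit_net(tiny_model_config(), state, seed = 33)
  batch <- random_batch(state, 7, seed = 34)
  tens <- structure(c(batch, list(y_revisit = rep(0L, 7),
                                  y_highrisk = rep(0L, 7),
                                  visit_id = as.character(1:7))),
                    class = "ed_tensors")
  p1 <- predict_proba(net, tens)
  p2 <- predict_proba(net, tens)
  expect_identical(p1, p2)
  expect_true(all(p1 >= 0 & p1 <= 1))
  # batch of 7 vs 7 single calls
  singles <- vapply(1:7, function(i) {
    predict_proba(net, edrevisit:::subset_tensors(tens, i))
  }, numeric(1))
  expect_equal(p1, singles, tolerance = 1e-5)
  # identical inputs give identical outputs
  twin <- edrevisit:::subset_tensors(tens, c(1, 1))
  pp <- predict_proba(net, twin)
  expect_equal(pp[1], pp[2])
  # permutation of the batch permutes the outputs
  perm <- sample(7)
  expect_equal(predict_proba(net, edrevisit:::subset_tensors(tens, perm)),
               p1[perm], tolerance = 1e-10)
})

test_that("the lambda gate behaves per its contract", {
  state <- make_state()
  batch <- random_batch(state, 2, seed = 35, lam = c(0L, 24L))

  # without the gate, predictions carry no lambda dependence beyond the
  # valid-region masking itself (checked on an all-pad-equivalent input,
  # where the masked content is identical for every lambda)
  net0 <- init_revisit_net(tiny_model_config(use_lambda = FALSE), state,
                           seed = 36)
  batch0 <- batch
  batch0$dyn[] <- 0
  fw <- edrevisit:::net_forward(net0, batch0)
  batch2 <- batch0
  batch2$lam <- c(24L, 0L)
  fw2 <- edrevisit:::net_forward(net0, batch2)
  expect_identical(fw$p, fw2$p)
  expect_null(fw$fusion_weight)

  # with the gate, w is in (0, 1) and monotone in lambda when a > 0
  net1 <- init_revisit_net(tiny_model_config(), state, seed = 36)
  net1$params$gate$a <- 1.3
  ws <- vapply(0:24, function(l) {
    b <- batch
    b$lam <- c(l, l)
    edrevisit:::net_forward(net1, b)$fusion_weight[1]
  }, numeric(1))
  expect_true(all(ws > 0 & ws < 1))
  expect_true(all(diff(ws) > 0))
})

test_that("ablated branches shrink the trainable parameter count", {
  state <- make_state()
  full <- init_revisit_net(small_model_config(), state, seed = 37)
  no_ft <- init_revisit_net(small_model_config(use_tabular = FALSE),
                            state, seed = 37)
  no_tcn <- init_revisit_net(small_model_config(use_tcn = FALSE),
                             state, seed = 37)
  no_lam <- init_revisit_net(small_model_config(use_lambda = FALSE),
                             state, seed = 37)
  expect_lt(n_params(no_ft), n_params(full))
  expect_lt(n_params(no_tcn), n_params(full))
  expect_lt(n_params(no_lam), n_params(full))
})

test_that("analytic gradients match finite differences through the whole network", {
  state <- make_state()
  net <- init_revisit_net(tiny_model_config(), state, seed = 38)
  batch <- random_batch(state, 3, seed = 39, lam = c(0L, 5L, 24L))
  y <- c(1, 0, 1)
  lossfun <- function(nn) {
    focal_loss(edrevisit:::net_forward(nn, batch)$p, y)
  }
  fw <- edrevisit:::net_forward(net, batch)
  dl <- focal_loss_grad_logit(fw$p, y)
  bw <- edrevisit:::net_backward(net, fw$cache, dl,
                                 need_input_grad = TRUE)
  # small step: the network is piecewise smooth (ReLU) and a larger step
  # can straddle a kink
  eps <- 1e-6
  set.seed(40)
  # probe a handful of coordinates in every major block
  probes <- list(
    c("tcn", 1, "W1", 2), c("tcn", 3, "W2", 1), c("tcn", 1, "Wd"),
    c("ft", "cls"), c("ft", "Ecat", 1), c("ft", "Wnum", 2),
    c("ft", "layers", 1, "Wq"), c("ft", "layers", 1, "Wf1"),
    c("ft", "layers", 1, "g1"), c("ft", "gf"),
    c("gate", "a"), c("gate", "b"),
    c("head", 1, "W"), c("head", 2, "b")
  )
  get_leaf <- function(lst, path) {
    for (k in path) lst <- lst[[if (grepl("^[0-9]+$", k)) as.integer(k)
                                else k]]
    lst
  }
  set_leaf <- function(lst, path, idx, val) {
    if (length(path) == 1) {
      k <- if (grepl("^[0-9]+$", path)) as.integer(path) else path
      lst[[k]][idx] <- val
      return(lst)
    }
    k <- if (grepl("^[0-9]+$", path[1])) as.integer(path[1]) else path[1]
    lst[[k]] <- set_leaf(lst[[k]], path[-1], idx, val)
    lst
  }
  for (pr in probes) {
    leaf <- get_leaf(net$params, pr)
    gleaf <- get_leaf(bw$grads, pr)
    idx <- sample(length(leaf), 1)
    v0 <- leaf[idx]
    np <- net
    np$params <- set_leaf(net$params, pr, idx, v0 + eps)
    lp <- lossfun(np)
    np$params <- set_leaf(net$params, pr, idx, v0 - eps)
    lm <- lossfun(np)
    num <- (lp - lm) / (2 * eps)
    expect_lt(abs(gleaf[idx] - num),
              1e-7 + 1e-3 * (abs(num) + abs(gleaf[idx])))
  }
  # input gradient (the saliency path)
  for (r in 1:5) {
    i <- c(sample(3, 1), sample(24, 1), sample(6, 1))
    v0 <- batch$dyn[i[1], i[2], i[3]]
    batch$dyn[i[1], i[2], i[3]] <- v0 + eps
    lp <- lossfun(net)
    batch$dyn[i[1], i[2], i[3]] <- v0 - eps
    lm <- lossfun(net)
    batch$dyn[i[1], i[2], i[3]] <- v0
    expect_equal(bw$ddyn[i[1], i[2], i[3]], (lp - lm) / (2 * eps),
                 tolerance = 1e-4)
  }
})

test_that("one focal-loss step on a positive example raises its predicted probability", {
  state <- make_state()
  net <- init_revisit_net(tiny_model_config(), state, seed = 41)
  batch <- random_batch(state, 1, seed = 42, lam = 12L)
  p0 <- edrevisit:::net_forward(net, batch)$p
  fw <- edrevisit:::net_forward(net, batch, training = FALSE)
  dl <- focal_loss_grad_logit(fw$p, 1)
  bw <- edrevisit:::net_backward(net, fw$cache, dl)
  opt <- edrevisit:::adam_init(net$params)
  stepped <- edrevisit:::adam_step(net$params, bw$grads, opt, lr = 1e-2)
  net$params <- stepped$params
  p1 <- edrevisit:::net_forward(net, batch)$p
  expect_gt(p1, p0)
})

test_that("attention weights over tokens are a proper distribution", {
  state <- make_state(n_num = 5, n_cat = 14, vocab_sizes = rep(3, 14))
  net <- init_revisit_net(small_model_config(), state, seed = 43)
  batch <- random_batch(state, 6, seed = 44)
  fw <- edrevisit:::net_forward(net, batch)
  # 19 features + the classification token = 20 tokens
  expect_equal(ncol(fw$cache$attn), 20)
  expect_equal(rowSums(fw$cache$attn), rep(1, 6), tolerance = 1e-10)
})

test_that("shape violations are rejected at prediction time", {
  state <- make_state()
  net <- init_revisit_net(tiny_model_config(), state, seed = 45)
  batch <- random_batch(state, 3, seed = 46)
  tens <- structure(c(batch, list(y_revisit = rep(0L, 3),
                                  y_highrisk = rep(0L, 3),
                                  visit_id = as.character(1:3))),
                    class = "ed_tensors")
  bad <- tens
  bad$num <- cbind(bad$num, extra = 1)
  expect_error(predict_proba(net, bad), "feature count")
  bad2 <- tens
  bad2$dyn <- bad2$dyn[, 1:12, , drop = FALSE]
  expect_error(predict_proba(net, bad2), "24 time steps")
})
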