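test_that("stratified splitting apportions sizes and positives within one", {
  coh <- generate_cohort(sim_config(n_visits = 1000, seed = 14))
  expect_equal(sum(coh$static$label_revisit), 44)
  sp <- stratified_split(coh$static, seed = 5)
  sizes <- table(sp$split)
  expect_true(all(abs(sizes[c("train", "val", "test")] -
                        c(700, 150, 150)) <= 1))
  pos <- table(sp$split[coh$static$label_revisit == 1])
  expect_true(all(abs(pos[c("train", "val", "test")] -
                        c(31, 7, 6)) <= 1))
  # deterministic
  sp2 <- stratified_split(coh$static, seed = 5)
  expect_identical(sp, sp2)
  # the high-risk task stratifies on the high-risk label
  coh2 <- generate_cohort(sim_config(n_visits = 4000, seed = 15,
                                     highrisk_rate = 0.01))
  sph <- stratified_split(coh2$static, seed = 6,
                          task = "highrisk_revisit")
  posh <- table(sph$split[coh2$static$label_highrisk == 1])
  expect_true(all(abs(posh[c("train", "val", "test")] -
                        c(28, 6, 6)) <= 1))
  # refuses to starve a split of positives
  coh3 <- coh
  coh3$static$label_revisit <- c(1L, rep(0L, 999))
  expect_error(stratified_split(coh3$static, seed = 1),
               "zero positives")
})

test_that("early stopping runs best_epoch + patience epochs and keeps the best", {
  out <- run_early_stopping(c(.2, .3, .3, .3, .3, .3, .3), patience = 5)
  expect_equal(out$stopped_after, 7)
  expect_equal(out$best_epoch, 2)
  # improving forever -> runs to the end
  out2 <- run_early_stopping(seq(0.1, 0.9, by = 0.1), patience = 3)
  expect_equal(out2$stopped_after, 9)
  expect_equal(out2$best_epoch, 9)
  # strictness: sub-threshold gains do not reset the counter
  out3 <- run_early_stopping(c(.5, .5 + 1e-9, .5 + 2e-9, .5 + 3e-9),
                             patience = 3)
  expect_equal(out3$stopped_after, 4)
  expect_equal(out3$best_epoch, 1)
  # late best within patience window
  out4 <- run_early_stopping(c(.1, .2, .15, .3, .1, .1, .1, .1),
                             patience = 4)
  expect_equal(out4$stopped_after, 8)
  expect_equal(out4$best_epoch, 4)
})

test_that("the training loop applies the early-stopping arithmetic and restores best weights", {
  coh <- generate_cohort(sim_config(n_visits = 400, seed = 16))
  sp <- stratified_split(coh$static, seed = 7)
  prep <- prepare_tensors(coh, sp)
  net <- init_revisit_net(tiny_model_config(), prep$state, seed = 8)
  cfg <- train_config(max_epochs = 6L, patience = 2L, seed = 8,
                      batch_size = 64L)
  fit <- train_revisit_net(net, prep$train, prep$val, cfg)
  expect_lte(nrow(fit$history), 6)
  es <- run_early_stopping(fit$history$val_auprc, patience = 2L)
  expect_equal(nrow(fit$history), es$stopped_after)
  expect_equal(fit$best_epoch, es$best_epoch)
})

test_that("rank-based AUROC matches the all-pairs count on random score sets", {
  set.seed(17)
  for (r in 1:100) {
    n <- sample(5:50, 1)
    labels <- c(0, 1, stats::rbinom(n - 2, 1, 0.4))
    scores <- round(stats::runif(n), sample(1:3, 1))  # force some ties
    expect_equal(auroc(scores, labels), auroc_pairs(scores, labels))
  }
})

test_that("step-integrated AUPRC matches the explicit threshold loop", {
  set.seed(18)
  for (r in 1:100) {
    n <- sample(5:50, 1)
    labels <- c(0, 1, stats::rbinom(n - 2, 1, 0.3))
    scores <- round(stats::runif(n), sample(1:3, 1))
    expect_equal(auprc(scores, labels), auprc_loop(scores, labels))
  }
})

test_that("metric edge cases and confusion-count identities hold", {
  scores <- c(0.9, 0.8, 0.2, 0.1)
  labels <- c(1, 1, 0, 0)
  m <- compute_metrics(scores, labels, threshold = 0.5)
  expect_equal(m$auroc, 1)
  expect_equal(m$auprc, 1)
  expect_equal(m$f1, 2 * m$precision * m$recall /
                 (m$precision + m$recall))
  # alert everyone: recall 1, precision = base rate
  m0 <- compute_metrics(scores, labels, threshold = 0)
  expect_equal(m0$recall, 1)
  expect_equal(m0$precision, m0$base_rate)
  # counts partition the classes
  set.seed(19)
  s <- stats::runif(200)
  y <- stats::rbinom(200, 1, 0.2)
  mm <- compute_metrics(s, y, threshold = 0.35)
  expect_equal(mm$tp + mm$fn, mm$n_pos)
  expect_equal(mm$fp + mm$tn, mm$n_neg)
  expect_error(compute_metrics(c(.1, .2), c(1, 1)), "single class")
  # AUROC/AUPRC invariant under strictly monotone transforms
  expect_equal(auroc(qlogis(pmin(pmax(s, 1e-6), 1 - 1e-6)), y),
               auroc(s, y))
  expect_equal(auprc(exp(3 * s), y), auprc(s, y))
  # tidy() exposes the report as one row
  expect_equal(nrow(tidy(mm)), 1)
  expect_equal(tidy(mm)$auroc, mm$auroc)
})

test_that("threshold selection hits the closest achievable recall", {
  # 5 positives, target 0.6 -> exactly 3 captured
  scores <- c(0.95, 0.9, 0.85, 0.4, 0.3, seq(0.8, 0.05,
                                             length.out = 10))
  labels <- c(rep(1, 5), rep(0, 10))
  thr <- choose_threshold_at_recall(scores, labels, 0.6)
  expect_equal(sum(labels == 1 & scores >= thr), 3)
  # target 1 -> the minimum positive score
  thr1 <- choose_threshold_at_recall(scores, labels, 1)
  expect_equal(thr1, 0.3)
  # 42 positives, target 0.6 -> 25 captured (25/42 is the closest)
  set.seed(20)
  s2 <- stats::runif(400)
  y2 <- rep(0, 400)
  y2[order(s2 + stats::rnorm(400, 0, 0.3), decreasing = TRUE)[1:42]] <- 1
  thr2 <- choose_threshold_at_recall(s2, y2, 0.6)
  expect_equal(sum(y2 == 1 & s2 >= thr2), 25)
})

test_that("the logistic baseline solves toy and recovery problems", {
  # 1-D perfectly separable: training AUROC 1
  X <- matrix(c(1:10), ncol = 1)
  y <- as.numeric(X[, 1] > 5)
  m <- fit_static_baseline(X, y, l2 = 1e-3)
  expect_equal(auroc(predict_baseline(m, X), y), 1)

  # parameter recovery on synthetic logistic data, no penalty
  set.seed(21)
  n <- 5000
  X2 <- matrix(stats::rnorm(n * 3), n)
  beta_true <- c(-1, 0.8, -1.4, 0.6)
  p <- edrevisit:::sigmoid(drop(cbind(1, X2) %*% beta_true))
  y2 <- stats::rbinom(n, 1, p)
  m2 <- fit_static_baseline(X2, y2, l2 = 0)
  expect_true(all(abs(m2$coef - beta_true) / abs(beta_true) < 0.10))
  expect_true(m2$converged)

  # all-zero features: constant prediction at the intercept
  X3 <- matrix(0, 50, 2)
  y3 <- rep(c(1, 0), c(10, 40))
  m3 <- fit_static_baseline(X3, y3, l2 = 0)
  pr <- predict_baseline(m3, X3)
  expect_equal(stats::sd(pr), 0)
  expect_equal(pr[1], 0.2, tolerance = 1e-4)
  expect_equal(nrow(tidy(m3)), 3)
})

test_that("first recorded vitals are extracted per sign and visit", {
  v <- tibble::tibble(
    visit_id = c("a", "a", "a", "b"),
    time_min = c(-300, -100, -200, -50),
    sign = c("HR", "HR", "SBP", "BT"),
    value = c(70, 90, 130, 37.5))
  fv <- first_vitals(v, c("a", "b"))
  expect_equal(unname(fv["a" == c("a", "b"), "HR"][1]), 70)  # earliest
  expect_equal(unname(fv[1, "SBP"]), 130)
  expect_equal(unname(fv[2, "BT"]), 37.5)
  expect_true(is.na(fv[2, "HR"]))
})

test_that("an end-to-end run is reproducible from its seeds", {
  coh <- generate_cohort(sim_config(n_visits = 600, seed = 22))
  mc <- tiny_model_config()
  tc <- train_config(max_epochs = 3L, seed = 23)
  r1 <- run_revisit_pipeline(coh, mc, tc, augment_config(seed = 24))
  r2 <- run_revisit_pipeline(coh, mc, tc, augment_config(seed = 24))
  expect_identical(tidy(r1$report), tidy(r2$report))
  expect_identical(r1$history, r2$history)
  expect_identical(r1$scores_test, r2$scores_test)
})
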