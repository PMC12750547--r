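test_that("same-hour measurements are averaged into one bin", {
  v <- tibble::tibble(visit_id = "v",
                      time_min = c(-50, -20),
                      sign = c("HR", "HR"),
                      value = c(80, 90))
  g <- hourly_divide(v)[["v"]]
  expect_equal(nrow(g), 1)
  expect_equal(g[1, "HR"], c(HR = 85))
  expect_true(all(is.na(g[1, setdiff(colnames(g), "HR")])))
})

test_that("measurements over four hours and three signs populate a 4-row grid", {
  v <- tibble::tibble(
    visit_id = "v",
    time_min = -c(30, 90, 150, 210),
    sign = c("HR", "SBP", "RR", "HR"),
    value = c(80, 120, 18, 90))
  g <- hourly_divide(v)[["v"]]
  expect_equal(nrow(g), 4)
  expect_equal(sum(!is.na(g)), 4)
  expect_setequal(colnames(g)[colSums(!is.na(g)) > 0],
                  c("HR", "SBP", "RR"))
  # single measurement -> at least one row, exactly one filled cell
  one <- hourly_divide(v[1, ])[["v"]]
  expect_gte(nrow(one), 1)
  expect_equal(sum(!is.na(one)), 1)
})

test_that("alignment pads short stays, truncates long ones, keeps exact ones", {
  mk <- function(H) matrix(seq_len(H * 6), H, 6,
                           dimnames = list(NULL, sign_catalogue()))
  short <- align_fixed_length(mk(3))
  expect_equal(short$lam, 3L)
  expect_true(all(is.na(short$mat[1:21, ])))
  expect_equal(short$mat[22:24, ], mk(3), ignore_attr = TRUE)
  expect_equal(sum(short$mask), 3)

  long <- align_fixed_length(mk(30))
  expect_equal(long$lam, 24L)
  expect_equal(long$mat, mk(30)[7:30, ], ignore_attr = TRUE)

  exact <- align_fixed_length(mk(24))
  expect_equal(exact$lam, 24L)
  expect_equal(exact$mat, mk(24), ignore_attr = TRUE)
})

test_that("forward fill then backward fill, with the mean fallback", {
  means <- stats::setNames(rep(36.9, 6), sign_catalogue())
  mk_seq <- function(valid) {
    m <- matrix(NA_real_, 24, 6, dimnames = list(NULL, sign_catalogue()))
    m[(24 - length(valid) + 1):24, "HR"] <- valid
    align <- list(mat = m, lam = length(valid),
                  mask = c(rep(FALSE, 24 - length(valid)),
                           rep(TRUE, length(valid))))
    class(align) <- "ed_seq"
    align
  }
  out <- impute_sequence(mk_seq(c(NA, 5, NA, 7)), means)
  expect_equal(unname(out$mat[21:24, "HR"]), c(5, 5, 5, 7))
  out <- impute_sequence(mk_seq(c(9, NA, NA)), means)
  expect_equal(unname(out$mat[22:24, "HR"]), c(9, 9, 9))
  out <- impute_sequence(mk_seq(c(NA, NA, NA)), means)
  expect_equal(unname(out$mat[22:24, "HR"]), rep(36.9, 3))
  # pad region untouched
  expect_true(all(is.na(out$mat[1:21, "HR"])))
})

test_that("encoding statistics use the population convention and lexicographic vocabularies", {
  st <- tibble::tibble(visit_id = c("a", "b", "c"))
  ft <- static_feature_types()
  for (f in ft$feature[ft$type == "numeric"]) st[[f]] <- c(30, 40, 50)
  for (f in ft$feature[ft$type == "categorical"]) st[[f]] <- c("M", "F",
                                                               "M")
  seqs <- list()
  state <- fit_encoding(st, seqs)
  expect_equal(state$num_stats$age$mean, 40)
  expect_equal(state$num_stats$age$sd, sqrt(mean((c(30, 40, 50) - 40)^2)))
  expect_equal(state$num_stats$age$sd, 8.1650, tolerance = 1e-4)
  expect_equal(state$vocab$sex, c("F", "M"))

  # constant feature maps to zero
  st2 <- st
  st2$age <- c(5, 5, 5)
  state2 <- fit_encoding(st2, seqs)
  expect_true(state2$num_stats$age$constant)
  grids <- replicate(3, matrix(NA_real_, 0, 6,
                               dimnames = list(NULL, sign_catalogue())),
                     simplify = FALSE)
  seqs3 <- lapply(grids, align_fixed_length)
  st2$label_revisit <- c(1L, 0L, 0L)
  st2$label_highrisk <- 0L
  tens <- apply_encoding(state2, st2, seqs3)
  expect_equal(unname(tens$num[, "age"]), c(0, 0, 0))

  # unseen category goes to the reserved unknown index
  st3 <- st2
  st3$sex <- c("Other", "F", "M")
  tens3 <- apply_encoding(state2, st3, seqs3)
  expect_equal(unname(tens3$cat[, "sex"]), c(2L, 0L, 1L))

  # z-scoring: value 50 with mean 40 sd 10 -> 1
  expect_equal(edrevisit:::encode_value(50, list(mean = 40, sd = 10,
                                                 constant = FALSE)), 1)
})

test_that("encoding applied to its own training split centers numerics at zero", {
  coh <- generate_cohort(sim_config(n_visits = 400, seed = 10))
  split <- stratified_split(coh$static, seed = 1)
  prep <- prepare_tensors(coh, split)
  mus <- colMeans(prep$train$num)
  expect_true(all(abs(mus) < 1e-9))
  sds <- apply(prep$train$num, 2, function(x) sqrt(mean((x - mean(x))^2)))
  expect_true(all(abs(sds - 1) < 1e-9 | sds == 0))
  # and never raises on unseen categories in a later split
  test_static <- coh$static[split$split == "test", ]
  test_static$department[1] <- "brand-new-unit"
  test_seqs <- lapply(prep$grids[test_static$visit_id],
                      align_fixed_length)
  expect_no_error(tens <- apply_encoding(prep$state, test_static,
                                         test_seqs))
  unk <- length(prep$state$vocab$department)
  expect_equal(tens$cat[1, "department"], c(department = unk))
})

test_that("encoding round-trips through JSON bit-exactly", {
  coh <- generate_cohort(sim_config(n_visits = 300, seed = 11))
  split <- stratified_split(coh$static, seed = 1)
  prep <- prepare_tensors(coh, split)
  path <- withr::local_tempfile(fileext = ".json")
  encoding_to_json(prep$state, path)
  back <- encoding_from_json(path)
  expect_identical(back$vocab$sex, prep$state$vocab$sex)
  expect_identical(back$num_stats$age$mean, prep$state$num_stats$age$mean)
  expect_identical(back$dyn_stats$HR$sd, prep$state$dyn_stats$HR$sd)
})

test_that("vectorized preprocessing matches the brute-force reference on random streams", {
  means <- stats::setNames(c(80, 75, 97, 36.8, 17, 125), sign_catalogue())
  for (seed in 1:300) {
    stream <- random_stream(seed)
    ref <- ref_align_impute(stream, means)
    got <- pkg_align_impute(stream, means)
    expect_identical(got$lam, ref$lam)
    expect_equal(got$mat, ref$mat, ignore_attr = TRUE)
  }
})

test_that("lam equals the span in whole hours, capped at 24, and the valid region is complete", {
  means <- stats::setNames(rep(0, 6), sign_catalogue())
  for (seed in 301:360) {
    stream <- random_stream(seed)
    got <- pkg_align_impute(stream, means)
    obs <- stream[!is.na(stream$value), ]
    span <- if (nrow(obs) == 0) 0 else floor(max(-obs$time_min) / 60) + 1
    expect_equal(got$lam, min(24, span))
    if (got$lam > 0) {
      expect_false(anyNA(got$mat[(24 - got$lam + 1):24, ]))
    }
  }
})
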