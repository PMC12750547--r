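#' Earliest recorded value of each vital sign per visit
#'
#' The static-only reference model sees, besides the triage table, only
#' the first recorded vital sign of each type after admission.
#'
#' @param vitals Cleaned long-format vitals tibble.
#' @param visit_ids Character vector fixing row order of the result.
#' @return A numeric matrix `length(visit_ids)` x 6 (raw scale, `NA`
#'   where a sign was never measured).
#' @export
first_vitals <- function(vitals, visit_ids) {
  signs <- sign_catalogue()
  obs <- vitals[!is.na(vitals$value), , drop = FALSE]
  obs <- dplyr::slice_min(
    dplyr::group_by(obs, .data$visit_id, .data$sign),
    .data$time_min, n = 1, with_ties = FALSE)
  m <- matrix(NA_real_, length(visit_ids), length(signs),
              dimnames = list(NULL, signs))
  m[cbind(match(obs$visit_id, as.character(visit_ids)),
          match(obs$sign, signs))] <- obs$value
  m
}

#' Design matrix for the static-only logistic baseline
#'
#' Z-scored numeric features, one-hot encoded categoricals (training
#' vocabularies; unseen levels fall in the unknown column) and the
#' z-scored first recorded vitals (missing = channel mean = 0 after
#' scaling).
#'
#' @param state A fitted `ed_encoding`.
#' @param static Static tibble.
#' @param first_vit Matrix from [first_vitals()], rows aligned with
#'   `static`.
#' @return Numeric design matrix (no intercept column).
#' @export
baseline_features <- function(state, static, first_vit) {
  n <- nrow(static)
  num <- matrix(0, n, length(state$num_features),
                dimnames = list(NULL, state$num_features))
  for (f in state$num_features) {
    x <- as.numeric(static[[f]])
    x[is.na(x)] <- state$num_stats[[f]]$mean
    num[, f] <- encode_value(x, state$num_stats[[f]])
  }
  onehots <- lapply(state$cat_features, function(f) {
    voc <- state$vocab[[f]]
    idx <- match(as.character(static[[f]]), voc)
    idx[is.na(idx)] <- length(voc) + 1L
    m <- matrix(0, n, length(voc) + 1L,
                dimnames = list(NULL, paste0(f, "=", c(voc, "<unk>"))))
    m[cbind(seq_len(n), idx)] <- 1
    m
  })
  fv <- first_vit
  for (s in colnames(fv)) {
    st <- state$dyn_stats[[s]]
    v <- fv[, s]
    v[is.na(v)] <- st$mean
    fv[, s] <- encode_value(v, st)
  }
  colnames(fv) <- paste0("first_", colnames(fv))
  cbind(num, do.call(cbind, onehots), fv)
}

#' Fit the static-only logistic-regression baseline
#'
#' Plain logistic regression fitted by Newton / iteratively reweighted
#' least squares with an optional L2 (ridge) penalty on the
#' non-intercept coefficients. Exposes the same probability contract as
#' the hybrid model.
#'
#' @param X Design matrix (rows = visits).
#' @param y Binary labels.
#' @param l2 Ridge penalty (default 1e-4; 0 disables).
#' @param max_iter Maximum Newton iterations.
#' @param tol Convergence tolerance on the coefficient step.
#' @return An `ed_baseline` with `coef` (named, intercept first) and
#'   `converged`.
#' @export
fit_static_baseline <- function(X, y, l2 = 1e-4, max_iter = 100L,
                                tol = 1e-8) {
  X1 <- cbind(`(Intercept)` = 1, X)
  p_dim <- ncol(X1)
  beta <- numeric(p_dim)
  pen <- diag(c(0, rep(l2, p_dim - 1L)), p_dim)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- drop(X1 %*% beta)
    mu <- sigmoid(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    grad <- crossprod(X1, y - mu) - pen %*% beta
    hess <- crossprod(X1 * w, X1) + pen
    step <- tryCatch(solve(hess, grad),
                     error = function(e) {
                       solve(hess + diag(1e-6, p_dim), grad)
                     })
    beta <- beta + drop(step)
    if (max(abs(step)) < tol) { converged <- TRUE; break }
  }
  if (!converged) {
    warning("baseline did not fully converge; returning best iterate",
            call. = FALSE)
  }
  structure(list(coef = stats::setNames(drop(beta), colnames(X1)),
                 converged = converged),
            class = "ed_baseline")
}

#' Predicted probabilities from the logistic baseline
#' @param model An `ed_baseline`.
#' @param X Design matrix with the same columns used for fitting.
#' @return Probabilities in `[0, 1]`.
#' @export
predict_baseline <- function(model, X) {
  sigmoid(drop(cbind(1, X) %*% model$coef))
}

#' @export
print.ed_baseline <- function(x, ...) {
  cat(sprintf("<ed_baseline> logistic regression, %d coefficients%s\n",
              length(x$coef),
              if (x$converged) "" else " (not converged)"))
  invisible(x)
}
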