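#' Bootstrap-lasso support inference for static models
#'
#' Union-of-intersections-style approximation to two-stage sparse selection:
#' over `n_boot` bootstrap resamples a lasso path is fit (via
#' \pkg{glmnet}) on a common log-spaced regularization grid for the regression
#' of the target on `(y_noti, x)`; at each regularization level the supports
#' are intersected across resamples; the level is then chosen by out-of-sample
#' R-squared of a restricted OLS refit on a held-out fraction of trials, and
#' the chosen intersection support is returned. Deterministic given `seed`.
#' This is a documented approximation to published union-of-intersections
#' selection, not a reimplementation of it.
#'
#' @param data a [static_dataset()] with at least 50 trials.
#' @param n_boot number of bootstrap resamples.
#' @param n_lambda number of regularization levels (log-spaced path).
#' @param holdout fraction of trials held out for the level choice.
#' @param seed integer seed controlling resampling and the holdout split.
#' @return A [support_mask()] over the target coupling and tuning.
#' @export
infer_support_static <- function(data, n_boot = 20L, n_lambda = 48L,
                                 holdout = 0.1, seed = 1L) {
  stopifnot(inherits(data, "cotula_data"))
  if (data$D < 50L) stop("support inference needs D >= 50 for resampling")
  set.seed(as.integer(seed))
  N <- data$N; M <- data$M; D <- data$D
  C <- cbind(data$Y, data$X)
  p <- N + M
  hold <- sample.int(D, max(1L, round(holdout * D)))
  train <- setdiff(seq_len(D), hold)
  Ct <- C[train, , drop = FALSE]; yt <- data$y[train]
  # common lambda grid from a path on the full training data
  lam <- glmnet::glmnet(Ct, yt, intercept = FALSE, nlambda = n_lambda,
                        standardize = TRUE)$lambda
  lam <- exp(seq(log(max(lam)), log(max(min(lam), 1e-4 * max(lam))),
                 length.out = n_lambda))
  keep <- matrix(TRUE, p, n_lambda)
  for (b in seq_len(n_boot)) {
    idx <- sample(train, length(train), replace = TRUE)
    fit <- glmnet::glmnet(C[idx, , drop = FALSE], data$y[idx],
                          intercept = FALSE, lambda = lam, standardize = TRUE)
    beta <- as.matrix(fit$beta)
    if (ncol(beta) < n_lambda)  # path may stop early; recycle last column
      beta <- cbind(beta, beta[, rep(ncol(beta), n_lambda - ncol(beta)), drop = FALSE])
    keep <- keep & (beta != 0)
  }
  # choose the regularization level by held-out R^2 of a restricted OLS refit
  yh <- data$y[hold]; Ch <- C[hold, , drop = FALSE]
  ss_tot <- sum((yh - mean(yh))^2)
  r2 <- apply(keep, 2L, function(act) {
    w <- tryCatch(
      .solve_restricted(crossprod(Ct), drop(crossprod(Ct, yt)), act),
      error = function(e) NULL)
    if (is.null(w)) return(-Inf)   # empty support => w = 0, R^2 vs zero fit
    1 - sum((yh - drop(Ch %*% w))^2) / ss_tot
  })
  act <- if (all(!is.finite(r2))) rep(FALSE, p) else keep[, which.max(r2)]
  support_mask(act[seq_len(N)], act[N + seq_len(M)])
}
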