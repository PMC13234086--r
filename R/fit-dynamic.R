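# Structural residuals r_t = y_t - A y_{t-1} - B x_t for the modeled
# transitions t = 2..T (the first transition is dropped: y_1 is conditioned
# on as the chain's initial observation).
.dyn_residuals <- function(params, data) {
  T_ <- data$T
  data$Y[-1L, , drop = FALSE] -
    data$Y[-T_, , drop = FALSE] %*% t(params$A) -
    data$X[-1L, , drop = FALSE] %*% t(params$B)
}

#' OLS fit of the dynamic CoTu model
#'
#' Row-wise restricted least squares of `y_t` on `(y_{t-1}, x_t)` over the
#' transitions `t = 2..T`; off-support entries of the coupling and tuning
#' matrices are exactly 0.
#'
#' @param data a [dynamic_dataset()].
#' @param support a [support_mask()] with matrix-valued `coupling` (`N x N`)
#'   and `tuning` (`N x M`); defaults to all-free.
#' @return A `"cotula_dyn_fit"` whose `$params` has latent dimension 0.
#' @export
fit_dynamic_cotu_ols <- function(data, support = NULL) {
  stopifnot(inherits(data, "cotula_dyn_data"))
  N <- data$N; M <- data$M; T_ <- data$T
  if (is.null(support))
    support <- support_mask(matrix(TRUE, N, N), matrix(TRUE, N, M))
  C <- cbind(data$Y[-T_, , drop = FALSE], data$X[-1L, , drop = FALSE])
  G <- crossprod(C)
  A <- matrix(0, N, N); B <- matrix(0, N, M)
  for (j in seq_len(N)) {
    act <- c(support$coupling[j, ], support$tuning[j, ])
    if (T_ - 1L <= sum(act)) stop("T too small for the active predictors of row ", j)
    w <- .solve_restricted(G, drop(crossprod(C, data$Y[-1L, j])), act)
    A[j, ] <- w[seq_len(N)]; B[j, ] <- w[N + seq_len(M)]
  }
  params <- dynamic_params(A = A, B = B, L = matrix(0, N, 0),
                           Sigma = pmax(colMeans(.dyn_residuals(
                             list(A = A, B = B), data)^2), 1e-12),
                           G = matrix(0, 0, 0), H = diag(0, M))
  new_cotula_dyn_fit(params, loglik = NA_real_, n_iter = 0L, converged = TRUE,
                     support = support, model = "cotu")
}

#' E-step for the dynamic CoTuLa model
#'
#' Exact Gaussian posterior of the latent chain given the data, computed by a
#' Kalman filter and Rauch-Tung-Striebel smoother on the state-space form
#' (state `z_t`, observation `r_t = y_t - A y_{t-1} - B x_t = L z_t + psi_t`).
#' This is algebraically the block-tridiagonal solve of the posterior
#' precision `Lambda^{-1} = L~' Sigma~^{-1} L~ + D_G' D_G`, in `O(T K^3)`:
#' the smoothed covariances are the diagonal blocks of `Lambda` and the
#' lag-one smoothed covariances its first off-diagonal blocks. The chain
#' start has prior `z ~ N(0, I_K)`; the modeled transitions are `t = 2..T`,
#' so all outputs have `T - 1` time blocks aligned to times `2..T`.
#'
#' @param params a [dynamic_params()] with `K >= 1`.
#' @param data a [dynamic_dataset()] with `T >= 2`.
#' @return A list of class `"cotula_dyn_posterior"`: `mu` (`(T-1) x K`
#'   posterior means), `V` (`K x K x (T-1)` diagonal covariance blocks),
#'   `C` (`K x K x (T-2)` off-diagonal blocks, `C[,,t] = Cov(z_t, z_{t+1})`),
#'   and `loglik`, the exact observed-data log-likelihood of `params` from
#'   the filter.
#' @export
dynamic_e_step <- function(params, data) {
  stopifnot(inherits(params, "cotula_dyn_params"), inherits(data, "cotula_dyn_data"))
  if (params$K < 1L) stop("E-step requires K >= 1")
  if (data$T < 2L) stop("T must be >= 2")
  R <- .dyn_residuals(params, data)         # n x N, n = T-1
  out <- .kalman_smoother_cpp(R, params$L, params$Sigma, params$G)
  structure(list(mu = out$mu, V = out$V, C = out$C, loglik = out$loglik),
            class = "cotula_dyn_posterior")
}

#' Expected complete-data log-likelihood of the dynamic CoTuLa model
#'
#' Evaluates the EM objective under the posterior latent statistics, using
#' only the diagonal and first off-diagonal posterior covariance blocks: the
#' observation quadratic and trace terms, the latent-chain quadratic and trace
#' terms, and the log-determinant term `n log det Sigma` (with `n` the number
#' of modeled transitions). Constant terms independent of the parameters are
#' dropped.
#'
#' @param params a [dynamic_params()].
#' @param data the [dynamic_dataset()] the posterior was computed on.
#' @param post a [dynamic_e_step()] result.
#' @return Scalar expected log-likelihood (up to an additive constant).
#' @export
dynamic_expected_loglik <- function(params, data, post) {
  stopifnot(inherits(post, "cotula_dyn_posterior"))
  L <- params$L; G <- params$G; Sig <- params$Sigma
  R <- .dyn_residuals(params, data)
  mu <- post$mu
  n <- nrow(mu); K <- ncol(mu)
  E <- R - mu %*% t(L)
  Vsum <- apply(post$V, c(1, 2), sum)
  Vsum_head <- Vsum - post$V[, , n]
  term_quad <- sum(sweep(E^2, 2L, 1 / Sig, "*"))
  term_tr <- sum(diag(t(L * (1 / Sig)) %*% L %*% Vsum))
  dmu <- mu - rbind(0, mu[-n, , drop = FALSE] %*% t(G))
  term_prior <- sum(dmu^2)
  term_prior_tr <- sum(diag(Vsum)) + sum(diag(crossprod(G) %*% Vsum_head))
  if (n >= 2L) {
    Csum <- apply(post$C, c(1, 2), sum)
    term_prior_tr <- term_prior_tr - 2 * sum(diag(G %*% Csum))
  }
  -0.5 * (term_quad + term_tr + term_prior + term_prior_tr) -
    0.5 * n * sum(log(Sig))
}

# scale a square matrix to spectral radius <= rho_max (EM safeguard)
.clip_spectral <- function(X, rho_max = 0.995) {
  if (!nrow(X)) return(X)
  r <- max(abs(eigen(X, only.values = TRUE)$values))
  if (r >= rho_max) X * (rho_max / r) else X
}

# M-step for the dynamic CoTuLa model: row-wise restricted LS for (A, B, L),
# expected-residual variances, latent lag regression for G.
.dyn_m_step <- function(data, post, support, K, var_floor = 1e-8) {
  N <- data$N; M <- data$M; T_ <- data$T
  mu <- post$mu; n <- nrow(mu)
  C <- cbind(data$Y[-T_, , drop = FALSE], data$X[-1L, , drop = FALSE], mu)
  Gm <- crossprod(C)
  iz <- N + M + seq_len(K)
  Vsum <- apply(post$V, c(1, 2), sum)
  Gm[iz, iz] <- Gm[iz, iz] + Vsum
  Yt <- data$Y[-1L, , drop = FALSE]
  A <- matrix(0, N, N); B <- matrix(0, N, M); L <- matrix(0, N, K)
  Sig <- numeric(N)
  for (j in seq_len(N)) {
    act <- c(support$coupling[j, ], support$tuning[j, ], rep(TRUE, K))
    w <- .solve_restricted(Gm, drop(crossprod(C, Yt[, j])), act)
    A[j, ] <- w[seq_len(N)]; B[j, ] <- w[N + seq_len(M)]; L[j, ] <- w[iz]
    res <- Yt[, j] - drop(C %*% w)
    Sig[j] <- max((sum(res^2) + drop(crossprod(L[j, ], Vsum %*% L[j, ]))) / n,
                  var_floor)
  }
  # latent lag regression: G = (sum E[z_t z_{t-1}']) (sum E[z_{t-1} z_{t-1}'])^-1
  if (n >= 2L) {
    S10 <- matrix(0, K, K); S00 <- matrix(0, K, K)
    for (t in 2:n) {
      S10 <- S10 + t(post$C[, , t - 1L]) + tcrossprod(mu[t, ], mu[t - 1L, ])
      S00 <- S00 + post$V[, , t - 1L] + tcrossprod(mu[t - 1L, ])
    }
    G <- .clip_spectral(t(solve(S00, t(S10))))
  } else G <- matrix(0, K, K)
  dynamic_params(A = .clip_spectral(A, 0.999), B = B, L = L, Sigma = Sig,
                 G = G, H = diag(0, M))
}

# default dynamic EM initialization: OLS for (A, B), factor-analysis-style
# loadings from the OLS residual covariance, lag-1 autocorrelation of the
# leading residual component for G.
.init_dynamic_em <- function(data, K, support, var_floor = 1e-8) {
  ols <- fit_dynamic_cotu_ols(data, support)$params
  R <- .dyn_residuals(ols, data)
  S <- crossprod(R) / nrow(R)
  ev <- eigen(S, symmetric = TRUE)
  lam <- pmax(ev$values[seq_len(K)], var_floor)
  L <- ev$vectors[, seq_len(K), drop = FALSE] %*% .diagv(sqrt(lam))
  Sig <- pmax(diag(S) - rowSums(L^2), var_floor)
  w <- R %*% ev$vectors[, 1L]
  g0 <- max(min(stats::cor(w[-1L], w[-length(w)]), 0.95), 0)
  # z has unit innovation variance: rescale loadings by the stationary sd
  L <- L * sqrt(1 - g0^2)
  dynamic_params(A = ols$A, B = ols$B, L = L, Sigma = Sig,
                 G = diag(g0, K), H = diag(0, data$M))
}

#' EM fit of the dynamic CoTuLa model
#'
#' Alternates [dynamic_e_step()] and a restricted least-squares M-step for
#' `(A, B, L)`, expected-residual private variances, and a latent
#' lag-regression update for `G`. The recorded trace is the exact
#' observed-data log-likelihood computed by the Kalman filter at each E-step;
#' it is non-decreasing across sweeps.
#'
#' @param data a [dynamic_dataset()].
#' @param K latent dimension, `>= 1`.
#' @param support a [support_mask()] with matrix `coupling`/`tuning`; default
#'   all-free.
#' @param init `NULL` (OLS + factor-analysis-style initialization) or a
#'   `"cotula_dyn_params"` starting point.
#' @param max_iter,tol iteration cap and relative log-likelihood tolerance.
#' @param var_floor private variance floor.
#' @return A `"cotula_dyn_fit"`; `$converged = FALSE` (never an error) if the
#'   tolerance was not met.
#' @export
fit_dynamic_cotula_em <- function(data, K = 1L, support = NULL, init = NULL,
                                  max_iter = 200L, tol = 1e-8,
                                  var_floor = 1e-8) {
  stopifnot(inherits(data, "cotula_dyn_data"))
  if (K < 1L) stop("K must be >= 1")
  N <- data$N; M <- data$M
  if (is.null(support))
    support <- support_mask(matrix(TRUE, N, N), matrix(TRUE, N, M))
  params <- if (inherits(init, "cotula_dyn_params")) init
            else .init_dynamic_em(data, K, support, var_floor)
  trace <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    post <- dynamic_e_step(params, data)
    trace <- c(trace, post$loglik)
    if (tol > 0 && is.finite(ll_old) &&
        abs(post$loglik - ll_old) <= tol * (abs(ll_old) + tol)) {
      converged <- TRUE
      break
    }
    ll_old <- post$loglik
    params <- .dyn_m_step(data, post, support, K, var_floor)
  }
  new_cotula_dyn_fit(params, loglik = trace, n_iter = iter,
                     converged = converged, support = support, model = "cotula")
}

new_cotula_dyn_fit <- function(params, loglik, n_iter, converged, support,
                               model, regime = NULL) {
  structure(list(params = params, loglik_trace = loglik, n_iter = n_iter,
                 converged = converged, support = support, model = model,
                 regime = regime),
            class = "cotula_dyn_fit")
}

#' Fit a dynamic coupling-tuning model to a time series
#'
#' Front-end for dynamic model fitting under the three model-support regimes
#' (see [cotula_static()] for the static analogue). `selection = "inferred"`
#' uses the normalization-and-cutoff selector [infer_support_dynamic()].
#'
#' @param data a [dynamic_dataset()].
#' @param model `"cotula"` (EM) or `"cotu"` (OLS).
#' @param selection model-support regime.
#' @param K latent dimension for the CoTuLa model.
#' @param support the true support for `selection = "oracle"`.
#' @param selection_control arguments forwarded to [infer_support_dynamic()].
#' @param ... further arguments to [fit_dynamic_cotula_em()] or
#'   [fit_dynamic_cotu_ols()].
#' @return A `"cotula_dyn_fit"` object.
#' @export
cotula_dynamic <- function(data, model = c("cotula", "cotu"),
                           selection = c("none", "oracle", "inferred"),
                           K = 1L, support = NULL, selection_control = list(),
                           ...) {
  model <- match.arg(model)
  selection <- match.arg(selection)
  supp <- switch(selection,
    none = support_mask(matrix(TRUE, data$N, data$N), matrix(TRUE, data$N, data$M)),
    oracle = {
      if (is.null(support)) stop("oracle selection requires `support`")
      support
    },
    inferred = do.call(infer_support_dynamic, c(list(data = data), selection_control)))
  fit <- if (model == "cotula") fit_dynamic_cotula_em(data, K = K, support = supp, ...)
         else fit_dynamic_cotu_ols(data, support = supp)
  fit$regime <- selection
  fit
}

#' @export
print.cotula_dyn_fit <- function(x, ...) {
  cat(sprintf("Dynamic %s fit (%s selection)", toupper(x$model),
              if (is.null(x$regime)) "explicit" else x$regime))
  if (x$model == "cotula")
    cat(sprintf(": K = %d, %d EM sweeps, %sconverged, loglik %.4f",
                x$params$K, x$n_iter, if (x$converged) "" else "NOT ",
                utils::tail(x$loglik_trace, 1)))
  cat("\n")
  invisible(x)
}

#' @export
coef.cotula_dyn_fit <- function(object, ...) {
  list(A = object$params$A, B = object$params$B)
}

#' @export
predict.cotula_dyn_fit <- function(object, newdata, ...) {
  p <- object$params
  T_ <- newdata$T
  newdata$Y[-T_, , drop = FALSE] %*% t(p$A) +
    newdata$X[-1L, , drop = FALSE] %*% t(p$B)
}

#' @export
residuals.cotula_dyn_fit <- function(object, data, ...) {
  .dyn_residuals(object$params, data)
}

#' @export
plot.cotula_dyn_fit <- function(x, ...) {
  plot(seq_along(x$loglik_trace), x$loglik_trace, type = "b",
       xlab = "EM sweep", ylab = "observed-data log-likelihood", ...)
  invisible(x)
}
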