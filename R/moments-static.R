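#' Exact joint Gaussian moments of the static CoTuLa model
#'
#' Mean and covariance of the stacked vector `(y_i, y_noti, z)` conditioned on
#' a stimulus `x`. The covariance does not depend on `x`; the mean is linear in
#' it. Blocks follow directly from the generative equations: with
#' `Pi = diag(Psi)` and `u = l + L a` (the target's total latent loading,
#' direct plus routed through the coupled non-targets),
#'
#' \deqn{Var(y_i) = \psi_i + a^T \Pi a + u^T u,\quad
#'       Cov(y_i, y_{\neg i}) = a^T \Pi + u^T L,\quad
#'       Cov(y_i, z) = u^T,}
#' \deqn{Var(y_{\neg i}) = \Pi + L^T L,\quad Cov(y_{\neg i}, z) = L^T,\quad
#'       Var(z) = I_K.}
#'
#' @param params a [static_params()] object.
#' @param x stimulus vector of length `M` (defaults to zeros, in which case the
#'   mean is zero up to intercepts).
#' @return A list with `mean` (length `N + 1 + K`) and `cov`
#'   (`(N+1+K) x (N+1+K)`), ordered target unit, non-target units, latent.
#' @seealso [precision_matrix()] for the closed-form inverse.
#' @export
joint_moments <- function(params, x = NULL) {
  stopifnot(inherits(params, "cotula_params"))
  N <- params$N; M <- params$M; K <- params$K
  if (is.null(x)) x <- numeric(M)
  if (length(x) != M) stop("x must have length M = ", M)
  a <- params$a; L <- params$L; Pi <- params$Psi
  u <- params$l + drop(L %*% a)             # l + L a
  mu_not <- drop(crossprod(params$B, x))
  if (!is.null(params$B0)) mu_not <- mu_not + params$B0
  mu_i <- sum(x * params$b) + sum(mu_not * a)
  if (!is.null(params$b0)) mu_i <- mu_i + params$b0
  mean <- c(mu_i, mu_not, numeric(K))

  cov <- matrix(0, N + 1 + K, N + 1 + K)
  iy <- 1L; inot <- 1L + seq_len(N); iz <- N + 1L + seq_len(K)
  cov[iy, iy] <- params$psi + sum(a^2 * Pi) + sum(u^2)
  c_ynot <- a * Pi + drop(crossprod(L, u))  # Pi a + L^T u
  cov[iy, inot] <- c_ynot; cov[inot, iy] <- c_ynot
  cov[inot, inot] <- .diagv(Pi) + crossprod(L)
  cov[iy, iz] <- u; cov[iz, iy] <- u
  cov[inot, iz] <- t(L); cov[iz, inot] <- L
  cov[iz, iz] <- diag(K)
  list(mean = mean, cov = cov)
}

#' Closed-form precision matrix of the static CoTuLa joint distribution
#'
#' The analytic inverse of the [joint_moments()] covariance of
#' `(y_i, y_noti, z)`:
#'
#' \deqn{\Sigma^{-1} = \begin{pmatrix}
#'  \psi^{-1} & -\psi^{-1} a^T & -\psi^{-1} l^T\\
#'  -\psi^{-1} a & \Pi^{-1} + \psi^{-1} a a^T & \psi^{-1} a l^T - \Pi^{-1} L^T\\
#'  -\psi^{-1} l & \psi^{-1} l a^T - L \Pi^{-1} & I + \psi^{-1} l l^T + L \Pi^{-1} L^T
#' \end{pmatrix}}
#'
#' Requires strictly positive private variances.
#'
#' @param params a [static_params()] object with `psi > 0` and `Psi > 0`.
#' @return The `(N+1+K) x (N+1+K)` precision matrix.
#' @export
precision_matrix <- function(params) {
  stopifnot(inherits(params, "cotula_params"))
  if (params$psi <= 0 || any(params$Psi <= 0))
    stop("precision matrix requires strictly positive private variances")
  N <- params$N; K <- params$K
  a <- params$a; l <- params$l; L <- params$L
  ipsi <- 1 / params$psi; iPi <- 1 / params$Psi
  P <- matrix(0, N + 1 + K, N + 1 + K)
  iy <- 1L; inot <- 1L + seq_len(N); iz <- N + 1L + seq_len(K)
  P[iy, iy] <- ipsi
  P[iy, inot] <- -ipsi * a; P[inot, iy] <- -ipsi * a
  P[iy, iz] <- -ipsi * l; P[iz, iy] <- -ipsi * l
  P[inot, inot] <- .diagv(iPi) + ipsi * tcrossprod(a)
  cross <- ipsi * outer(a, l) - t(L * rep(iPi, each = K))  # psi^-1 a l^T - Pi^-1 L^T
  P[inot, iz] <- cross; P[iz, inot] <- t(cross)
  P[iz, iz] <- diag(K) + ipsi * tcrossprod(l) + (L * rep(iPi, each = K)) %*% t(L)
  P
}

#' Marginal log-likelihood of observed activity under the static CoTuLa model
#'
#' Sums, over trials, the log density of the observed `(y_i, y_noti)` under the
#' `(N+1)`-dimensional Gaussian marginal of the joint distribution (latent
#' integrated out). The marginal covariance is the observed block of the
#' [joint_moments()] covariance and is shared across trials; the mean is
#' trial-specific through the stimulus.
#'
#' @param params a [static_params()] object.
#' @param data a [static_dataset()].
#' @return Scalar log-likelihood.
#' @export
marginal_loglik <- function(params, data) {
  stopifnot(inherits(params, "cotula_params"), inherits(data, "cotula_data"))
  if (data$N != params$N || data$M != params$M)
    stop("data dimensions do not match params")
  S <- joint_moments(params)$cov[seq_len(params$N + 1L), seq_len(params$N + 1L)]
  ch <- tryCatch(chol(S), error = function(e)
    stop("marginal covariance of (y_i, y_noti) is not positive definite"))
  # trial means
  Mu_not <- data$X %*% params$B                     # D x N
  if (!is.null(params$B0)) Mu_not <- sweep(Mu_not, 2L, params$B0, "+")
  mu_i <- drop(data$X %*% params$b) + drop(Mu_not %*% params$a)
  if (!is.null(params$b0)) mu_i <- mu_i + params$b0
  Rres <- cbind(data$y - mu_i, data$Y - Mu_not)     # D x (N+1)
  W <- forwardsolve(t(ch), t(Rres))                 # whitened residuals
  -0.5 * data$D * ((params$N + 1L) * log(2 * pi) + 2 * sum(log(diag(ch)))) -
    0.5 * sum(W * W)
}
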