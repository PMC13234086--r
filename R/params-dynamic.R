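#' Dynamic CoTuLa model parameters
#'
#' Parameterization of the dynamic (VAR(1)) coupling-tuning-latent model of a
#' simultaneously recorded population of `N` units driven by an
#' `M`-dimensional stimulus and a `K`-dimensional latent state:
#'
#' \deqn{y_t = A y_{t-1} + B x_t + L z_t + \psi_t,\qquad
#'       \psi_t \sim N(0, \Sigma)\ (\Sigma\ \mathrm{diagonal}),}
#' \deqn{z_t = G z_{t-1} + \eta_t,\ \eta_t \sim N(0, I_K),\qquad
#'       x_t = H x_{t-1} + \eta^x_t.}
#'
#' There is no target/non-target distinction in the dynamic case. The latent
#' innovation covariance is fixed to the identity; the stimulus innovation
#' variance defaults to `1 - h^2` per coordinate so the stationary stimulus
#' variance is 1 regardless of `H` (for diagonal `H`).
#'
#' @param A `N x N` coupling matrix, spectral radius `< 1`.
#' @param B `N x M` tuning matrix.
#' @param L `N x K` latent loading matrix.
#' @param Sigma private noise variances: length-`N` vector or diagonal matrix,
#'   entries `> 0`.
#' @param G `K x K` latent autoregression matrix, spectral radius `< 1`.
#' @param H `M x M` stimulus autoregression matrix (diagonal or full),
#'   spectral radius `< 1`. A scalar is expanded to `h I_M`.
#' @param sigma_x stimulus innovation standard deviations (length `M`);
#'   defaults to `sqrt(1 - diag(H)^2)`.
#' @return An object of class `"cotula_dyn_params"`.
#' @export
dynamic_params <- function(A, B, L, Sigma, G, H = 0, sigma_x = NULL) {
  A <- as.matrix(A); B <- as.matrix(B); L <- as.matrix(L); G <- as.matrix(G)
  N <- nrow(A); M <- ncol(B); K <- ncol(L)
  if (ncol(A) != N) stop("A must be square")
  if (nrow(B) != N || nrow(L) != N) stop("B and L must have N rows")
  if (!identical(dim(G), c(K, K))) stop("G must be K x K")
  if (length(H) == 1L) H <- diag(as.numeric(H), M)
  H <- as.matrix(H)
  if (!identical(dim(H), c(M, M))) stop("H must be M x M")
  Sigma <- if (is.matrix(Sigma)) diag(Sigma) else as.numeric(Sigma)
  if (length(Sigma) != N || any(Sigma <= 0))
    stop("Sigma must give N positive private variances")
  spec <- function(X) if (nrow(X)) max(abs(eigen(X, only.values = TRUE)$values)) else 0
  if (spec(A) >= 1 || spec(G) >= 1 || spec(H) >= 1)
    stop("A, G and H must each have spectral radius < 1 (stationarity)")
  if (is.null(sigma_x)) sigma_x <- sqrt(pmax(1 - diag(H)^2, 1e-12))
  structure(list(A = A, B = B, L = L, Sigma = Sigma, G = G, H = H,
                 sigma_x = as.numeric(sigma_x), N = N, M = M, K = K),
            class = "cotula_dyn_params")
}

#' @export
print.cotula_dyn_params <- function(x, ...) {
  spec <- function(X) max(abs(eigen(X, only.values = TRUE)$values))
  cat(sprintf("Dynamic CoTuLa parameters: N = %d units, M = %d stimulus features, K = %d latent\n",
              x$N, x$M, x$K))
  cat(sprintf("  spectral radii: coupling %.3f, latent AR %.3f, stimulus AR %.3f\n",
              spec(x$A), spec(x$G), spec(x$H)))
  invisible(x)
}

#' Univariate dynamic parameters
#'
#' Convenience constructor for the scalar (`N = M = K = 1`) dynamic CoTuLa
#' model with coupling `a`, tuning `b`, latent loading `ell`, latent AR
#' coefficient `g`, stimulus AR coefficient `h`, and private variance
#' `sigma2`.
#'
#' @param a,b,ell,g,h,sigma2 scalar parameters.
#' @return A `"cotula_dyn_params"` object.
#' @export
univariate_dynamic_params <- function(a, b, ell = 1, g = 0, h = 0, sigma2 = 1) {
  dynamic_params(A = matrix(a, 1, 1), B = matrix(b, 1, 1),
                 L = matrix(ell, 1, 1), Sigma = sigma2,
                 G = matrix(g, 1, 1), H = h)
}

#' Dynamic time-series dataset
#'
#' @param X `T x M` stimulus series.
#' @param Y `T x N` activity series.
#' @param Z optional `T x K` latent series (kept by the generator).
#' @return An object of class `"cotula_dyn_data"`.
#' @export
dynamic_dataset <- function(X, Y, Z = NULL) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  T_ <- nrow(Y)
  if (nrow(X) != T_ || (!is.null(Z) && nrow(Z) != T_))
    stop("X, Y (and Z) must share the same number of time points")
  if (!all(is.finite(X)) || !all(is.finite(Y)) ||
      (!is.null(Z) && !all(is.finite(Z))))
    stop("all entries must be finite")
  structure(list(X = X, Y = Y, Z = if (!is.null(Z)) as.matrix(Z),
                 T = T_, N = ncol(Y), M = ncol(X)),
            class = "cotula_dyn_data")
}

#' @export
print.cotula_dyn_data <- function(x, ...) {
  cat(sprintf("Dynamic dataset: T = %d time points, N = %d units, M = %d stimulus features\n",
              x$T, x$N, x$M))
  invisible(x)
}

#' Simulate a multivariate time series from the dynamic CoTuLa model
#'
#' Simulates the stimulus and latent AR(1) chains and the activity VAR(1)
#' recursion, discards `burn_in` initial steps, and returns the retained
#' series (including the latent draws).
#'
#' @param params a [dynamic_params()] object.
#' @param T number of retained time points.
#' @param burn_in number of discarded initial steps.
#' @param seed optional integer seed.
#' @return A [dynamic_dataset()] with `$Z` filled.
#' @export
generate_dynamic <- function(params, T, burn_in = 500L, seed = NULL) {
  stopifnot(inherits(params, "cotula_dyn_params"))
  if (T < 2L) stop("T must be >= 2")
  if (!is.null(seed)) set.seed(seed)
  N <- params$N; M <- params$M; K <- params$K
  Ttot <- T + burn_in
  # AR(1) chains; columns simulated jointly via the recursion
  X <- matrix(0, Ttot, M); Z <- matrix(0, Ttot, K); Y <- matrix(0, Ttot, N)
  Ex <- matrix(stats::rnorm(Ttot * M), Ttot, M) %*% .diagv(params$sigma_x)
  Ez <- matrix(stats::rnorm(Ttot * K), Ttot, K)
  Ey <- matrix(stats::rnorm(Ttot * N), Ttot, N) %*% .diagv(sqrt(params$Sigma))
  diag_H <- all(params$H[row(params$H) != col(params$H)] == 0)
  if (diag_H && all(params$G[row(params$G) != col(params$G)] == 0)) {
    # diagonal AR chains: vectorized per-coordinate recursive filter
    for (m in seq_len(M))
      X[, m] <- stats::filter(Ex[, m], params$H[m, m], method = "recursive")
    for (k in seq_len(K))
      Z[, k] <- stats::filter(Ez[, k], params$G[k, k], method = "recursive")
  } else {
    for (t in 2:Ttot) {
      X[t, ] <- params$H %*% X[t - 1L, ] + Ex[t, ]
      Z[t, ] <- params$G %*% Z[t - 1L, ] + Ez[t, ]
    }
    X[1L, ] <- Ex[1L, ]; Z[1L, ] <- Ez[1L, ]
  }
  drive <- X %*% t(params$B) + Z %*% t(params$L) + Ey
  if (all(params$A[row(params$A) != col(params$A)] == 0)) {
    for (n in seq_len(N))
      Y[, n] <- stats::filter(drive[, n], params$A[n, n], method = "recursive")
  } else {
    Y[1L, ] <- drive[1L, ]
    for (t in 2:Ttot) Y[t, ] <- params$A %*% Y[t - 1L, ] + drive[t, ]
  }
  keep <- burn_in + seq_len(T)
  dynamic_dataset(X[keep, , drop = FALSE], Y[keep, , drop = FALSE],
                  Z[keep, , drop = FALSE])
}

#' @describeIn generate_dynamic `simulate` method; `nsim` is the series length
#'   `T`.
#' @param object,nsim,... standard [stats::simulate()] arguments.
#' @export
simulate.cotula_dyn_params <- function(object, nsim = 1, seed = NULL, ...) {
  generate_dynamic(object, T = nsim, seed = seed, ...)
}

#' Stationary second moments of the univariate dynamic CoTuLa model
#'
#' Closed-form stationary values of `E[x^2]`, `E[z^2]` and `E[y^2]` for the
#' scalar model, from the lag-covariance equations of the joint linear system:
#' with `S_yx = b E[x^2] / (1 - a h)` and `S_yz = l E[z^2] / (1 - a g)`,
#' \deqn{E[y^2] = \frac{b^2 E[x^2]\frac{1+ah}{1-ah} +
#'   \ell^2 E[z^2]\frac{1+ag}{1-ag} + \sigma^2}{1 - a^2}.}
#'
#' @param params a univariate `"cotula_dyn_params"` object.
#' @return Named list with `Ey2`, `Ex2`, `Ez2`.
#' @export
stationary_moments_univariate <- function(params) {
  stopifnot(inherits(params, "cotula_dyn_params"))
  if (params$N != 1L || params$M != 1L || params$K != 1L)
    stop("closed-form stationary moments are for the univariate model")
  a <- params$A[1]; b <- params$B[1]; l <- params$L[1]
  g <- params$G[1]; h <- params$H[1]; s2 <- params$Sigma[1]
  Ex2 <- params$sigma_x[1]^2 / (1 - h^2)
  Ez2 <- 1 / (1 - g^2)
  Ey2 <- (b^2 * Ex2 * (1 + a * h) / (1 - a * h) +
            l^2 * Ez2 * (1 + a * g) / (1 - a * g) + s2) / (1 - a^2)
  list(Ey2 = Ey2, Ex2 = Ex2, Ez2 = Ez2)
}

#' Closed-form OLS systematic errors for the univariate dynamic model
#'
#' Normalized errors of the OLS coupling and tuning estimates when the plain
#' autoregressive coupling-tuning model is fit to data generated with
#' temporally correlated latent noise:
#' \deqn{\begin{pmatrix}(\hat a - a)/a\\(\hat b - b)/b\end{pmatrix} =
#'  \frac{ga}{1-ga}\cdot
#'  \frac{\ell^2 E[z^2]}{a^2 E[y^2] - (\frac{ha}{1-ha})^2 b^2 E[x^2]}
#'  \begin{pmatrix}1\\ -\frac{ha}{1-ha}\end{pmatrix}.}
#' With `g = 0` both errors vanish; with `h = 0` the tuning error vanishes.
#'
#' @param params a univariate `"cotula_dyn_params"` object.
#' @param moments `"stationary"` (closed-form stationary moments) or a list
#'   with elements `Ey2`, `Ex2`, `Ez2`.
#' @return Named numeric vector `c(rel_err_a, rel_err_b)`.
#' @export
analytic_univariate_errors <- function(params, moments = "stationary") {
  stopifnot(inherits(params, "cotula_dyn_params"))
  if (params$N != 1L || params$M != 1L || params$K != 1L)
    stop("analytic errors are derived for the univariate model")
  a <- params$A[1]; b <- params$B[1]; l <- params$L[1]
  g <- params$G[1]; h <- params$H[1]
  if (identical(moments, "stationary")) moments <- stationary_moments_univariate(params)
  if (1 - g * a == 0 || 1 - h * a == 0) stop("1 - ga and 1 - ha must be nonzero")
  hh <- h * a / (1 - h * a)
  denom <- a^2 * moments$Ey2 - hh^2 * b^2 * moments$Ex2
  fac <- (g * a / (1 - g * a)) * l^2 * moments$Ez2 / denom
  c(rel_err_a = fac, rel_err_b = -hh * fac)
}
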