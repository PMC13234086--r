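#' Static CoTuLa model parameters
#'
#' Container for the full parameterization of the static coupling-tuning-latent
#' (CoTuLa) generative model of trial-level neural activity. The observed
#' population has `N + 1` units: one *target* unit and `N` non-target units
#' (the target is, by convention, column 1 wherever the population is stored as
#' a single matrix). The target unit depends on the non-target activity
#' (coupling `a`), on an `M`-dimensional external stimulus (tuning `b`), and on
#' a `K`-dimensional latent state shared with the non-target units:
#'
#' \deqn{y_i = a^T y_{\neg i} + b^T x + l^T z + \psi_i,\qquad
#'       y_{\neg i} = B^T x + L^T z + \psi_{\neg i},\qquad z \sim N(0, I_K).}
#'
#' Setting `l`, `L` and the latent dimension aside (all-zero loadings)
#' recovers the plain coupling-tuning (CoTu) regression model.
#'
#' @param a numeric length-`N` coupling vector (target on non-targets).
#' @param b numeric length-`M` target tuning vector.
#' @param B `M x N` non-target tuning matrix (column j is unit j's tuning).
#' @param l numeric length-`K` target latent loading.
#' @param L `K x N` non-target latent loading matrix.
#' @param psi scalar target private variance, `>= 0`.
#' @param Psi numeric length-`N` non-target private variances, each `>= 0`.
#' @param b0 optional scalar target intercept.
#' @param B0 optional length-`N` non-target intercepts.
#'
#' @return An object of class `"cotula_params"`: a list with the above fields
#'   plus integer dimensions `N`, `M`, `K`.
#' @seealso [generate_static()], [joint_moments()], [apply_transform()]
#' @export
static_params <- function(a, b, B, l, L, psi, Psi, b0 = NULL, B0 = NULL) {
  a <- as.numeric(a); b <- as.numeric(b); l <- as.numeric(l)
  Psi <- as.numeric(Psi); psi <- as.numeric(psi)
  B <- as.matrix(B); L <- as.matrix(L)
  N <- length(a); M <- length(b); K <- length(l)
  if (!identical(dim(B), c(M, N)))
    stop("B must be M x N (", M, " x ", N, "), got ", nrow(B), " x ", ncol(B))
  if (!identical(dim(L), c(K, N)))
    stop("L must be K x N (", K, " x ", N, "), got ", nrow(L), " x ", ncol(L))
  if (length(psi) != 1L || psi < 0) stop("psi must be a scalar >= 0")
  if (length(Psi) != N || any(Psi < 0)) stop("Psi must be length N with entries >= 0")
  if (!is.null(b0) && length(b0) != 1L) stop("b0 must be a scalar")
  if (!is.null(B0) && length(B0) != N) stop("B0 must have length N")
  vals <- c(a, b, B, l, L, psi, Psi, b0, B0)
  if (any(!is.finite(vals))) stop("all parameters must be finite")
  structure(list(a = a, b = b, B = B, l = l, L = L, psi = psi, Psi = Psi,
                 b0 = b0, B0 = B0, N = N, M = M, K = K),
            class = "cotula_params")
}

#' @export
print.cotula_params <- function(x, ...) {
  cat("Static CoTuLa model parameters\n")
  cat(sprintf("  population: %d + 1 units, stimulus features M = %d, latent dim K = %d\n",
              x$N, x$M, x$K))
  cat(sprintf("  coupling a: %d nonzero of %d;  tuning b: %d nonzero of %d\n",
              sum(x$a != 0), x$N, sum(x$b != 0), x$M))
  cat(sprintf("  target private variance psi = %.4g\n", x$psi))
  if (!is.null(x$b0)) cat("  intercepts present\n")
  invisible(x)
}

# diag() that is safe for length-1 vectors
.diagv <- function(v) diag(v, nrow = length(v))

#' Model support mask
#'
#' Boolean pattern of free (TRUE) versus exactly-zero (FALSE) coupling and
#' tuning parameters. For static models the mask covers the target unit's
#' coupling vector (length `N`) and tuning vector (length `M`); for dynamic
#' models it covers the `N x N` coupling matrix and `N x M` tuning matrix. The
#' derived sparsity levels `k_C` and `k_T` are the fractions of exact zeros.
#'
#' @param coupling logical vector (static) or matrix (dynamic) for coupling.
#' @param tuning logical vector (static) or matrix (dynamic) for tuning.
#' @return An object of class `"cotula_support"` with elements `coupling`,
#'   `tuning`, `k_C`, `k_T`.
#' @export
support_mask <- function(coupling, tuning) {
  if (any(is.na(coupling)) || any(is.na(tuning)))
    stop("support entries must be TRUE/FALSE")
  coupling <- if (is.matrix(coupling)) coupling * TRUE > 0 else as.logical(coupling)
  tuning <- if (is.matrix(tuning)) tuning * TRUE > 0 else as.logical(tuning)
  structure(list(coupling = coupling, tuning = tuning,
                 k_C = mean(!coupling), k_T = mean(!tuning)),
            class = "cotula_support")
}

#' @export
print.cotula_support <- function(x, ...) {
  cat(sprintf("Model support: coupling %d/%d free (k_C = %.2f), tuning %d/%d free (k_T = %.2f)\n",
              sum(x$coupling), length(x$coupling), x$k_C,
              sum(x$tuning), length(x$tuning), x$k_T))
  invisible(x)
}

#' Oracle support of a parameter set
#'
#' The true pattern of nonzero coupling/tuning parameters, as used by the
#' "oracle selection" inference regime.
#'
#' @param params a `"cotula_params"` or `"cotula_dyn_params"` object.
#' @return A [support_mask()].
#' @export
oracle_support <- function(params) {
  if (inherits(params, "cotula_dyn_params"))
    support_mask(params$A != 0, params$B != 0)
  else
    support_mask(params$a != 0, params$b != 0)
}

#' Static trial-level dataset
#'
#' @param X `D x M` stimulus matrix.
#' @param Y `D x N` non-target activity matrix.
#' @param y length-`D` target activity vector.
#' @param Z optional `D x K` latent draws (kept by the generator).
#' @return An object of class `"cotula_data"`.
#' @export
static_dataset <- function(X, Y, y, Z = NULL) {
  X <- as.matrix(X); Y <- as.matrix(Y); y <- as.numeric(y)
  D <- nrow(X)
  if (nrow(Y) != D || length(y) != D || (!is.null(Z) && nrow(Z) != D))
    stop("X, Y, y (and Z) must have the same number of rows/trials")
  if (!all(is.finite(X)) || !all(is.finite(Y)) || !all(is.finite(y)) ||
      (!is.null(Z) && !all(is.finite(Z))))
    stop("all dataset entries must be finite")
  structure(list(X = X, Y = Y, y = y, Z = if (!is.null(Z)) as.matrix(Z),
                 D = D, N = ncol(Y), M = ncol(X)),
            class = "cotula_data")
}

#' @export
print.cotula_data <- function(x, ...) {
  cat(sprintf("Static dataset: D = %d trials, %d + 1 units, M = %d stimulus features%s\n",
              x$D, x$N, x$M, if (is.null(x$Z)) "" else sprintf(", latent draws (K = %d) retained", ncol(x$Z))))
  invisible(x)
}

#' Simulate trials from the static CoTuLa model
#'
#' Draws `D` i.i.d. trials. Per trial a stimulus `x` is drawn from
#' `stimulus_spec`, a shared latent `z ~ N(0, I_K)` feeds both the target and
#' the non-target units, private noise is Gaussian with variances `psi`/`Psi`,
#' and the activities follow the model equations (see [static_params()]).
#'
#' @param params a `"cotula_params"` object.
#' @param D number of trials, `>= 1`.
#' @param stimulus_spec stimulus distribution: `"gaussian"` (i.i.d. standard
#'   normal across trials and features, the default) or `"onehot"`
#'   (categorical: each trial activates one of the `M` levels uniformly).
#' @param seed optional integer seed (set with [set.seed()] when non-NULL).
#' @return A [static_dataset()] with the latent draws in `$Z`.
#' @export
generate_static <- function(params, D, stimulus_spec = c("gaussian", "onehot"),
                            seed = NULL) {
  stopifnot(inherits(params, "cotula_params"))
  if (D < 1) stop("D must be >= 1")
  stimulus_spec <- match.arg(stimulus_spec)
  if (!is.null(seed)) set.seed(seed)
  N <- params$N; M <- params$M; K <- params$K
  X <- switch(stimulus_spec,
    gaussian = matrix(stats::rnorm(D * M), D, M),
    onehot = {
      lev <- sample.int(M, D, replace = TRUE)
      X <- matrix(0, D, M); X[cbind(seq_len(D), lev)] <- 1; X
    })
  Z <- matrix(stats::rnorm(D * K), D, K)
  E <- matrix(stats::rnorm(D * N), D, N) %*% .diagv(sqrt(params$Psi))
  Y <- X %*% params$B + Z %*% params$L + E
  if (!is.null(params$B0)) Y <- sweep(Y, 2L, params$B0, "+")
  y <- drop(Y %*% params$a + X %*% params$b + Z %*% params$l) +
    stats::rnorm(D, sd = sqrt(params$psi))
  if (!is.null(params$b0)) y <- y + params$b0
  static_dataset(X, Y, y, Z)
}

#' @describeIn generate_static `simulate` method; `nsim` is the number of
#'   trials `D`.
#' @param object,nsim,... standard [stats::simulate()] arguments.
#' @export
simulate.cotula_params <- function(object, nsim = 1, seed = NULL, ...) {
  generate_static(object, D = nsim, seed = seed, ...)
}

#' Uniform-noise-correlation CoTuLa construction
#'
#' Builds a `K = 1` parameter set in which every unit (target and non-target)
#' has the identical latent loading `l` and private variance `psi`, chosen so
#' that the residual (noise) correlation between any pair of units equals
#' `rho` and each unit's residual variance is 1: `l = sqrt(rho)`,
#' `psi = 1 - rho`. Used to emulate uniform noise correlations across a
#' recorded population.
#'
#' @param a,b,B coupling vector, target tuning vector, non-target tuning matrix
#'   (as in [static_params()]).
#' @param rho target pairwise noise correlation in `[0, 1)`; default `0.10`.
#' @return A `"cotula_params"` object.
#' @export
uniform_correlation_params <- function(a, b, B, rho = 0.10) {
  if (rho < 0 || rho >= 1) stop("rho must be in [0, 1)")
  N <- length(a)
  static_params(a = a, b = b, B = B,
                l = sqrt(rho), L = matrix(sqrt(rho), 1, N),
                psi = 1 - rho, Psi = rep(1 - rho, N))
}
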