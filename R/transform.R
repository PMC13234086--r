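#' Identifiability transform of the static CoTuLa model
#'
#' The static CoTuLa model is structurally non-identifiable: for any direction
#' `delta` in the `K`-dimensional latent space there is a transformed parameter
#' set with identical marginal likelihood on every dataset. With
#' `P = (Pi + L^T L)^{-1}` (the non-target neural variability precision
#' matrix), the transform is linear in the target coupling, tuning and loading
#' and quadratic in the target private variance:
#'
#' \deqn{l' = l + \delta,\qquad a' = a - P L^T \delta,\qquad
#'       b' = b + B P L^T \delta,}
#' \deqn{\psi' = \psi - 2 l^T W \delta - \delta^T W \delta,\qquad
#'       W = I_K - L P L^T.}
#'
#' The quadratic metric `W` is exactly what makes the observed
#' `(y_i, y_noti)` covariance — and hence the marginal likelihood on every
#' dataset — invariant; this is checked against the likelihood-invariance
#' oracle in the test suite. Non-target parameters are unchanged. `delta` is
#' admissible only if
#' `psi' >= 0`; inadmissible directions are rejected (for `K = 1` the error
#' message reports the admissible interval, the two roots of the downward
#' parabola `psi'(delta)`).
#'
#' @param params a [static_params()] object.
#' @param delta numeric length-`K` transform direction.
#' @param tol admissibility tolerance on `psi' >= 0`.
#' @return The transformed `"cotula_params"` object.
#' @seealso [transform_family()], [check_identifiability()]
#' @export
apply_transform <- function(params, delta, tol = 1e-12) {
  stopifnot(inherits(params, "cotula_params"))
  delta <- as.numeric(delta)
  if (length(delta) != params$K) stop("delta must have length K = ", params$K)
  tr <- .transform_mats(params)
  psi2 <- params$psi - 2 * sum(tr$lproj * delta) -
    drop(crossprod(delta, tr$W %*% delta))
  if (psi2 < -tol) {
    msg <- "inadmissible delta: transformed private variance would be negative"
    if (params$K == 1L) {
      iv <- admissible_interval(params)
      msg <- sprintf("%s (admissible interval: [%.6g, %.6g])", msg, iv[1], iv[2])
    }
    stop(msg)
  }
  out <- params
  out$l <- params$l + delta
  out$a <- params$a - drop(tr$Q %*% delta)
  out$b <- params$b + drop(tr$R %*% delta)
  out$psi <- max(psi2, 0)
  out
}

# P, Q = P L^T, R = B Q, the quadratic metric W = I - L P L^T and W l
.transform_mats <- function(params) {
  L <- params$L
  P <- solve(.diagv(params$Psi) + crossprod(L))    # (Pi + L^T L)^{-1}, N x N
  Q <- P %*% t(L)                                  # N x K
  R <- params$B %*% Q                              # M x K
  W <- diag(params$K) - L %*% Q                    # I - L P L^T, K x K
  W <- (W + t(W)) / 2
  list(P = P, Q = Q, R = R, W = W, lproj = drop(W %*% params$l))
}

#' Admissible interval of the scalar identifiability transform (K = 1)
#'
#' For `K = 1` the transformed private variance
#' `psi'(delta) = psi - 2 c delta - w delta^2` is a downward parabola (with
#' scalars `w = 1 - L P L^T` in `(0, 1]` and `c = w l`); the admissible set
#' `psi' >= 0` is the interval between its roots
#' `(-c +- sqrt(c^2 + w psi)) / w`, and the apex (maximal `psi'`) sits at
#' `delta = -c / w`.
#'
#' @param params a [static_params()] object with `K = 1`.
#' @return Numeric length-2 vector, the interval endpoints.
#' @export
admissible_interval <- function(params) {
  stopifnot(inherits(params, "cotula_params"))
  if (params$K != 1L) stop("admissible interval is only computed for K = 1")
  tr <- .transform_mats(params)
  w <- drop(tr$W); cc <- tr$lproj
  r <- sqrt(cc^2 + w * params$psi)
  c((-cc - r) / w, (-cc + r) / w)
}

#' Equally spaced parameter configurations along an identifiability family
#'
#' For a `K = 1` model, returns `n_points` transformed parameter sets at
#' equally spaced `delta` values spanning the full admissible interval of
#' [apply_transform()]. All members have identical marginal likelihood; the
#' endpoints sit on the admissibility boundary (`psi' = 0`).
#'
#' @param params a [static_params()] object with `K = 1`.
#' @param n_points number of family members, `>= 2`.
#' @return A list of `"cotula_params"`; the `delta` values are attached as
#'   attribute `"delta"`.
#' @export
transform_family <- function(params, n_points = 30L) {
  stopifnot(inherits(params, "cotula_params"))
  if (params$K != 1L)
    stop("transform_family requires K = 1 (the family is a K-dimensional manifold)")
  if (n_points < 2L) stop("n_points must be >= 2")
  iv <- admissible_interval(params)
  deltas <- seq(iv[1], iv[2], length.out = n_points)
  fam <- lapply(deltas, function(d) apply_transform(params, d))
  attr(fam, "delta") <- deltas
  fam
}

#' Sparsity-based identifiability test
#'
#' Numeric test of the sufficient condition under which sparse support removes
#' the structural non-identifiability of the static CoTuLa model:
#' stack the rows of `Q = P L^T` indexed by the zero entries of the coupling
#' support and the rows of `R = B Q` indexed by the zero entries of the tuning
#' support into a matrix `S` (`(N k_C + M k_T) x K`). If `K <= N k_C + M k_T`
#' and `S` has full column rank `K`, the only support-preserving transform
#' direction is `delta = 0` and support-restricted estimation is identifiable.
#' The nullspace dimension of `S` counts the independent support-preserving
#' `delta` directions that remain.
#'
#' @param params a [static_params()] object.
#' @param support a [support_mask()] over the target coupling and tuning.
#' @return A list: `condition_holds` (sparsity inequality and full rank both
#'   satisfied), `rank_deficiency` (`K - rank(S)`, the support-preserving
#'   nullspace dimension), `rank_S`, `sparsity_ok` (`K <= N k_C + M k_T`),
#'   `S`, and `nullspace` (a `K x rank_deficiency` orthonormal basis of
#'   support-preserving directions).
#' @export
check_identifiability <- function(params, support) {
  stopifnot(inherits(params, "cotula_params"), inherits(support, "cotula_support"))
  if (length(support$coupling) != params$N || length(support$tuning) != params$M)
    stop("support dimensions do not match params")
  tr <- .transform_mats(params)
  S <- rbind(tr$Q[!support$coupling, , drop = FALSE],
             tr$R[!support$tuning, , drop = FALSE])
  K <- params$K
  n_zero <- nrow(S)  # N k_C + M k_T
  if (n_zero == 0L) {
    rank_S <- 0L
    null_basis <- diag(K)
  } else {
    sv <- svd(S, nu = 0, nv = K)
    d <- sv$d
    thr <- max(dim(S)) * .Machine$double.eps * max(d, 0)
    rank_S <- sum(d > thr)
    null_basis <- sv$v[, seq_len(K) > rank_S, drop = FALSE]
  }
  list(condition_holds = (K <= n_zero) && (rank_S == K),
       rank_deficiency = K - rank_S,
       rank_S = rank_S,
       sparsity_ok = K <= n_zero,
       S = S,
       nullspace = null_basis)
}
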