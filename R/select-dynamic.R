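#' Normalization-and-cutoff support inference for dynamic models
#'
#' Selects the dynamic model support from a plain CoTu OLS fit: each
#' coefficient of the estimated coupling matrix `A` and tuning matrix `B` is
#' normalized by a robust scale of its own matrix's entries (median absolute
#' deviation about zero), and entries whose normalized magnitude exceeds
#' `cutoff` are kept. Deterministic. This stands in for an appendix-level
#' selection heuristic; it exploits the fact that OLS noise on truly-zero
#' entries sets the MAD scale when the matrices are sparse.
#'
#' @param data a [dynamic_dataset()].
#' @param cutoff normalized-magnitude threshold (default 2.0 MADs).
#' @return A [support_mask()] with matrix-valued `coupling` and `tuning`.
#' @export
infer_support_dynamic <- function(data, cutoff = 2.0) {
  stopifnot(inherits(data, "cotula_dyn_data"))
  fit <- fit_dynamic_cotu_ols(data)
  score <- function(W) {
    s <- stats::mad(as.numeric(W), center = 0)
    if (s <= 0) s <- max(abs(W), .Machine$double.eps)
    abs(W) / s > cutoff
  }
  support_mask(score(fit$params$A), score(fit$params$B))
}

#' Temporal-structure summary (a, h, g)
#'
#' Scalar summaries of the temporal structure of a fitted dynamic dataset:
#' `a` is the eigenvalue with the largest real part of the estimated coupling
#' matrix; `h` is the corresponding eigenvalue of a VAR(1) autoregression
#' matrix fit to the stimulus series by least squares; `g` is the
#' corresponding eigenvalue of the latent autoregression matrix of a CoTuLa
#' fit (when supplied).
#'
#' @param A_hat estimated `N x N` coupling matrix.
#' @param X `T x M` stimulus series.
#' @param cotula_fit optional `"cotula_dyn_fit"` providing the fitted `G`.
#' @return Named numeric vector `c(a, h, g)` (real parts; `g = NA` without a
#'   CoTuLa fit).
#' @export
temporal_structure_summary <- function(A_hat, X, cotula_fit = NULL) {
  lead_eig <- function(W) {
    if (!nrow(W)) return(NA_real_)
    ev <- eigen(W, only.values = TRUE)$values
    Re(ev[which.max(Re(ev))])
  }
  X <- as.matrix(X)
  T_ <- nrow(X)
  H_hat <- t(solve(crossprod(X[-T_, , drop = FALSE]),
                   crossprod(X[-T_, , drop = FALSE], X[-1L, , drop = FALSE])))
  c(a = lead_eig(as.matrix(A_hat)),
    h = lead_eig(H_hat),
    g = if (is.null(cotula_fit)) NA_real_ else lead_eig(cotula_fit$params$G))
}
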