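# Restricted least-squares solve: pins inactive coordinates to exactly 0.
# G is the Gram matrix, r the right-hand side, active a logical vector.
.solve_restricted <- function(G, r, active) {
  w <- numeric(length(r))
  if (!any(active)) return(w)
  Ga <- G[active, active, drop = FALSE]
  sol <- tryCatch(solve(Ga, r[active]), error = function(e)
    stop("design is rank-deficient on the requested support"))
  w[active] <- sol
  w
}

#' Ordinary least squares fit of the static CoTu model
#'
#' Regresses the target activity on the non-target activities and the stimulus,
#' restricted to the columns marked free in `support`; off-support coefficients
#' are exactly 0. This is the estimation stage for the coupling-tuning model
#' without latent variables.
#'
#' @param data a [static_dataset()].
#' @param support a [support_mask()]; defaults to all-free.
#' @param intercept include an (always free) intercept term?
#' @return A `"cotula_fit"` object whose `$params` has latent dimension 0.
#' @export
fit_cotu_ols <- function(data, support = NULL, intercept = FALSE) {
  stopifnot(inherits(data, "cotula_data"))
  N <- data$N; M <- data$M
  if (is.null(support)) support <- support_mask(rep(TRUE, N), rep(TRUE, M))
  active <- c(support$coupling, support$tuning, intercept)
  if (data$D <= sum(active)) stop("D must exceed the number of active predictors")
  C <- cbind(data$Y, data$X, if (intercept) rep(1, data$D))
  w <- .solve_restricted(crossprod(C), drop(crossprod(C, data$y)),
                         c(support$coupling, support$tuning, rep(TRUE, intercept)))
  res <- data$y - drop(C %*% w)
  # non-target units: plain per-unit tuning regressions (shared across units)
  Xd <- cbind(data$X, if (intercept) rep(1, data$D))
  Wn <- solve(crossprod(Xd), crossprod(Xd, data$Y))          # (M[+1]) x N
  Rn <- data$Y - Xd %*% Wn
  params <- static_params(
    a = w[seq_len(N)], b = w[N + seq_len(M)],
    B = Wn[seq_len(M), , drop = FALSE],
    l = numeric(0), L = matrix(0, 0, N),
    psi = max(mean(res^2), 1e-12), Psi = pmax(colMeans(Rn^2), 1e-12),
    b0 = if (intercept) w[N + M + 1L], B0 = if (intercept) Wn[M + 1L, ])
  new_cotula_fit(params, loglik = marginal_loglik(params, data), n_iter = 0L,
                 converged = TRUE, support = support, model = "cotu")
}

#' E-step of the static CoTuLa EM algorithm
#'
#' Exact Gaussian posterior of the latent state given each trial's data: the
#' posterior covariance is shared across trials,
#' \deqn{\Sigma_q^{-1} = I_K + L \Pi^{-1} L^T}
#' (with `L` the full `K x (N+1)` loading and `Pi` all private variances), and
#' the per-trial mean is
#' \deqn{\mu^{(d)} = \Sigma_q [\, l\, \psi^{-1} r_i^{(d)} +
#'   L_{\neg i} \Pi_{\neg i}^{-1} r_{\neg i}^{(d)} ]}
#' with `r_i`, `r_noti` the structural residuals of the target and non-target
#' equations.
#'
#' @param params a [static_params()] with `K >= 1` and positive private
#'   variances.
#' @param data a [static_dataset()].
#' @return A list of class `"cotula_posterior"`: `mu` (`D x K` posterior
#'   means) and `Sigma` (`K x K` shared posterior covariance).
#' @export
em_e_step <- function(params, data) {
  stopifnot(inherits(params, "cotula_params"), inherits(data, "cotula_data"))
  if (params$K < 1L) stop("E-step requires K >= 1")
  if (params$psi <= 0 || any(params$Psi <= 0)) stop("private variances must be > 0")
  K <- params$K
  Lfull <- cbind(params$l, params$L)               # K x (N+1)
  ivar <- c(1 / params$psi, 1 / params$Psi)
  Sq_inv <- diag(K) + (Lfull * rep(ivar, each = K)) %*% t(Lfull)
  Sq <- solve(Sq_inv)
  Sq <- (Sq + t(Sq)) / 2
  Mu_not <- data$X %*% params$B
  if (!is.null(params$B0)) Mu_not <- sweep(Mu_not, 2L, params$B0, "+")
  r_i <- data$y - drop(data$X %*% params$b) - drop(data$Y %*% params$a)
  if (!is.null(params$b0)) r_i <- r_i - params$b0
  Rfull <- cbind(r_i, data$Y - Mu_not)             # D x (N+1)
  Mu <- Rfull %*% (t(Lfull) * ivar) %*% Sq         # D x K
  structure(list(mu = Mu, Sigma = Sq), class = "cotula_posterior")
}

#' M-step of the static CoTuLa EM algorithm
#'
#' Maximizer of the expected complete log-likelihood given posterior latent
#' statistics. The target equation's `(a, b, l)` are found by one joint
#' restricted least-squares solve against the predictors
#' `(y_noti, x, mu^(d))`, with the Gram matrix augmented by `D * Sigma_q` on
#' the latent block (off-support coupling/tuning entries pinned to 0, the
#' loading always free); each non-target unit's `(B, L)` row solves the
#' analogous problem against `(x, mu^(d))`. Private variances are the expected
#' residual quadratics, floored at `var_floor`.
#'
#' @param data a [static_dataset()].
#' @param post an [em_e_step()] result computed under `current`.
#' @param support a [support_mask()] over target coupling/tuning.
#' @param current the `"cotula_params"` the posterior was computed under (used
#'   for dimensions and intercept structure).
#' @param var_floor lower bound for the updated variances.
#' @return The updated `"cotula_params"`.
#' @export
em_m_step <- function(data, post, support, current, var_floor = 1e-8) {
  stopifnot(inherits(data, "cotula_data"), inherits(post, "cotula_posterior"))
  N <- data$N; M <- data$M; D <- data$D
  K <- ncol(post$mu)
  intercept <- !is.null(current$b0)
  Mu <- post$mu; Sq <- post$Sigma

  # target equation: predictors (Y, X, mu [, 1])
  C <- cbind(data$Y, data$X, Mu, if (intercept) rep(1, D))
  G <- crossprod(C)
  iz <- N + M + seq_len(K)
  G[iz, iz] <- G[iz, iz] + D * Sq
  active <- c(support$coupling, support$tuning, rep(TRUE, K), rep(TRUE, intercept))
  w <- .solve_restricted(G, drop(crossprod(C, data$y)), active)
  a_new <- w[seq_len(N)]; b_new <- w[N + seq_len(M)]; l_new <- w[iz]
  res <- data$y - drop(C %*% w)
  psi_new <- max((sum(res^2) + D * drop(crossprod(l_new, Sq %*% l_new))) / D,
                 var_floor)

  # non-target equations, row-wise: predictors (X, mu [, 1])
  Cn <- cbind(data$X, Mu, if (intercept) rep(1, D))
  Gn <- crossprod(Cn)
  izn <- M + seq_len(K)
  Gn[izn, izn] <- Gn[izn, izn] + D * Sq
  Wn <- tryCatch(solve(Gn, crossprod(Cn, data$Y)), error = function(e)
    stop("degenerate normal equations in the non-target M-step"))
  Resn <- data$Y - Cn %*% Wn
  Ln <- Wn[izn, , drop = FALSE]
  Psi_new <- pmax((colSums(Resn^2) +
                     D * colSums(Ln * (Sq %*% Ln))) / D, var_floor)

  static_params(a = a_new, b = b_new, B = Wn[seq_len(M), , drop = FALSE],
                l = l_new, L = Ln, psi = psi_new, Psi = Psi_new,
                b0 = if (intercept) w[length(w)],
                B0 = if (intercept) Wn[nrow(Wn), ])
}

# Default EM initialization: coupling/tuning from restricted OLS, loadings
# factor-analysis-style from the top-K eigenvectors of the per-unit residual
# covariance, private variances from the residual variances.
.init_static_em <- function(data, K, support, intercept = FALSE,
                            perturb_sd = 0, var_floor = 1e-8) {
  ols <- fit_cotu_ols(data, support, intercept = intercept)$params
  Xd <- cbind(data$X, if (intercept) rep(1, data$D))
  Mu_not <- data$X %*% ols$B
  if (intercept) Mu_not <- sweep(Mu_not, 2L, ols$B0, "+")
  r_i <- data$y - drop(data$Y %*% ols$a) - drop(data$X %*% ols$b)
  if (intercept) r_i <- r_i - ols$b0
  R <- cbind(r_i, data$Y - Mu_not)
  S <- crossprod(R) / data$D
  ev <- eigen(S, symmetric = TRUE)
  lam <- pmax(ev$values[seq_len(K)], var_floor)
  Lfull <- t(ev$vectors[, seq_len(K), drop = FALSE] %*% .diagv(sqrt(lam))) # K x (N+1)
  Psi_full <- pmax(diag(S) - colSums(Lfull^2), var_floor)
  if (perturb_sd > 0) {
    Lfull <- Lfull + matrix(stats::rnorm(length(Lfull), sd = perturb_sd),
                            nrow(Lfull))
    ols$a[support$coupling] <- ols$a[support$coupling] +
      stats::rnorm(sum(support$coupling), sd = perturb_sd)
    ols$b[support$tuning] <- ols$b[support$tuning] +
      stats::rnorm(sum(support$tuning), sd = perturb_sd)
  }
  static_params(a = ols$a, b = ols$b, B = ols$B,
                l = Lfull[, 1L], L = Lfull[, -1L, drop = FALSE],
                psi = Psi_full[1L], Psi = Psi_full[-1L],
                b0 = ols$b0, B0 = ols$B0)
}

#' EM fit of the static CoTuLa model
#'
#' Alternates [em_e_step()] and [em_m_step()] until the relative change in the
#' marginal log-likelihood falls below `tol` or `max_iter` sweeps are reached.
#' The marginal log-likelihood is recorded after every M-step and is
#' non-decreasing (an EM guarantee, checked by the test suite).
#'
#' @param data a [static_dataset()].
#' @param K latent dimension, `>= 1`.
#' @param support a [support_mask()] over the target coupling/tuning; defaults
#'   to all-free (the "no selection" regime).
#' @param init either `NULL` (deterministic OLS + factor-analysis-style
#'   initialization), a `"cotula_params"` object to start from, or an integer
#'   seed for a randomly perturbed initialization.
#' @param max_iter,tol EM iteration cap and relative log-likelihood tolerance.
#'   `tol = 0` always runs `max_iter` sweeps (useful for tracing EM's motion
#'   along likelihood-flat directions).
#' @param intercept include intercept terms?
#' @param var_floor variance floor passed to the M-step.
#' @return A `"cotula_fit"` with the estimate in `$params`, the per-iteration
#'   `$loglik_trace`, `$n_iter`, and `$converged` (never an error on
#'   non-convergence).
#' @export
fit_cotula_em <- function(data, K = 1L, support = NULL, init = NULL,
                          max_iter = 500L, tol = 1e-8, intercept = FALSE,
                          var_floor = 1e-8) {
  stopifnot(inherits(data, "cotula_data"))
  if (K < 1L) stop("K must be >= 1")
  N <- data$N; M <- data$M
  if (is.null(support)) support <- support_mask(rep(TRUE, N), rep(TRUE, M))
  params <- if (inherits(init, "cotula_params")) {
    if (init$K != K) stop("init has latent dimension ", init$K, ", expected ", K)
    init$psi <- max(init$psi, var_floor)   # boundary inits (psi = 0) admitted
    init$Psi <- pmax(init$Psi, var_floor)
    init
  } else if (is.numeric(init)) {
    set.seed(as.integer(init))
    .init_static_em(data, K, support, intercept, perturb_sd = 0.1,
                    var_floor = var_floor)
  } else {
    .init_static_em(data, K, support, intercept, var_floor = var_floor)
  }
  trace <- numeric(0)
  ll_old <- marginal_loglik(params, data)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    post <- em_e_step(params, data)
    params <- em_m_step(data, post, support, params, var_floor = var_floor)
    ll <- marginal_loglik(params, data)
    trace <- c(trace, ll)
    if (tol > 0 && abs(ll - ll_old) <= tol * (abs(ll_old) + tol)) {
      converged <- TRUE
      break
    }
    ll_old <- ll
  }
  new_cotula_fit(params, loglik = trace, n_iter = iter, converged = converged,
                 support = support, model = "cotula")
}

new_cotula_fit <- function(params, loglik, n_iter, converged, support,
                           model, regime = NULL) {
  structure(list(params = params, loglik_trace = loglik, n_iter = n_iter,
                 converged = converged, support = support, model = model,
                 regime = regime),
            class = "cotula_fit")
}

#' Fit a static coupling-tuning model to trial data
#'
#' Front-end for static model fitting under the three model-support regimes.
#' `selection = "none"` estimates all parameters; `"oracle"` restricts
#' estimation to a user-supplied true support; `"inferred"` first runs
#' [infer_support_static()] and then estimates on the inferred support
#' (selection-then-estimation).
#'
#' @param data a [static_dataset()].
#' @param model `"cotula"` (EM with `K` latent factors) or `"cotu"` (OLS).
#' @param selection model-support regime.
#' @param K latent dimension for the CoTuLa model.
#' @param support the support to use for `selection = "oracle"` (a
#'   [support_mask()], typically [oracle_support()] of the generating
#'   parameters).
#' @param selection_control list of arguments forwarded to
#'   [infer_support_static()].
#' @param ... further arguments to [fit_cotula_em()] or [fit_cotu_ols()].
#' @return A `"cotula_fit"` object.
#' @examples
#' truth <- uniform_correlation_params(a = c(0.5, 0, 0.5), b = c(1, 0),
#'                                     B = matrix(0.5, 2, 3))
#' dat <- generate_static(truth, D = 500, seed = 1)
#' fit <- cotula_static(dat, model = "cotula", selection = "oracle",
#'                      support = oracle_support(truth))
#' coef(fit)
#' @export
cotula_static <- function(data, model = c("cotula", "cotu"),
                          selection = c("none", "oracle", "inferred"),
                          K = 1L, support = NULL, selection_control = list(),
                          ...) {
  model <- match.arg(model)
  selection <- match.arg(selection)
  supp <- switch(selection,
    none = support_mask(rep(TRUE, data$N), rep(TRUE, data$M)),
    oracle = {
      if (is.null(support)) stop("oracle selection requires `support`")
      support
    },
    inferred = do.call(infer_support_static, c(list(data = data), selection_control)))
  fit <- if (model == "cotula") fit_cotula_em(data, K = K, support = supp, ...)
         else fit_cotu_ols(data, support = supp, ...)
  fit$regime <- selection
  fit
}

#' @export
print.cotula_fit <- function(x, ...) {
  cat(sprintf("%s fit (%s selection): ", toupper(x$model),
              if (is.null(x$regime)) "explicit" else x$regime))
  if (x$model == "cotula")
    cat(sprintf("K = %d, %d EM iterations, %sconverged\n", x$params$K, x$n_iter,
                if (x$converged) "" else "NOT "))
  else cat("OLS\n")
  cat(sprintf("  marginal log-likelihood: %.4f\n", utils::tail(x$loglik_trace, 1)))
  invisible(x)
}

#' @export
coef.cotula_fit <- function(object, ...) {
  p <- object$params
  stats::setNames(c(p$a, p$b),
                  c(paste0("a", seq_along(p$a)), paste0("b", seq_along(p$b))))
}

#' @export
summary.cotula_fit <- function(object, ...) {
  p <- object$params
  out <- list(model = object$model, regime = object$regime,
              n_iter = object$n_iter, converged = object$converged,
              loglik = utils::tail(object$loglik_trace, 1),
              coupling = p$a, tuning = p$b, psi = p$psi, K = p$K,
              support = object$support)
  class(out) <- "summary.cotula_fit"
  out
}

#' @export
print.summary.cotula_fit <- function(x, ...) {
  cat(sprintf("%s model, %s selection\n", toupper(x$model),
              if (is.null(x$regime)) "explicit" else x$regime))
  cat(sprintf("log-likelihood %.4f after %d iterations (converged: %s)\n",
              x$loglik, x$n_iter, x$converged))
  cat("coupling a:\n"); print(signif(x$coupling, 4))
  cat("tuning b:\n"); print(signif(x$tuning, 4))
  cat(sprintf("target private variance: %.4g\n", x$psi))
  invisible(x)
}

#' @export
predict.cotula_fit <- function(object, newdata, ...) {
  p <- object$params
  out <- drop(newdata$Y %*% p$a) + drop(newdata$X %*% p$b)
  if (!is.null(p$b0)) out <- out + p$b0
  out
}

#' @export
residuals.cotula_fit <- function(object, data, ...) {
  data$y - predict(object, data)
}

#' @export
plot.cotula_fit <- function(x, ...) {
  plot(seq_along(x$loglik_trace), x$loglik_trace, type = "b",
       xlab = "EM iteration", ylab = "marginal log-likelihood", ...)
  invisible(x)
}
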