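test_that("dynamic E-step returns the latent-chain prior when loadings vanish", {
  p <- rand_dynamic(N = 3, M = 2, K = 1, seed = 1)
  p$L[] <- 0
  d <- generate_dynamic(p, 30, seed = 2)
  post <- dynamic_e_step(p, d)
  expect_equal(max(abs(post$mu)), 0)
  # with K = 1 and G = 0 the posterior factorizes over time
  p0 <- p; p0$G <- matrix(0, 1, 1)
  post0 <- dynamic_e_step(p0, d)
  expect_equal(max(abs(post0$C)), 0)
})

test_that("Kalman/RTS E-step equals the dense block-tridiagonal inverse", {
  for (s in 1:8) {
    K <- sample(1:3, 1)
    p <- rand_dynamic(N = sample(2:4, 1), M = 2, K = K, seed = 10 + s)
    d <- generate_dynamic(p, sample(5:20, 1), seed = 40 + s)
    post <- dynamic_e_step(p, d)
    or <- dense_dyn_posterior(p, d)
    expect_lt(max(abs(post$mu - or$mu)), 1e-9)
    for (t in seq_len(or$n)) {
      blk <- or$Lam[((t - 1) * K + 1):(t * K), ((t - 1) * K + 1):(t * K)]
      expect_lt(max(abs(post$V[, , t] - blk)), 1e-9)
    }
    for (t in seq_len(or$n - 1)) {
      blk <- or$Lam[((t - 1) * K + 1):(t * K), (t * K + 1):((t + 1) * K)]
      expect_lt(max(abs(post$C[, , t] - blk)), 1e-9)
    }
  }
})

test_that("expected log-likelihood matches the dense-matrix computation", {
  p <- rand_dynamic(N = 3, M = 2, K = 2, seed = 3)
  d <- generate_dynamic(p, 10, seed = 4)
  post <- dynamic_e_step(p, d)
  or <- dense_dyn_posterior(p, d)
  mu_vec <- as.numeric(t(or$mu))
  rt <- as.numeric(t(or$R))
  brute <- -0.5 * (sum((rt - or$Lt %*% mu_vec)^2 * rep(1 / p$Sigma, or$n)) +
                     sum(diag(t(or$Lt) %*% or$Sti %*% or$Lt %*% or$Lam)) +
                     drop(t(mu_vec) %*% t(or$DG) %*% or$DG %*% mu_vec) +
                     sum(diag(t(or$DG) %*% or$DG %*% or$Lam))) -
    0.5 * or$n * sum(log(p$Sigma))
  expect_equal(dynamic_expected_loglik(p, d, post), brute, tolerance = 1e-8)
})

test_that("M-step increases the expected log-likelihood and EM trace is monotone", {
  truth <- rand_dynamic(N = 3, M = 2, K = 1, seed = 5)
  d <- generate_dynamic(truth, 800, seed = 6)
  p0 <- rand_dynamic(N = 3, M = 2, K = 1, seed = 7)
  post <- dynamic_e_step(p0, d)
  supp <- support_mask(matrix(TRUE, 3, 3), matrix(TRUE, 3, 2))
  p1 <- cotula:::.dyn_m_step(d, post, supp, K = 1)
  expect_gte(dynamic_expected_loglik(p1, d, post),
             dynamic_expected_loglik(p0, d, post) - 1e-8)
  fit <- fit_dynamic_cotula_em(d, K = 1, max_iter = 40)
  tr <- fit$loglik_trace
  expect_true(all(diff(tr) >= -1e-8 * abs(tr[-1])))
})

test_that("dynamic OLS is consistent without a latent confounder", {
  truth <- rand_dynamic(N = 3, M = 2, K = 1, seed = 8)
  truth$L[] <- 0
  d <- generate_dynamic(truth, 2e4, seed = 9)
  err <- normalized_error(fit_dynamic_cotu_ols(d), truth)
  expect_lt(median(abs(err$coupling)), 0.05)
  expect_lt(median(abs(err$tuning)), 0.05)
})

test_that("univariate dynamic OLS reproduces the analytic systematic errors", {
  p <- univariate_dynamic_params(a = 0.5, b = 1, ell = 1, g = 0.6, h = 0)
  d <- generate_dynamic(p, 1e5, seed = 10)
  fit <- fit_dynamic_cotu_ols(d)
  ana <- analytic_univariate_errors(p)
  emp_a <- (fit$params$A[1, 1] - 0.5) / 0.5
  expect_gt(emp_a, 0)                               # coupling overestimated
  expect_equal(emp_a, unname(ana["rel_err_a"]),
               tolerance = 0.08 * ana["rel_err_a"])
  expect_lt(abs(fit$params$B[1, 1] - 1), 0.02)      # tuning error ~ 0
})

test_that("oracle-support dynamic EM recovers sparse truth", {
  set.seed(11)
  A <- diag(0.5, 3); A[1, 2] <- 0.3
  B <- matrix(0, 3, 2); B[cbind(1:3, c(1, 2, 1))] <- 1
  truth <- dynamic_params(A = A, B = B, L = matrix(1, 3, 1),
                          Sigma = rep(1, 3), G = matrix(0.6, 1, 1), H = 0.6)
  d <- generate_dynamic(truth, 4000, seed = 12)
  fit <- fit_dynamic_cotula_em(d, K = 1, support = oracle_support(truth),
                               max_iter = 60, tol = 1e-7)
  err <- normalized_error(fit, truth)
  expect_lt(median(abs(c(err$coupling, err$tuning))), 0.1)
  # off-support entries exactly zero
  expect_identical(fit$params$A[A == 0], rep(0, sum(A == 0)))
})

test_that("normalization-and-cutoff selection recovers well-separated dynamic supports", {
  set.seed(13)
  A <- matrix(0, 4, 4); diag(A) <- 0.5; A[1, 2] <- -0.5
  B <- matrix(0, 4, 4); B[cbind(1:4, 1:4)] <- 0.5
  truth <- dynamic_params(A = A, B = B, L = matrix(0.3, 4, 1),
                          Sigma = rep(0.2, 4), G = matrix(0.3, 1, 1), H = 0.3)
  d <- generate_dynamic(truth, 5000, seed = 14)
  s <- infer_support_dynamic(d)
  expect_identical(s$coupling, A != 0)
  expect_identical(s$tuning, B != 0)
  # all-zero coupling: near-empty coupling support
  truth0 <- dynamic_params(A = matrix(0, 4, 4), B = B,
                           L = matrix(0.3, 4, 1), Sigma = rep(0.2, 4),
                           G = matrix(0.3, 1, 1), H = 0.3)
  d0 <- generate_dynamic(truth0, 5000, seed = 15)
  s0 <- infer_support_dynamic(d0)
  expect_lte(sum(s0$coupling), 2)
})

test_that("temporal-structure summary extracts the leading autoregressive scales", {
  expect_equal(unname(temporal_structure_summary(
    diag(c(0.2, 0.7)), matrix(rnorm(100), 50, 2))["a"]), 0.7)
  p <- univariate_dynamic_params(a = 0.3, b = 1, g = 0.2, h = 0.6)
  d <- generate_dynamic(p, 1e5, seed = 16)
  fit <- fit_dynamic_cotula_em(d, K = 1, max_iter = 30, tol = 1e-6)
  ts <- temporal_structure_summary(fit$params$A, d$X, fit)
  expect_equal(unname(ts["h"]), 0.6, tolerance = 0.02)
  expect_true(is.finite(ts["g"]))
})
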