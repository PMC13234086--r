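test_that("CoTu OLS is consistent without latent confounding", {
  set.seed(20)
  N <- 6; M <- 4
  truth <- static_params(a = rnorm(N, 0.5, 0.1), b = rnorm(M, 0.5, 0.1),
                         B = matrix(rnorm(M * N), M, N),
                         l = 0, L = matrix(0, 1, N), psi = 0.5, Psi = rep(1, N))
  d <- generate_static(truth, 1e4, seed = 21)
  fit <- fit_cotu_ols(d)
  err <- normalized_error(fit, truth)
  expect_lt(median(abs(err$coupling)), 0.05)
  expect_lt(median(abs(err$tuning)), 0.05)
  # errors shrink with sample size
  err_small <- normalized_error(fit_cotu_ols(generate_static(truth, 500,
                                                             seed = 21)),
                                truth)
  expect_lt(median(abs(err$tuning)), median(abs(err_small$tuning)))
})

test_that("masking a truly-zero orthogonal column leaves active OLS coefficients unchanged", {
  set.seed(22)
  D <- 400
  X <- matrix(rnorm(D * 2), D, 2)
  Yn <- cbind(rnorm(D), rnorm(D))
  # make column 2 exactly orthogonal to the other predictors jointly
  Co <- cbind(Yn[, 1], X)
  Yn[, 2] <- Yn[, 2] - Co %*% solve(crossprod(Co), crossprod(Co, Yn[, 2]))
  y <- 0.8 * Yn[, 1] + drop(X %*% c(1, -1)) + rnorm(D, 0, 0.1)
  d <- static_dataset(X, Yn, y)
  full <- fit_cotu_ols(d)
  masked <- fit_cotu_ols(d, support_mask(c(TRUE, FALSE), c(TRUE, TRUE)))
  expect_equal(masked$params$a[1], full$params$a[1], tolerance = 1e-10)
  expect_equal(masked$params$b, full$params$b, tolerance = 1e-10)
  expect_identical(masked$params$a[2], 0)
})

test_that("OLS rejects rank-deficient designs on the requested support", {
  set.seed(23)
  X <- matrix(rnorm(60), 30, 2)
  Yn <- cbind(rnorm(30), 0)  # constant zero column
  d <- static_dataset(X, Yn, rnorm(30))
  expect_error(fit_cotu_ols(d), "rank-deficient")
})

test_that("E-step returns the prior when loadings vanish", {
  p <- rand_static(seed = 24)
  p$l[] <- 0; p$L[] <- 0
  d <- generate_static(p, 50, seed = 25)
  post <- em_e_step(p, d)
  expect_equal(max(abs(post$mu)), 0)
  expect_equal(post$Sigma, diag(p$K))
})

test_that("E-step equals conditioning the full joint Gaussian", {
  p <- rand_static(N = 4, M = 3, K = 2, seed = 26)
  d <- generate_static(p, 3, seed = 27)
  post <- em_e_step(p, d)
  S <- joint_moments(p)$cov
  iobs <- seq_len(p$N + 1); iz <- p$N + 1 + seq_len(p$K)
  Szy <- S[iz, iobs]; Syy <- S[iobs, iobs]
  cond_cov <- S[iz, iz] - Szy %*% solve(Syy) %*% t(Szy)
  expect_equal(post$Sigma, cond_cov, tolerance = 1e-10)
  mu_not <- d$X %*% p$B
  mu_i <- drop(d$X %*% p$b) + drop(mu_not %*% p$a)
  for (t in 1:3) {
    r <- c(d$y[t] - mu_i[t], d$Y[t, ] - mu_not[t, ])
    expect_equal(post$mu[t, ], drop(Szy %*% solve(Syy) %*% r),
                 tolerance = 1e-10)
  }
  # posterior precision equals the latent block of the joint precision
  expect_equal(solve(post$Sigma), precision_matrix(p)[iz, iz],
               tolerance = 1e-8)
})

test_that("M-step solves the expected complete-likelihood stationarity conditions", {
  p <- rand_static(N = 4, M = 3, K = 2, seed = 28)
  d <- generate_static(p, 300, seed = 29)
  supp <- support_mask(c(FALSE, rep(TRUE, 3)), rep(TRUE, 3))
  post <- em_e_step(p, d)
  up <- em_m_step(d, post, supp, p)
  expect_identical(up$a[1], 0)
  # numeric gradient of the fixed-posterior objective is ~0 on active coords
  grad <- function(get, set) {
    eps <- 1e-6
    pp <- up; pm <- up
    set(pp, get(up) + eps); set(pm, get(up) - eps)
    (q_static(pp, d, post) - q_static(pm, d, post)) / (2 * eps)
  }
  for (j in 2:4) {
    pp <- up; pm <- up; eps <- 1e-6
    pp$a[j] <- pp$a[j] + eps; pm$a[j] <- pm$a[j] - eps
    expect_lt(abs(q_static(pp, d, post) - q_static(pm, d, post)) / (2 * eps),
              1e-4)
  }
  for (j in 1:3) {
    pp <- up; pm <- up; eps <- 1e-6
    pp$b[j] <- pp$b[j] + eps; pm$b[j] <- pm$b[j] - eps
    expect_lt(abs(q_static(pp, d, post) - q_static(pm, d, post)) / (2 * eps),
              1e-4)
    pp <- up; pm <- up
    pp$l[1] <- pp$l[1] + eps; pm$l[1] <- pm$l[1] - eps
    expect_lt(abs(q_static(pp, d, post) - q_static(pm, d, post)) / (2 * eps),
              1e-4)
  }
  pp <- up; pm <- up; eps <- 1e-6
  pp$B[2, 3] <- pp$B[2, 3] + eps; pm$B[2, 3] <- pm$B[2, 3] - eps
  expect_lt(abs(q_static(pp, d, post) - q_static(pm, d, post)) / (2 * eps),
            1e-4)
  pp <- up; pm <- up
  pp$L[1, 2] <- pp$L[1, 2] + eps; pm$L[1, 2] <- pm$L[1, 2] - eps
  expect_lt(abs(q_static(pp, d, post) - q_static(pm, d, post)) / (2 * eps),
            1e-4)
})

test_that("M-step degenerates to OLS when loadings carry no information", {
  p <- rand_static(K = 1, seed = 30)
  p$l[] <- 0; p$L[] <- 0
  d <- generate_static(p, 500, seed = 31)
  supp <- support_mask(rep(TRUE, p$N), rep(TRUE, p$M))
  post <- em_e_step(p, d)   # mu = 0, Sigma = I
  up <- em_m_step(d, post, supp, p)
  ols <- fit_cotu_ols(d)$params
  expect_equal(up$a, ols$a, tolerance = 1e-10)
  expect_equal(up$b, ols$b, tolerance = 1e-10)
  expect_equal(up$l, 0)
})

test_that("one EM sweep never decreases the marginal likelihood", {
  d <- generate_static(rand_sparse_static(seed = 32), 400, seed = 33)
  for (s in 1:50) {
    p0 <- rand_static(N = 8, M = 6, K = 1, seed = 400 + s, a_sd = 0.5)
    ll0 <- marginal_loglik(p0, d)
    supp <- support_mask(rep(TRUE, 8), rep(TRUE, 6))
    p1 <- em_m_step(d, em_e_step(p0, d), supp, p0)
    expect_gte(marginal_loglik(p1, d), ll0 - 1e-9 * abs(ll0))
  }
})

test_that("EM trace is monotone and oracle-support EM recovers sparse truth", {
  truth <- rand_sparse_static(seed = 34)
  d <- generate_static(truth, 4000, seed = 35)
  fit <- fit_cotula_em(d, K = 1, support = oracle_support(truth))
  tr <- fit$loglik_trace
  expect_true(all(diff(tr) >= -1e-9 * abs(tr[-1])))
  err <- normalized_error(fit, truth)
  expect_lt(median(abs(c(err$coupling, err$tuning))), 0.05)
})

test_that("EM reports non-convergence instead of raising", {
  d <- generate_static(rand_sparse_static(seed = 36), 500, seed = 37)
  fit <- fit_cotula_em(d, K = 1, max_iter = 2)
  expect_false(fit$converged)
  expect_identical(fit$n_iter, 2L)
})

test_that("unselected estimation on correlated data shows the systematic error signature", {
  # positive coupling/tuning means, uniform positive noise correlations:
  # coupling is overestimated, tuning magnitude underestimated
  truth <- rand_sparse_static(seed = 38, mean_a = 0.5, mean_b = 0.5)
  d <- generate_static(truth, 4000, seed = 39)
  raw_cotu <- normalized_error(fit_cotu_ols(d), truth)$raw
  expect_gt(min(raw_cotu$coupling), 0)
  expect_lt(median(raw_cotu$tuning), 0)
  raw_em <- normalized_error(fit_cotula_em(d, K = 1), truth)$raw
  expect_gt(median(raw_em$coupling), 0)
  expect_lt(median(raw_em$tuning), 0)
})

test_that("intercept variant recovers intercepts", {
  set.seed(40)
  N <- 4; M <- 3
  truth <- static_params(a = c(0.5, 0, 0.4, 0), b = c(1, 0, 0.5),
                         B = matrix(rnorm(M * N, 0.3, 0.1), M, N),
                         l = sqrt(0.1), L = matrix(sqrt(0.1), 1, N),
                         psi = 0.9, Psi = rep(0.9, N),
                         b0 = 1.5, B0 = seq(-1, 0.5, length.out = N))
  d <- generate_static(truth, 4000, seed = 41)
  fit <- fit_cotula_em(d, K = 1, support = oracle_support(truth),
                       intercept = TRUE)
  expect_equal(fit$params$b0, 1.5, tolerance = 0.15)
  expect_equal(fit$params$B0, truth$B0, tolerance = 0.15)
  tr <- fit$loglik_trace
  expect_true(all(diff(tr) >= -1e-9 * abs(tr[-1])))
})

test_that("bootstrap-lasso support inference recovers strongly separated supports", {
  set.seed(42)
  N <- 8; M <- 6
  a <- numeric(N); a[c(1, 4, 6)] <- c(1, -1, 1)
  b <- numeric(M); b[c(2, 5)] <- c(1, -1)
  truth <- static_params(a = a, b = b, B = matrix(0, M, N), l = 0,
                         L = matrix(0, 1, N), psi = 0.01, Psi = rep(1, N))
  d <- generate_static(truth, 2000, seed = 43)
  s <- infer_support_static(d, seed = 9)
  expect_identical(unname(s$coupling), unname(a != 0))
  expect_identical(unname(s$tuning), unname(b != 0))
  # deterministic given the seed
  s2 <- infer_support_static(d, seed = 9)
  expect_identical(s, s2)
  # pure-noise target: near-empty support
  s3 <- infer_support_static(static_dataset(d$X, d$Y, rnorm(2000)), seed = 9)
  expect_lte(sum(s3$coupling) + sum(s3$tuning), 2)
})

test_that("normalized errors and the aggregation scheme are computed exactly", {
  truth <- rand_sparse_static(seed = 44)
  expect_true(all(normalized_error(truth, truth)$coupling == 0))
  twice <- truth; twice$a <- 2 * truth$a; twice$b <- 2 * truth$b
  ne <- normalized_error(twice, truth)
  expect_true(all(abs(c(ne$coupling, ne$tuning) - 1) < 1e-12))
  expect_identical(ne$n_excluded,
                   sum(truth$a == 0) + sum(truth$b == 0))
  # hand-checked toy: 2 models x 2 replicates x 2 parameters
  errs <- list(model1 = list(c(0.1, 0.3), c(0.3, 0.5)),
               model2 = list(c(1.0, 0.0), c(0.0, 0.2)))
  # means over reps: m1 = (0.2, 0.4); m2 = (0.5, 0.1)
  # medians over models (per param): (0.35, 0.25); median over params: 0.3
  expect_equal(aggregate_errors(errs), 0.3)
})
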