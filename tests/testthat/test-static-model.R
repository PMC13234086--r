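test_that("generator reduces to pure noise in the decoupled limit", {
  N <- 4; M <- 3
  p <- static_params(a = rep(0, N), b = rep(0, M), B = matrix(0, M, N),
                     l = 0, L = matrix(0, 1, N), psi = 1, Psi = rep(1, N))
  d <- generate_static(p, 5e4, seed = 1)
  expect_equal(var(d$y), 1, tolerance = 0.03)
  expect_equal(unname(apply(d$Y, 2, var)), rep(1, N), tolerance = 0.05)
})

test_that("uniform-correlation construction calibrates pairwise noise correlations", {
  p <- rand_sparse_static(seed = 10, rho = 0.10)
  d <- generate_static(p, 5e4, seed = 2)
  res <- cbind(d$y - drop(d$X %*% p$b) - drop(d$Y %*% p$a),
               d$Y - d$X %*% p$B)
  cc <- cor(res)
  expect_equal(mean(cc[lower.tri(cc)]), 0.10, tolerance = 0.01)
})

test_that("generator rejects invalid inputs", {
  p <- rand_static(seed = 3)
  expect_error(generate_static(p, 0), "D")
  expect_error(static_params(a = 0, b = 0, B = matrix(0, 1, 1), l = 0,
                             L = matrix(0, 1, 1), psi = -1, Psi = 1),
               "psi")
})

test_that("empirical covariance of generated trials matches the analytic joint moments", {
  p <- rand_static(seed = 4)
  d <- generate_static(p, 5e4, seed = 5)
  mu_not <- d$X %*% p$B
  mu_i <- drop(d$X %*% p$b) + drop(mu_not %*% p$a)
  emp <- cov(cbind(d$y - mu_i, d$Y - mu_not, d$Z))
  expect_lt(max(abs(emp - joint_moments(p)$cov)), 0.15)
})

test_that("joint covariance is block diagonal in the decoupled limit", {
  N <- 3; M <- 2; K <- 2
  p <- static_params(a = rep(0, N), b = rnorm(M), B = matrix(rnorm(M * N), M, N),
                     l = rep(0, K), L = matrix(0, K, N),
                     psi = 0.7, Psi = seq(0.5, 1.5, length.out = N))
  cv <- joint_moments(p)$cov
  expect_equal(cv, diag(c(0.7, p$Psi, rep(1, K))))
})

test_that("closed-form precision inverts the joint covariance", {
  for (s in 1:25) {
    p <- rand_static(N = sample(2:6, 1), M = sample(1:5, 1),
                     K = sample(1:3, 1), seed = 100 + s)
    cv <- joint_moments(p)$cov
    pr <- precision_matrix(p)
    expect_lt(max(abs(cv %*% pr - diag(nrow(pr)))), 1e-10)
    expect_lt(max(abs(pr - t(pr))), 1e-12)
  }
})

test_that("precision matrix rejects zero private variance", {
  p <- rand_static(seed = 6)
  p$psi <- 0
  expect_error(precision_matrix(p), "positive")
})

test_that("marginal log-likelihood matches a hand-computed bivariate normal", {
  # one trial, N = M = K = 1, all unit parameters
  p <- static_params(a = 1, b = 1, B = matrix(1, 1, 1), l = 1,
                     L = matrix(1, 1, 1), psi = 1, Psi = 1)
  x <- 0.3; ynot <- -0.2; yi <- 0.5
  d <- static_dataset(matrix(x, 1, 1), matrix(ynot, 1, 1), yi)
  # marginal covariance of (y_i, y_not): psi + a^2 Pi + (l + La)^2 etc.
  S <- matrix(c(1 + 1 + 4, 1 + 2, 1 + 2, 2), 2, 2)
  mu <- c(x + x * 1, x)
  r <- c(yi, ynot) - mu
  byhand <- -log(2 * pi) - 0.5 * log(det(S)) -
    0.5 * drop(r %*% solve(S) %*% r)
  expect_equal(marginal_loglik(p, d), byhand, tolerance = 1e-12)
})

test_that("identifiability transform preserves the marginal likelihood", {
  p <- rand_static(seed = 7)
  d <- generate_static(p, 200, seed = 8)
  ll0 <- marginal_loglik(p, d)
  expect_identical(apply_transform(p, rep(0, p$K))$a, p$a)
  set.seed(9)
  n_ok <- 0
  while (n_ok < 20) {
    delta <- rnorm(p$K, 0, 0.3)
    pt <- tryCatch(apply_transform(p, delta), error = function(e) NULL)
    if (is.null(pt)) next
    n_ok <- n_ok + 1
    expect_lt(abs(marginal_loglik(pt, d) - ll0), 1e-8 * abs(ll0))
    # non-target parameters untouched
    expect_identical(pt$B, p$B)
    expect_identical(pt$L, p$L)
  }
})

test_that("inadmissible transform directions are rejected with the admissible interval", {
  p <- rand_static(K = 1, seed = 11)
  iv <- admissible_interval(p)
  expect_error(apply_transform(p, iv[2] + 1), "admissible interval")
  # psi' is a downward parabola: apex between the roots, zero at the roots
  mid <- -(.5 * (iv[1] + iv[2]))
  psis <- sapply(seq(iv[1], iv[2], length.out = 11),
                 function(dl) apply_transform(p, dl)$psi)
  expect_lt(abs(psis[1]), 1e-10)
  expect_lt(abs(psis[11]), 1e-10)
  expect_true(which.max(psis) %in% 4:8)
})

test_that("transform_family spans the admissible interval with equal likelihood", {
  p <- rand_static(K = 1, seed = 12)
  d <- generate_static(p, 150, seed = 13)
  fam <- transform_family(p, 30)
  lls <- vapply(fam, marginal_loglik, 0, data = d)
  expect_lt(diff(range(lls)), 1e-8 * abs(lls[1]))
  expect_lt(fam[[1]]$psi, 1e-10)
  expect_lt(fam[[30]]$psi, 1e-10)
  ends <- transform_family(p, 2)
  expect_lt(ends[[1]]$psi, 1e-10)
  expect_lt(ends[[2]]$psi, 1e-10)
  expect_error(transform_family(rand_static(K = 2, seed = 14)), "K = 1")
  # apex of the psi parabola is generally off the interval midpoint
  dl <- attr(fam, "delta")
  psis <- vapply(fam, function(q) q$psi, 0)
  expect_gt(abs(dl[which.max(psis)] - mean(range(dl))), 1e-6)
})

test_that("sparsity-based identifiability test follows the rank dichotomy", {
  p <- rand_static(N = 6, M = 4, K = 1, seed = 15)
  # dense support: no rows in S, the whole K-space preserves the support
  dense <- check_identifiability(p, support_mask(rep(TRUE, 6), rep(TRUE, 4)))
  expect_false(dense$condition_holds)
  expect_identical(dense$rank_deficiency, 1L)
  # one zeroed coupling entry at K = 1: generic row is nonzero, S full rank
  sp <- support_mask(c(FALSE, rep(TRUE, 5)), rep(TRUE, 4))
  res <- check_identifiability(p, sp)
  expect_true(res$condition_holds)
  expect_identical(res$rank_deficiency, 0L)
})

test_that("support-preserving transform directions exist exactly when the test fails", {
  for (s in 1:10) {
    K <- sample(1:3, 1)
    p <- rand_static(N = 6, M = 5, K = K, seed = 200 + s)
    nzero <- sample(0:3, 1)
    p$a[seq_len(nzero)] <- 0          # model consistent with the support
    supp <- support_mask(c(rep(FALSE, nzero), rep(TRUE, 6 - nzero)),
                         rep(TRUE, 5))
    res <- check_identifiability(p, supp)
    expect_identical(res$rank_deficiency, max(0L, K - res$rank_S))
    if (res$condition_holds) {
      # null space is trivial
      expect_identical(ncol(res$nullspace), 0L)
    } else if (nzero > 0) {
      # a nonzero support-preserving delta exists and preserves the likelihood
      delta <- res$nullspace[, 1]
      delta <- delta * 0.1 / max(abs(delta))
      pt <- tryCatch(apply_transform(p, delta), error = function(e) NULL)
      if (!is.null(pt)) {
        expect_lt(max(abs(pt$a[!supp$coupling])), 1e-10)
        d <- generate_static(p, 50, seed = 300 + s)
        expect_lt(abs(marginal_loglik(pt, d) - marginal_loglik(p, d)),
                  1e-8 * abs(marginal_loglik(p, d)))
      }
    }
  }
})
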