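# random model builders shared across tests

rand_static <- function(N = 5, M = 4, K = 2, seed = NULL, a_sd = 0.3) {
  if (!is.null(seed)) set.seed(seed)
  static_params(a = rnorm(N, 0, a_sd), b = rnorm(M),
                B = matrix(rnorm(M * N), M, N),
                l = rnorm(K), L = matrix(rnorm(K * N, 0, 0.5), K, N),
                psi = runif(1, 0.5, 1.5), Psi = runif(N, 0.5, 1.5))
}

# sparse, identifiable K = 1 model with uniform noise correlations
rand_sparse_static <- function(N = 8, M = 6, rho = 0.10, mean_a = 0.5,
                               mean_b = 0.5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  a <- numeric(N); a[sample.int(N, N %/% 2)] <- rnorm(N %/% 2, mean_a, 0.1)
  b <- numeric(M); b[sample.int(M, M %/% 2)] <- rnorm(M %/% 2, mean_b, 0.1)
  uniform_correlation_params(a, b, matrix(rnorm(M * N, mean_b, 0.1), M, N),
                             rho = rho)
}

rand_dynamic <- function(N = 3, M = 2, K = 2, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  dynamic_params(A = matrix(rnorm(N * N, 0, 0.2), N),
                 B = matrix(rnorm(N * M), N, M),
                 L = matrix(rnorm(N * K), N, K),
                 Sigma = runif(N, 0.5, 1.5),
                 G = diag(runif(K, 0.2, 0.6), K),
                 H = 0.3)
}

# expected complete-data log-likelihood of the static model under a fixed
# posterior (independent implementation, used as the M-step gradient oracle)
q_static <- function(params, data, post) {
  D <- data$D
  r_i <- data$y - drop(data$X %*% params$b) - drop(data$Y %*% params$a)
  Enot <- data$Y - data$X %*% params$B
  quad_i <- sum((r_i - drop(post$mu %*% params$l))^2) +
    D * drop(crossprod(params$l, post$Sigma %*% params$l))
  Rn <- Enot - post$mu %*% params$L
  quad_not <- sum(sweep(Rn^2, 2, 1 / params$Psi, "*")) +
    D * sum(diag((params$L %*% .d(1 / params$Psi) %*% t(params$L)) %*% post$Sigma))
  -0.5 * (D * log(params$psi) + quad_i / params$psi +
            D * sum(log(params$Psi)) + quad_not)
}

.d <- function(v) diag(v, nrow = length(v))

# dense-matrix construction of the dynamic latent posterior (oracle for the
# Kalman/RTS E-step): builds Lambda^-1 explicitly and inverts it
dense_dyn_posterior <- function(params, data) {
  K <- params$K
  R <- residuals(structure(list(params = params), class = "cotula_dyn_fit"),
                 data)
  n <- nrow(R)
  DG <- diag(n * K)
  for (t in 2:n)
    DG[((t - 1) * K + 1):(t * K), ((t - 2) * K + 1):((t - 1) * K)] <- -params$G
  Lt <- kronecker(diag(n), params$L)
  Sti <- kronecker(diag(n), .d(1 / params$Sigma))
  Lam <- solve(t(Lt) %*% Sti %*% Lt + t(DG) %*% DG)
  mu <- matrix(Lam %*% t(Lt) %*% Sti %*% as.numeric(t(R)), n, K, byrow = TRUE)
  list(mu = mu, Lam = Lam, Lt = Lt, Sti = Sti, DG = DG, n = n, K = K, R = R)
}
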