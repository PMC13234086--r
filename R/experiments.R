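#' Counter-based child seeds
#'
#' Derives a reproducible stream of child seeds from a master seed so that
#' any unit of a larger experiment (one model, one dataset) can be re-run in
#' isolation.
#'
#' @param master master integer seed.
#' @param index non-negative counter.
#' @return An integer seed in `[0, 2^31)`.
#' @export
spawn_seed <- function(master, index) {
  as.integer((as.double(master) %% 2147483647 + 104729 * (index + 1)) %% 2147483647)
}

#' Configuration for the static parameter-recovery sweep
#'
#' Describes the grid experiment over the means of the coupling and tuning
#' parameter distributions. Per grid cell, `n_models` sparse ground-truth
#' models are drawn (nonzero coupling/tuning values normal around the cell
#' means with standard deviation `param_sd`, sparsity `k_C`/`k_T`, uniform
#' noise correlations `rho` via the `K = 1` equal-loading construction); per
#' model, `n_datasets` datasets of `D` trials are generated and fit on
#' `n_folds` disjoint folds under the requested model/selection regimes.
#'
#' @param coupling_means,tuning_means numeric grid values (defaults: 3 values
#'   spanning `[-1, 1]`).
#' @param n_models,n_datasets,n_folds,D replication counts and trials per
#'   dataset.
#' @param N,M population and stimulus sizes.
#' @param k_C,k_T coupling/tuning sparsity (fraction of exact zeros).
#' @param rho uniform noise-correlation target.
#' @param param_sd standard deviation of the nonzero parameter draws.
#' @param regimes character vector of `model_selection` regimes from
#'   `"cotu_none"`, `"cotu_oracle"`, `"cotu_inferred"`, `"cotula_none"`,
#'   `"cotula_oracle"`, `"cotula_inferred"`.
#' @param seed master seed.
#' @param positive_tuning truncate tuning draws at zero (used by the
#'   identifiability-family experiment designs)?
#' @return A list of class `"cotula_sweep_config"`.
#' @export
sweep_config <- function(coupling_means = c(-1, 0, 1),
                         tuning_means = c(-1, 0, 1),
                         n_models = 3L, n_datasets = 5L, n_folds = 3L,
                         D = 2000L, N = 8L, M = 6L,
                         k_C = 0.5, k_T = 0.5, rho = 0.10, param_sd = 0.1,
                         regimes = c("cotu_none", "cotu_oracle",
                                     "cotu_inferred", "cotula_none",
                                     "cotula_oracle", "cotula_inferred"),
                         seed = 1L, positive_tuning = FALSE) {
  stopifnot(n_models >= 1L, n_datasets >= 1L, n_folds >= 1L, D >= 1L,
            all(abs(coupling_means) <= 1), all(abs(tuning_means) <= 1))
  structure(list(coupling_means = coupling_means, tuning_means = tuning_means,
                 n_models = as.integer(n_models),
                 n_datasets = as.integer(n_datasets),
                 n_folds = as.integer(n_folds), D = as.integer(D),
                 N = as.integer(N), M = as.integer(M), k_C = k_C, k_T = k_T,
                 rho = rho, param_sd = param_sd, regimes = regimes,
                 seed = as.integer(seed), positive_tuning = positive_tuning),
            class = "cotula_sweep_config")
}

# Draw one sparse uniform-correlation ground-truth model for a sweep cell.
# The support is drawn so the sparsity-based identifiability condition holds
# (at K = 1 any zeroed coupling or tuning entry suffices generically).
.draw_sweep_model <- function(cmean, tmean, cfg, seed) {
  set.seed(seed)
  N <- cfg$N; M <- cfg$M
  nz_c <- max(1L, round(N * (1 - cfg$k_C)))
  nz_t <- max(1L, round(M * (1 - cfg$k_T)))
  if ((N - nz_c) + (M - nz_t) < 1L)
    stop("cell has no zero entries: identifiability construction infeasible")
  a <- numeric(N); b <- numeric(M)
  a[sample.int(N, nz_c)] <- stats::rnorm(nz_c, cmean, cfg$param_sd)
  tvals <- stats::rnorm(nz_t, tmean, cfg$param_sd)
  if (cfg$positive_tuning) tvals <- abs(tvals)
  b[sample.int(M, nz_t)] <- tvals
  B <- matrix(stats::rnorm(M * N, tmean, cfg$param_sd), M, N)
  uniform_correlation_params(a, b, B, rho = cfg$rho)
}

#' Run the static mean-sweep experiment
#'
#' For every (coupling mean, tuning mean) grid cell of `config`, draws sparse
#' identifiable ground-truth models, generates uniform-noise-correlation
#' datasets, fits the requested model/selection regimes per fold, and
#' aggregates the normalized errors of the target coupling and tuning
#' parameters with the scheme of [aggregate_errors()]. Fully deterministic
#' given the config's master seed.
#'
#' @param config a [sweep_config()].
#' @return A `"cotula_error_report"`: list with `summary` (one row per cell,
#'   regime and parameter class, with the aggregated normalized error),
#'   `raw` (one row per model/dataset/fold/parameter), and `config`.
#' @export
run_static_sweep <- function(config) {
  stopifnot(inherits(config, "cotula_sweep_config"))
  cfg <- config
  raw <- list(); ri <- 0L
  ctr <- 0L
  grid <- expand.grid(cmean = cfg$coupling_means, tmean = cfg$tuning_means,
                      KEEP.OUT.ATTRS = FALSE)
  for (gi in seq_len(nrow(grid))) {
    cmean <- grid$cmean[gi]; tmean <- grid$tmean[gi]
    for (mi in seq_len(cfg$n_models)) {
      ctr <- ctr + 1L
      truth <- .draw_sweep_model(cmean, tmean, cfg, spawn_seed(cfg$seed, ctr))
      osupp <- oracle_support(truth)
      for (di in seq_len(cfg$n_datasets)) {
        ctr <- ctr + 1L
        dat <- generate_static(truth, cfg$D, seed = spawn_seed(cfg$seed, ctr))
        ctr <- ctr + 1L
        set.seed(spawn_seed(cfg$seed, ctr))
        folds <- split(sample.int(cfg$D), rep(seq_len(cfg$n_folds),
                                              length.out = cfg$D))
        for (fi in seq_along(folds)) {
          fd <- static_dataset(dat$X[folds[[fi]], , drop = FALSE],
                               dat$Y[folds[[fi]], , drop = FALSE],
                               dat$y[folds[[fi]]])
          for (rg in cfg$regimes) {
            parts <- strsplit(rg, "_", fixed = TRUE)[[1]]
            ctr <- ctr + 1L
            fit <- cotula_static(
              fd, model = parts[1], selection = parts[2], K = 1L,
              support = osupp,
              selection_control = list(seed = spawn_seed(cfg$seed, ctr)))
            err <- normalized_error(fit, truth)
            for (ptype in c("coupling", "tuning")) {
              e <- err[[ptype]]
              ri <- ri + 1L
              raw[[ri]] <- data.frame(
                cmean = cmean, tmean = tmean, model = mi, dataset = di,
                fold = fi, regime = rg, param = ptype,
                index = as.integer(names(e)), error = as.numeric(e),
                raw_error = as.numeric(err$raw[[ptype]]))
            }
          }
        }
      }
    }
  }
  raw <- do.call(rbind, raw)
  summary <- .aggregate_sweep(raw)
  structure(list(summary = summary, raw = raw, config = cfg),
            class = "cotula_error_report")
}

# sweep aggregation: mean over dataset x fold, median over models (per
# parameter position), median over parameters -- per cell/regime/param class
.aggregate_sweep <- function(raw) {
  key <- interaction(raw$cmean, raw$tmean, raw$regime, raw$param, drop = TRUE)
  parts <- split(raw, key)
  out <- lapply(parts, function(df) {
    per_model <- split(df, df$model)
    errs <- lapply(per_model, function(dm) {
      reps <- split(dm, interaction(dm$dataset, dm$fold, drop = TRUE))
      lapply(reps, function(r) r$error[order(r$index)])
    })
    data.frame(cmean = df$cmean[1], tmean = df$tmean[1], regime = df$regime[1],
               param = df$param[1], error = aggregate_errors(errs))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' @export
print.cotula_error_report <- function(x, ...) {
  cat("Parameter-recovery error report\n")
  print(utils::head(x$summary, 12))
  if (nrow(x$summary) > 12) cat("  ...", nrow(x$summary), "summary rows\n")
  invisible(x)
}

#' Identifiability-family clustering experiment
#'
#' Probes how structural non-identifiability shapes EM estimates: builds
#' `n_inits` equally spaced parameter configurations spanning the `K = 1`
#' identifiability family of `base_params`, generates one dataset from
#' `base_params`, and runs no-selection EM from every family member for a
#' fixed iteration budget (the family is likelihood-flat, so a
#' likelihood-change stopping rule cannot trace EM's drift along it).
#' Reports where along the family the fits land.
#'
#' @param base_params a `"cotula_params"` with `K = 1`.
#' @param n_inits number of family-spanning initializations.
#' @param D trials in the generated dataset.
#' @param n_iter fixed EM iteration budget per initialization.
#' @param seed master seed.
#' @return A list of class `"cotula_ident_experiment"`: `fits`, `estimates`
#'   (matrix of fitted `(a, b, l, psi)` per init), `init_matrix` (same for
#'   the initializations), `pca` (2-component scores of the estimates),
#'   `psi_fitted`, `psi_family_max` (the family's apex private variance),
#'   `init_spread` and `fit_spread` (per-parameter standard deviations of the
#'   coupling entries across inits/fits).
#' @export
run_identifiability_experiment <- function(base_params, n_inits = 30L,
                                           D = 2000L, n_iter = 300L,
                                           seed = 1L) {
  stopifnot(inherits(base_params, "cotula_params"))
  if (base_params$K != 1L) stop("experiment requires K = 1")
  dat <- generate_static(base_params, D, seed = spawn_seed(seed, 0L))
  fam <- transform_family(base_params, n_inits)
  trm <- .transform_mats(base_params)
  apex <- apply_transform(base_params, -trm$lproj / drop(trm$W))
  pack <- function(p) c(p$a, p$b, p$l, p$psi)
  fits <- vector("list", n_inits)
  for (i in seq_len(n_inits)) {
    fits[[i]] <- fit_cotula_em(dat, K = 1L, init = fam[[i]],
                               max_iter = n_iter, tol = 0)
  }
  est <- t(vapply(fits, function(f) pack(f$params), pack(base_params)))
  ini <- t(vapply(fam, pack, pack(base_params)))
  colnames(est) <- colnames(ini) <-
    c(paste0("a", seq_len(base_params$N)), paste0("b", seq_len(base_params$M)),
      "l", "psi")
  pca <- stats::prcomp(est, center = TRUE, scale. = FALSE)
  N <- base_params$N
  structure(list(
    fits = fits, estimates = est, init_matrix = ini,
    pca = pca$x[, seq_len(min(2L, ncol(pca$x))), drop = FALSE],
    psi_fitted = est[, "psi"], psi_family_max = apex$psi,
    init_spread = apply(ini[, seq_len(N), drop = FALSE], 2L, stats::sd),
    fit_spread = apply(est[, seq_len(N), drop = FALSE], 2L, stats::sd),
    truth = base_params, data = dat),
    class = "cotula_ident_experiment")
}

#' @export
print.cotula_ident_experiment <- function(x, ...) {
  cat(sprintf("Identifiability-family experiment: %d inits\n", nrow(x$estimates)))
  cat(sprintf("  coupling spread: inits %.4f, fits %.4f (mean per-entry SD)\n",
              mean(x$init_spread), mean(x$fit_spread)))
  cat(sprintf("  fitted psi: median %.4f (family max %.4f)\n",
              stats::median(x$psi_fitted), x$psi_family_max))
  invisible(x)
}

#' Configuration for the dynamic four-condition experiment
#'
#' The 2 x 2 conditions cross temporal correlation in the stimulus (`h`) and
#' in the latent noise (`g`): "on" means AR coefficient `ar_on`, "off" means
#' 0. Per condition, `n_real` ground-truth models are drawn (sparse coupling
#' and tuning, unit latent loadings) and one series of length `T` generated
#' from each.
#'
#' @param N,M,K,T model sizes and series length.
#' @param n_real realizations per condition.
#' @param ar_on AR coefficient used when a correlation is "on".
#' @param a_diag,a_off mean diagonal / off-diagonal coupling values.
#' @param offdiag_frac fraction of off-diagonal coupling entries that are
#'   nonzero.
#' @param b_mean mean of nonzero tuning values; `k_T` tuning sparsity.
#' @param ell latent loading value (all units).
#' @param sigma2 private noise variance.
#' @param regimes `model_selection` regimes (as in [sweep_config()]).
#' @param seed master seed.
#' @return A list of class `"cotula_dyncond_config"`.
#' @export
dynamic_conditions_config <- function(N = 4L, M = 2L, K = 1L, T = 5000L,
                                      n_real = 50L, ar_on = 0.6,
                                      a_diag = 0.4, a_off = 0.2,
                                      offdiag_frac = 0.25, b_mean = 1,
                                      k_T = 0.5, ell = 1, sigma2 = 1,
                                      regimes = c("cotu_none", "cotula_oracle"),
                                      seed = 1L) {
  stopifnot(n_real >= 1L, T >= 10L)
  structure(list(N = as.integer(N), M = as.integer(M), K = as.integer(K),
                 T = as.integer(T), n_real = as.integer(n_real),
                 ar_on = ar_on, a_diag = a_diag, a_off = a_off,
                 offdiag_frac = offdiag_frac, b_mean = b_mean, k_T = k_T,
                 ell = ell, sigma2 = sigma2, regimes = regimes,
                 seed = as.integer(seed)),
            class = "cotula_dyncond_config")
}

# draw one dynamic ground-truth model for a condition
.draw_dynamic_model <- function(cfg, h, g, seed) {
  set.seed(seed)
  N <- cfg$N; M <- cfg$M; K <- cfg$K
  A <- diag(stats::rnorm(N, cfg$a_diag, 0.05), N)
  off <- which(row(A) != col(A))
  n_off <- round(cfg$offdiag_frac * length(off))
  if (n_off > 0L)
    A[sample(off, n_off)] <- stats::rnorm(n_off, cfg$a_off, 0.05)
  A <- .clip_spectral(A, 0.85)
  B <- matrix(0, N, M)
  nz <- max(1L, round((1 - cfg$k_T) * M))
  for (j in seq_len(N)) B[j, sample.int(M, nz)] <- stats::rnorm(nz, cfg$b_mean, 0.1)
  dynamic_params(A = A, B = B, L = matrix(cfg$ell, N, K),
                 Sigma = rep(cfg$sigma2, N), G = diag(g, K), H = h)
}

#' Run the dynamic four-condition error experiment
#'
#' For each of the four temporal-correlation conditions, repeatedly draws a
#' ground-truth dynamic CoTuLa model, simulates a series, fits the requested
#' model/selection regimes, and collects the normalized errors of the nonzero
#' coupling and tuning entries. Deterministic given the config seed.
#'
#' @param config a [dynamic_conditions_config()].
#' @param em_control list of extra arguments for [fit_dynamic_cotula_em()]
#'   (e.g. `max_iter`, `tol`).
#' @return A `"cotula_error_report"` whose `summary` holds the median and
#'   quartiles of the normalized errors per condition, regime and parameter
#'   class, and whose `raw` holds every per-entry error.
#' @export
run_dynamic_conditions <- function(config, em_control = list()) {
  stopifnot(inherits(config, "cotula_dyncond_config"))
  cfg <- config
  conds <- expand.grid(h = c(0, cfg$ar_on), g = c(0, cfg$ar_on),
                       KEEP.OUT.ATTRS = FALSE)
  raw <- list(); ri <- 0L; ctr <- 0L
  for (ci in seq_len(nrow(conds))) {
    h <- conds$h[ci]; g <- conds$g[ci]
    cond <- sprintf("h=%g,g=%g", h, g)
    for (r in seq_len(cfg$n_real)) {
      ctr <- ctr + 1L
      truth <- .draw_dynamic_model(cfg, h, g, spawn_seed(cfg$seed, ctr))
      ctr <- ctr + 1L
      dat <- generate_dynamic(truth, cfg$T, seed = spawn_seed(cfg$seed, ctr))
      osupp <- oracle_support(truth)
      for (rg in cfg$regimes) {
        parts <- strsplit(rg, "_", fixed = TRUE)[[1]]
        fit <- if (parts[1] == "cotu") {
          cotula_dynamic(dat, model = "cotu", selection = parts[2],
                         support = osupp)
        } else {
          do.call(cotula_dynamic,
                  c(list(data = dat, model = "cotula", selection = parts[2],
                         K = cfg$K, support = osupp), em_control))
        }
        err <- normalized_error(fit, truth)
        for (ptype in c("coupling", "tuning")) {
          e <- err[[ptype]]
          ri <- ri + 1L
          raw[[ri]] <- data.frame(condition = cond, h = h, g = g,
                                  realization = r, regime = rg, param = ptype,
                                  index = as.integer(names(e)),
                                  error = as.numeric(e),
                                  raw_error = as.numeric(err$raw[[ptype]]))
        }
      }
    }
  }
  raw <- do.call(rbind, raw)
  key <- interaction(raw$condition, raw$regime, raw$param, drop = TRUE)
  summary <- do.call(rbind, lapply(split(raw, key), function(df) {
    q <- stats::quantile(df$error, c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(condition = df$condition[1], h = df$h[1], g = df$g[1],
               regime = df$regime[1], param = df$param[1],
               q25 = q[1], median = q[2], q75 = q[3])
  }))
  rownames(summary) <- NULL
  structure(list(summary = summary, raw = raw, config = cfg),
            class = "cotula_error_report")
}

#' Variance fractions of the model terms
#'
#' Fraction of the target unit's variance contributed by each model term:
#' coupling (`Var(a' y_noti)`), tuning (`Var(b' x)`), latent (`Var(l' z-hat)`
#' with `z-hat` the posterior latent mean), and private (`psi / Var(y_i)`).
#' The terms are not orthogonal, so the fractions need not sum to 1. For
#' dynamic fits the per-unit fractions are averaged across units (coupling
#' term `A y_{t-1}`, tuning `B x_t`, latent `L z-hat_t`).
#'
#' @param params fitted `"cotula_params"` or `"cotula_dyn_params"` (or a fit
#'   object).
#' @param data the dataset the parameters were fit to.
#' @return Named numeric vector `c(coupling, tuning, latent, private)`.
#' @export
variance_fractions <- function(params, data) {
  if (inherits(params, "cotula_fit") || inherits(params, "cotula_dyn_fit"))
    params <- params$params
  if (inherits(params, "cotula_dyn_params")) {
    stopifnot(inherits(data, "cotula_dyn_data"))
    T_ <- data$T
    vy <- apply(data$Y[-1L, , drop = FALSE], 2L, stats::var)
    if (any(vy == 0)) stop("zero target variance")
    co <- data$Y[-T_, , drop = FALSE] %*% t(params$A)
    tu <- data$X[-1L, , drop = FALSE] %*% t(params$B)
    la <- if (params$K >= 1L)
      dynamic_e_step(params, data)$mu %*% t(params$L)
      else matrix(0, T_ - 1L, params$N)
    c(coupling = mean(apply(co, 2L, stats::var) / vy),
      tuning = mean(apply(tu, 2L, stats::var) / vy),
      latent = mean(apply(la, 2L, stats::var) / vy),
      private = mean(params$Sigma / vy))
  } else {
    stopifnot(inherits(data, "cotula_data"))
    vy <- stats::var(data$y)
    if (vy == 0) stop("zero target variance")
    zhat <- if (params$K >= 1L) em_e_step(params, data)$mu
            else matrix(0, data$D, 0)
    lat <- if (params$K >= 1L) drop(zhat %*% params$l) else numeric(data$D)
    c(coupling = stats::var(drop(data$Y %*% params$a)) / vy,
      tuning = stats::var(drop(data$X %*% params$b)) / vy,
      latent = stats::var(lat) / vy,
      private = params$psi / vy)
  }
}

#' Tuning-curve modulation depth
#'
#' Minimum-to-maximum distance of a tuning curve across stimulus levels;
#' invariant to additive offsets.
#'
#' @param tuning_curve numeric vector of predicted tuning contributions, one
#'   per stimulus level (at least 2).
#' @return Scalar `max - min`.
#' @export
tuning_modulation <- function(tuning_curve) {
  if (length(tuning_curve) < 2L) stop("need at least 2 stimulus levels")
  max(tuning_curve) - min(tuning_curve)
}

#' Tuning-to-coupling variance ratio
#'
#' Ratio of the tuning to the coupling variance fraction; reported as `NA`
#' (missing denominator) when the coupling fraction is not positive.
#'
#' @param fractions a named vector from [variance_fractions()].
#' @return Scalar ratio or `NA_real_`.
#' @export
tuning_coupling_ratio <- function(fractions) {
  if (!all(c("coupling", "tuning") %in% names(fractions)))
    stop("fractions must contain 'coupling' and 'tuning'")
  if (fractions[["coupling"]] <= 0) return(NA_real_)
  fractions[["tuning"]] / fractions[["coupling"]]
}
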