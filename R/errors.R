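#' Normalized estimation errors against ground truth
#'
#' Per-parameter normalized error `(estimate - truth) / truth`, computed on
#' the truly nonzero coupling and tuning entries of the target equation (zero
#' true values are excluded and counted). Works for static parameter pairs
#' (`a`, `b` vectors) and dynamic pairs (`A`, `B` matrices).
#'
#' @param estimate,truth parameter objects of the same class
#'   (`"cotula_params"` or `"cotula_dyn_params"`), or `"cotula_fit"`s.
#' @return A list of class `"cotula_errors"`: `coupling` and `tuning`
#'   normalized error vectors (named by flat index), matching `raw` (un-normalized)
#'   errors, and `n_excluded` zero-truth entries.
#' @seealso [aggregate_errors()] for the sweep aggregation scheme.
#' @export
normalized_error <- function(estimate, truth) {
  if (inherits(estimate, "cotula_fit") || inherits(estimate, "cotula_dyn_fit"))
    estimate <- estimate$params
  if (inherits(truth, "cotula_fit") || inherits(truth, "cotula_dyn_fit"))
    truth <- truth$params
  dyn <- inherits(truth, "cotula_dyn_params")
  ce <- if (dyn) as.numeric(estimate$A) else estimate$a
  ct <- if (dyn) as.numeric(truth$A) else truth$a
  te <- if (dyn) as.numeric(estimate$B) else estimate$b
  tt <- if (dyn) as.numeric(truth$B) else truth$b
  kc <- which(ct != 0); kt <- which(tt != 0)
  structure(list(
    coupling = stats::setNames((ce[kc] - ct[kc]) / ct[kc], kc),
    tuning = stats::setNames((te[kt] - tt[kt]) / tt[kt], kt),
    raw = list(coupling = stats::setNames(ce[kc] - ct[kc], kc),
               tuning = stats::setNames(te[kt] - tt[kt], kt)),
    n_excluded = (length(ct) - length(kc)) + (length(tt) - length(kt))),
    class = "cotula_errors")
}

#' @export
print.cotula_errors <- function(x, ...) {
  cat(sprintf("Normalized errors on true support: coupling median %.4f, tuning median %.4f (%d zero-truth entries excluded)\n",
              stats::median(x$coupling), stats::median(x$tuning), x$n_excluded))
  invisible(x)
}

#' Aggregate normalized errors across datasets, folds, models
#'
#' Implements the sweep aggregation scheme: for each model and parameter,
#' average the normalized error across datasets and folds; then take the
#' median across models (per parameter position); then the median across
#' parameters. `errors` is a list (over models) of lists (over dataset/fold
#' replicates) of numeric vectors of per-parameter normalized errors; every
#' replicate of a model must evaluate the same parameter positions.
#'
#' @param errors nested list as described above.
#' @return Scalar aggregated error.
#' @export
aggregate_errors <- function(errors) {
  per_model <- lapply(errors, function(reps) {
    mat <- do.call(rbind, lapply(reps, as.numeric))
    colMeans(mat)                                   # mean over datasets/folds
  })
  len <- max(vapply(per_model, length, 1L))
  padded <- vapply(per_model, function(v) c(v, rep(NA_real_, len - length(v))),
                   numeric(len))
  per_param <- apply(matrix(padded, nrow = len), 1L, stats::median, na.rm = TRUE)
  stats::median(per_param, na.rm = TRUE)            # median across parameters
}
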