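# full-precision CSV helpers: numbers written with 17 significant digits so
# that read-back reproduces the doubles exactly
.write_csv_precise <- function(df, path) {
  out <- df
  for (j in seq_along(out))
    if (is.double(out[[j]])) out[[j]] <- sprintf("%.17g", out[[j]])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
}

.read_matrix_csv <- function(path) {
  if (!file.exists(path)) stop("missing file: ", path)
  as.matrix(utils::read.csv(path, check.names = FALSE))
}

#' Write / read a dataset directory
#'
#' Serializes a static or dynamic dataset as delimited text: `X.csv` for the
#' stimulus, `Y.csv` for the activity (for static datasets the target unit is
#' column 1, followed by the non-target units), optional `Z.csv` for
#' generator latents, and a JSON sidecar `meta.json` with the dimensions,
#' kind and any extra metadata.
#'
#' @param data a [static_dataset()] or [dynamic_dataset()].
#' @param dir directory to create/write into.
#' @param meta optional named list merged into the sidecar.
#' @return `dir`, invisibly (`write_dataset`); the reconstructed dataset
#'   object (`read_dataset`).
#' @export
write_dataset <- function(data, dir, meta = list()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  static <- inherits(data, "cotula_data")
  Y <- if (static) cbind(target = data$y, data$Y) else data$Y
  .write_csv_precise(as.data.frame(data$X), file.path(dir, "X.csv"))
  .write_csv_precise(as.data.frame(Y), file.path(dir, "Y.csv"))
  if (!is.null(data$Z))
    .write_csv_precise(as.data.frame(data$Z), file.path(dir, "Z.csv"))
  side <- c(list(kind = if (static) "static" else "dynamic",
                 N = data$N, M = data$M,
                 K = if (is.null(data$Z)) NA else ncol(data$Z),
                 rows = if (static) data$D else data$T),
            meta)
  jsonlite::write_json(side, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = I(17), null = "null")
  invisible(dir)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(dir) {
  meta_path <- file.path(dir, "meta.json")
  if (!file.exists(meta_path)) stop("missing file: ", meta_path)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  X <- .read_matrix_csv(file.path(dir, "X.csv"))
  Y <- .read_matrix_csv(file.path(dir, "Y.csv"))
  zp <- file.path(dir, "Z.csv")
  Z <- if (file.exists(zp)) .read_matrix_csv(zp)
  if (identical(meta$kind, "static"))
    static_dataset(X, Y[, -1L, drop = FALSE], Y[, 1L], Z)
  else
    dynamic_dataset(X, Y, Z)
}

#' Serialize model parameters to JSON
#'
#' Writes a static or dynamic parameter set as a single JSON document with
#' named arrays (matrices stored with a `dim` field), and reads it back.
#'
#' @param params a `"cotula_params"` or `"cotula_dyn_params"`.
#' @param path JSON file path.
#' @return `path` invisibly (`write_params`); the parameter object
#'   (`read_params`).
#' @export
write_params <- function(params, path) {
  kind <- if (inherits(params, "cotula_dyn_params")) "dynamic" else "static"
  enc <- function(x) if (is.matrix(x)) list(data = as.numeric(x), dim = dim(x))
                     else as.numeric(x)
  fields <- setdiff(names(params), c("N", "M", "K"))
  doc <- c(list(kind = kind),
           lapply(stats::setNames(fields, fields), function(f)
             if (is.null(params[[f]])) NULL else enc(params[[f]])))
  jsonlite::write_json(doc, path, auto_unbox = FALSE, digits = I(17),
                       null = "null")
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  if (!file.exists(path)) stop("missing file: ", path)
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  dec <- function(x) {
    if (is.list(x) && !is.null(x$dim)) matrix(x$data, x$dim[1], x$dim[2])
    else if (is.null(x) || length(x) == 0) NULL
    else as.numeric(x)
  }
  if (identical(unlist(doc$kind), "static"))
    static_params(a = dec(doc$a), b = dec(doc$b), B = dec(doc$B),
                  l = dec(doc$l), L = dec(doc$L),
                  psi = dec(doc$psi), Psi = dec(doc$Psi),
                  b0 = dec(doc$b0), B0 = dec(doc$B0))
  else
    dynamic_params(A = dec(doc$A), B = dec(doc$B), L = dec(doc$L),
                   Sigma = dec(doc$Sigma), G = dec(doc$G), H = dec(doc$H),
                   sigma_x = dec(doc$sigma_x))
}

# per-kind configuration defaults; names double as the set of allowed keys
.config_defaults <- function(kind) {
  switch(kind,
    "static-sweep" = unclass(sweep_config()),
    "identifiability" = list(n_inits = 30L, D = 2000L, n_iter = 300L,
                             seed = 1L),
    "dynamic-conditions" = unclass(dynamic_conditions_config()),
    "single-fit" = list(data_dir = NA_character_, model = "cotula",
                        selection = "none", K = 1L, seed = 1L),
    stop("unknown experiment kind: ", kind))
}

#' Load and validate an experiment configuration
#'
#' Reads a YAML (or JSON) experiment configuration with a mandatory `kind`
#' field (`"static-sweep"`, `"identifiability"`, `"dynamic-conditions"` or
#' `"single-fit"`), fills defaults for omitted settings, and rejects unknown
#' keys, type mismatches and constraint violations with the offending key
#' named. The validated configuration round-trips losslessly through
#' [save_config()].
#'
#' @param path configuration file (`.yaml`/`.yml` or `.json`).
#' @return A list of class `"cotula_config"` with attributes `kind`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("missing file: ", path)
  raw <- if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
         else yaml::read_yaml(path)
  if (is.null(raw$kind)) stop("config must declare `kind`")
  kind <- raw$kind
  defaults <- .config_defaults(kind)
  extra <- setdiff(names(raw), c("kind", names(defaults)))
  if (length(extra)) stop("unknown config key(s): ", paste(extra, collapse = ", "))
  cfg <- defaults
  for (k in setdiff(names(raw), "kind")) {
    v <- raw[[k]]
    tmpl <- defaults[[k]]
    if (is.numeric(tmpl) && !is.numeric(v))
      stop("config key `", k, "` must be numeric")
    if (is.character(tmpl) && !is.character(v))
      stop("config key `", k, "` must be character")
    cfg[[k]] <- if (is.integer(tmpl) && is.numeric(v)) as.integer(v) else v
  }
  for (k in intersect(names(cfg), c("D", "T", "n_models", "n_datasets",
                                    "n_folds", "n_real", "n_inits", "N", "M",
                                    "K", "n_iter")))
    if (cfg[[k]] < 1) stop("config key `", k, "` must be >= 1")
  structure(cfg, kind = kind, class = "cotula_config")
}

#' @rdname load_config
#' @param config a `"cotula_config"` (or plain list plus `kind`).
#' @param kind experiment kind (taken from the config attribute if absent).
#' @export
save_config <- function(config, path, kind = attr(config, "kind")) {
  if (is.null(kind)) stop("config kind unknown")
  doc <- c(list(kind = kind), unclass(config))
  attributes(doc) <- list(names = names(doc))
  if (grepl("\\.json$", path))
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17))
  else yaml::write_yaml(doc, path)
  invisible(path)
}

#' Save / load an experiment error report
#'
#' Persists a `"cotula_error_report"` as plain text: `summary.csv`,
#' `raw_errors.csv` (full precision) and `config.json` (an echo of the
#' generating configuration, including its master seed). `load_results`
#' reconstructs the in-memory report exactly.
#'
#' @param report a `"cotula_error_report"` from [run_static_sweep()] or
#'   [run_dynamic_conditions()].
#' @param dir output directory.
#' @return `dir` invisibly (`save_results`); the report (`load_results`).
#' @export
save_results <- function(report, dir) {
  stopifnot(inherits(report, "cotula_error_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  .write_csv_precise(report$summary, file.path(dir, "summary.csv"))
  .write_csv_precise(report$raw, file.path(dir, "raw_errors.csv"))
  cfg <- unclass(report$config)
  jsonlite::write_json(c(list(class = class(report$config)), cfg),
                       file.path(dir, "config.json"), auto_unbox = TRUE,
                       digits = I(17))
  invisible(dir)
}

#' @rdname save_results
#' @export
load_results <- function(dir) {
  for (f in c("summary.csv", "raw_errors.csv", "config.json"))
    if (!file.exists(file.path(dir, f)))
      stop("missing file: ", file.path(dir, f))
  cfgdoc <- jsonlite::read_json(file.path(dir, "config.json"),
                                simplifyVector = TRUE)
  cls <- cfgdoc$class
  cfg <- cfgdoc[setdiff(names(cfgdoc), "class")]
  for (k in c("n_models", "n_datasets", "n_folds", "D", "N", "M", "K", "T",
              "n_real", "seed"))
    if (!is.null(cfg[[k]])) cfg[[k]] <- as.integer(cfg[[k]])
  class(cfg) <- cls
  structure(list(summary = utils::read.csv(file.path(dir, "summary.csv")),
                 raw = utils::read.csv(file.path(dir, "raw_errors.csv")),
                 config = cfg),
            class = "cotula_error_report")
}
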