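#' Read a kinetic matrix with its sidecar metadata
#'
#' Dense matrices are delimited text (CSV/TSV, optional header); sparse
#' matrices are Matrix Market (`.mtx`). A JSON sidecar (`<file>.json`, or an
#' explicit `metadata` path) records the chain `kind` (`rate`/`markov`), the
#' `lag_tau` and the stochastic `orientation` (`"column"` as stored by this
#' package, or `"row"` for matrices that need transposing at load time).
#' Missing metadata falls back to the function arguments.
#'
#' @param path matrix file.
#' @param kind,lag_tau,orientation fallbacks when no sidecar exists.
#' @param metadata explicit sidecar path.
#' @param validate return a validated `kinetic_chain` (default) or the raw
#'   matrix.
#' @return a `kinetic_chain` (or matrix when `validate = FALSE`).
#' @export
read_kinetic_matrix <- function(path, kind = "rate", lag_tau = 1,
                                orientation = "column", metadata = NULL,
                                validate = TRUE) {
  meta_path <- metadata %||% paste0(path, ".json")
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path)
    kind <- meta$kind %||% kind
    lag_tau <- meta$lag_tau %||% lag_tau
    orientation <- meta$orientation %||% orientation
  }
  m <- if (grepl("\\.mtx$", path, ignore.case = TRUE)) {
    as.matrix(Matrix::readMM(path))
  } else {
    first <- readLines(path, n = 1L)
    sep <- if (grepl("\t", first)) "\t" else ","
    has_header <- !grepl("^[-+0-9eE.,\t ]+$", first)
    as.matrix(utils::read.table(path, sep = sep, header = has_header))
  }
  dimnames(m) <- NULL
  if (identical(orientation, "row")) m <- t(m)
  if (!validate) return(m)
  validate_chain(m, kind, lag_tau = lag_tau)
}

#' Write a kinetic matrix with its sidecar metadata
#'
#' @param chain a `kinetic_chain` (or a bare matrix plus `kind`).
#' @param path output file; `.mtx` selects Matrix Market, anything else dense
#'   CSV (no header).
#' @param kind chain kind when `chain` is a bare matrix.
#' @param lag_tau lag time recorded in the sidecar.
#' @return `path`, invisibly.
#' @export
write_kinetic_matrix <- function(chain, path, kind = NULL, lag_tau = NULL) {
  if (inherits(chain, "kinetic_chain")) {
    m <- chain_matrix(chain)
    kind <- chain$kind
    lag_tau <- if (chain$kind == "markov") chain$lag_tau else lag_tau
  } else m <- as.matrix(chain)
  if (grepl("\\.mtx$", path, ignore.case = TRUE)) {
    Matrix::writeMM(Matrix::Matrix(m, sparse = TRUE), path)
  } else {
    utils::write.table(m, path, sep = ",", row.names = FALSE, col.names = FALSE)
  }
  jsonlite::write_json(list(kind = kind, lag_tau = lag_tau,
                            orientation = "column", n_states = nrow(m)),
                       paste0(path, ".json"), auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' Read / write cluster labels (one 0-based integer per line)
#'
#' @param path label file.
#' @return integer vector of 0-based labels.
#' @export
read_labels <- function(path) {
  as.integer(utils::read.table(path, header = FALSE)[[1L]])
}

#' @rdname read_labels
#' @param labels integer labels (0- or 1-based; written as 0-based).
#' @export
write_labels <- function(labels, path) {
  labels <- as.integer(labels)
  if (length(labels) && min(labels) >= 1L &&
      !any(labels == 0L)) labels <- labels - 1L
  utils::write.table(labels, path, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Serialize a population result to disk
#'
#' Writes per-run records as JSON lines, the best crisp labels as a
#' single-column CSV and a population summary JSON.
#'
#' @param result a `population_result`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_population_result <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rec_lines <- vapply(result$records, function(r)
    jsonlite::toJSON(list(model_seed = r$model_seed, final_loss = r$final_loss,
                          final_delta_k = r$final_delta_k,
                          steps_completed = r$steps_completed,
                          culled = isTRUE(r$culled),
                          crisp_labels = r$crisp_labels),
                     auto_unbox = TRUE, digits = NA, na = "null"), "")
  writeLines(rec_lines, file.path(dir, "runs.jsonl"))
  if (!is.null(result$best_record))
    write_labels(result$best_record$crisp_labels, file.path(dir, "best_labels.csv"))
  dks <- vapply(result$records, function(r)
    if (isTRUE(r$culled)) NA_real_ else r$final_delta_k, 1.0)
  jsonlite::write_json(
    list(n_models = length(result$records),
         n_culled = sum(vapply(result$records, function(r) isTRUE(r$culled), TRUE)),
         best_delta_k = if (is.null(result$best_record)) NULL
                        else result$best_record$final_delta_k,
         mean_delta_k = mean(dks[is.finite(dks)]),
         n_clusters = result$config$n_clusters,
         encoder = result$config$encoder, decoder = result$config$decoder),
    file.path(dir, "summary.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Model parameter archive
#'
#' Saves a parameter set as a JSON manifest (configuration echo plus array
#' shapes) and one delimited text file per named array, all inside `dir`.
#'
#' @param params a `model_params` list.
#' @param config the [model_config()] the parameters belong to.
#' @param dir archive directory.
#' @return `dir` (write) / a `model_params` list (read).
#' @export
write_model_params <- function(params, config, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  shapes <- lapply(params, dim)
  jsonlite::write_json(list(config = unclass(config), shapes = shapes),
                       file.path(dir, "manifest.json"), auto_unbox = TRUE)
  for (nm in names(params))
    utils::write.table(params[[nm]], file.path(dir, paste0(nm, ".csv")),
                       sep = ",", row.names = FALSE, col.names = FALSE)
  invisible(dir)
}

#' @rdname write_model_params
#' @export
read_model_params <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  params <- lapply(names(manifest$shapes), function(nm)
    as.matrix(utils::read.table(file.path(dir, paste0(nm, ".csv")), sep = ",")))
  names(params) <- names(manifest$shapes)
  params <- lapply(params, function(m) { dimnames(m) <- NULL; m })
  class(params) <- "model_params"
  params
}

#' Read a run configuration file
#'
#' YAML configuration mirroring the [model_config()], [train_config()],
#' [feature_spec()] and [penalty_params()] fields under the keys `model`,
#' `train`, `features` and `penalty` (all optional; defaults fill the gaps).
#'
#' @param path YAML file.
#' @return list with `model`, `train`, `features`, `penalty`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path) %||% list()
  list(model = do.call(model_config, y$model %||% list()),
       train = do.call(train_config, y$train %||% list()),
       features = do.call(feature_spec, y$features %||% list()),
       penalty = do.call(penalty_params, y$penalty %||% list()))
}
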