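# Serialization and reproducible experiment orchestration.
#
# Networks travel as weighted edge lists (TSV, 0-based indices, columns
# source / target / weight) or MatrixMarket coordinate files, with a JSON
# metadata sidecar (<path>.json) recording size, ensemble family and seed.
# Edge orientation on disk follows the in-memory convention: an edge
# (source j, target i) is entry W[i, j].

#' Write / read a threshold network
#'
#' Lossless round-trip of the weight matrix. `"edge_tsv"` writes
#' `source<TAB>target<TAB>weight` with 0-based node indices; `"mtx"` writes
#' MatrixMarket coordinate format (1-based on disk, converted on read). A
#' JSON sidecar `<path>.json` stores `n`, the ensemble family and any
#' metadata passed in `meta`.
#'
#' @param net A `threshold_net`.
#' @param path Output file path.
#' @param format `"edge_tsv"` or `"mtx"` (default: from file extension,
#'   `.mtx` vs anything else).
#' @param meta Named list merged into the JSON sidecar.
#' @return `write_network()`: `path`, invisibly. `read_network()`: a
#'   `threshold_net`.
#' @export
write_network <- function(net, path, format = NULL, meta = list()) {
  stopifnot(inherits(net, "threshold_net"))
  format <- resolve_format(path, format)
  W <- net$weights
  if (format == "mtx") {
    Matrix::writeMM(W, path)
  } else {
    tw <- Matrix::summary(W)  # i (target, 1-based), j (source), x
    df <- data.frame(source = tw$j - 1L, target = tw$i - 1L, weight = tw$x)
    df <- df[order(df$source, df$target), ]
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
  }
  sidecar <- c(list(n = net$n, family = net$family, format = format), meta)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_network
#' @param n Node count; required for `"edge_tsv"` files lacking a sidecar.
#' @export
read_network <- function(path, format = NULL, n = NULL) {
  format <- resolve_format(path, format)
  sidecar_path <- paste0(path, ".json")
  meta <- if (file.exists(sidecar_path))
    jsonlite::read_json(sidecar_path, simplifyVector = TRUE) else list()
  if (format == "mtx") {
    W <- methods::as(Matrix::readMM(path), "CsparseMatrix")
  } else {
    df <- tryCatch(
      utils::read.table(path, header = TRUE, sep = "\t",
                        colClasses = c("integer", "integer", "numeric")),
      error = function(e) stop("malformed edge list '", path, "': ",
                               conditionMessage(e)))
    if (!identical(names(df), c("source", "target", "weight")))
      stop("edge list must have header: source, target, weight")
    nn <- n %||% meta$n %||%
      (max(df$source, df$target, -1L) + 1L)
    W <- Matrix::sparseMatrix(i = df$target + 1L, j = df$source + 1L,
                              x = df$weight, dims = c(nn, nn))
  }
  threshold_network(W, family = meta$family %||% NULL)
}

resolve_format <- function(path, format) {
  if (!is.null(format)) return(match.arg(format, c("edge_tsv", "mtx")))
  if (grepl("\\.mtx$", path)) "mtx" else "edge_tsv"
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Experiment configuration
#'
#' Validated, fully serializable description of a pipeline run for
#' [run_experiment()]. Three pipelines are available:
#' * `"convergence"`: generate -> simulate -> classify -> aggregate.
#'   Needs `ensemble` (a named list with `family` and its parameters, as in
#'   [ensemble_params()], or `mode`/`loop`/... as in [lumped_hub_spec()]),
#'   `n_realizations`, and optionally the protocol fields `burn_in`,
#'   `window`, `update_fraction`, `criterion`.
#' * `"census"`: exhaustive fixed-point census. Needs `n`,
#'   `n_realizations`, `sigma_h`.
#' * `"mft"`: mean-field table over parameter vectors `k_b`, `sigma_h`,
#'   `alpha`.
#'
#' @param pipeline One of `"convergence"`, `"census"`, `"mft"`.
#' @param seed Master seed (required for stochastic pipelines).
#' @param ... Pipeline fields, see above.
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(pipeline = c("convergence", "census", "mft"),
                              seed = NULL, ...) {
  pipeline <- match.arg(pipeline)
  fields <- list(...)
  allowed <- switch(pipeline,
    convergence = c("ensemble", "n_realizations", "burn_in", "window",
                    "update_fraction", "criterion", "qfp_threshold",
                    "sign_variant"),
    census = c("n", "n_realizations", "sigma_h"),
    mft = c("k_b", "sigma_h", "alpha", "n", "k_h", "delta"))
  bad <- setdiff(names(fields), allowed)
  if (length(bad))
    stop("unknown config field(s) for pipeline '", pipeline, "': ",
         paste(bad, collapse = ", "))
  if (pipeline %in% c("convergence", "census")) {
    nr <- fields$n_realizations
    if (is.null(nr) || length(nr) != 1 || nr < 1)
      stop("n_realizations must be a positive count")
    if (is.null(seed)) stop("stochastic pipelines require a seed")
  }
  structure(c(list(pipeline = pipeline, seed = seed), fields),
            class = "experiment_config")
}

ensemble_from_config <- function(e) {
  if (!is.null(e$mode))
    return(lumped_hub_spec(
      mode = e$mode, loop = e$loop %||% "open",
      n_bulk = e$n_bulk,
      params = if (!is.null(e$k_b))
        lumped_hub_params(e$k_b, e$sigma_h, e$alpha,
                          m = e$m %||% 1,
                          k_h = e$k_h %||% ((e$m %||% 1) * e$k_b)),
      source = if (!is.null(e$source))
        do.call(ensemble_params, e$source),
      m = e$m %||% 4))
  do.call(ensemble_params, e)
}

#' Run a configured experiment
#'
#' Executes the pipeline described by an [experiment_config()] and, when
#' `out_dir` is given, writes the result table (`results.tsv`) and a JSON
#' summary (`summary.json`) including the resolved seed.
#'
#' @param config An `experiment_config`.
#' @param out_dir Optional output directory (created if missing).
#' @return The result tibble, invisibly when writing.
#' @export
run_experiment <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "experiment_config"))
  res <- switch(config$pipeline,
    convergence = {
      spec <- ensemble_from_config(config$ensemble)
      estimate_convergence_probability(
        spec, config$n_realizations,
        criterion = config$criterion %||% "qfp",
        burn_in = config$burn_in %||% 4000,
        window = config$window %||% 1000,
        update_fraction = config$update_fraction %||% 0.1,
        qfp_threshold = config$qfp_threshold %||% 0.9,
        sign_variant = config$sign_variant %||% "zero",
        seed = config$seed)
    },
    census = {
      cen <- fixed_point_census(config$n %||% 16, config$n_realizations,
                                sigma_h = config$sigma_h %||% 0,
                                seed = config$seed)
      tidy(cen)
    },
    mft = {
      grid <- tidyr_crossing(k_b = config$k_b,
                             sigma_h = config$sigma_h,
                             alpha = config$alpha)
      purrr::pmap_dfr(grid, mft_prediction,
                      n = config$n %||% 1500,
                      delta = config$delta %||% 0.1)
    })
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    tab <- res
    tab <- tab[, !vapply(tab, is.list, logical(1)), drop = FALSE]
    utils::write.table(tab, file.path(out_dir, "results.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
      list(pipeline = config$pipeline, seed = config$seed,
           n_rows = nrow(res)),
      file.path(out_dir, "summary.json"), auto_unbox = TRUE, digits = NA)
    return(invisible(res))
  }
  res
}
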