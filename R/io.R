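#' Read a location table
#'
#' CSV dialect: header `id,x,y,population` (planar, km) or
#' `id,lon,lat,population` (geographic, decimal degrees); UTF-8, decimal
#' point. The coordinate mode is inferred from the header unless forced.
#'
#' @param path CSV file path.
#' @param coord_mode optional `"planar"` or `"geographic"` override.
#' @return a [build_system()] object.
#' @export
read_locations <- function(path, coord_mode = NULL) {
  if (!file.exists(path)) rf_stop("io_failure", "no such file: %s", path)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  sys <- build_system(tab, coord_mode = coord_mode)
  message(sprintf("read %d locations from %s", sys$N, path))
  sys
}

#' Write a location table
#'
#' @param system a [build_system()] object.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_locations <- function(system, path) {
  cols <- if (system$coord_mode == "planar") c("x", "y") else c("lon", "lat")
  tab <- data.frame(id = system$id, a = system$x, b = system$y,
                    population = system$population)
  names(tab)[2:3] <- cols
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an observed flow edge list
#'
#' CSV dialect: header `origin,destination,trips`. Intrazonal rows are
#' dropped (with a message) and duplicate OD rows are summed.
#'
#' @param path CSV file path.
#' @param system a [build_system()] object resolving the ids.
#' @return a [flux_matrix()].
#' @export
read_flows <- function(path, system) {
  if (!file.exists(path)) rf_stop("io_failure", "no such file: %s", path)
  flux_from_edges(utils::read.csv(path, stringsAsFactors = FALSE), system)
}

#' Write a flux matrix as a flow edge list
#'
#' Positive entries only, sorted by origin then destination. If the matrix
#' carries a `model_spec` attribute (a [predict_generalized()] output), a
#' JSON sidecar `<path>.spec.json` with the variant, lambda, kappa and
#' support policy is written next to it.
#'
#' @param flux a [flux_matrix()].
#' @param path output CSV path.
#' @return character vector of written paths, invisibly.
#' @export
write_flows <- function(flux, path) {
  utils::write.csv(flux_edges(flux), path, row.names = FALSE, quote = FALSE)
  paths <- path
  spec <- attr(flux, "model_spec")
  if (!is.null(spec)) {
    sidecar <- paste0(path, ".spec.json")
    jsonlite::write_json(unclass(spec), sidecar, auto_unbox = TRUE,
                         digits = NA, null = "null")
    paths <- c(paths, sidecar)
  }
  invisible(paths)
}

#' Write a fit result or evaluation report
#'
#' `fit_result` objects become `fit_result.json` (grid, curves, selections).
#' `eval_report` objects become `eval_report.json` plus the per-table CSVs
#' `dist_distribution.csv`, `pop_distribution.csv`, `flux_bins.csv` and
#' `phase_grid.csv`. The output directory is created if needed.
#'
#' @param report a `fit_result` or `eval_report`.
#' @param out_dir output directory.
#' @return character vector of written paths.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) rf_stop("io_failure", "cannot create %s", out_dir)
  if (inherits(report, "fit_result")) {
    p <- file.path(out_dir, "fit_result.json")
    jsonlite::write_json(unclass(report), p, auto_unbox = TRUE, digits = NA)
    return(p)
  }
  if (!inherits(report, "eval_report")) {
    rf_stop("io_failure", "write_report expects a fit_result or eval_report")
  }
  paths <- character(0)
  pmf_df <- function(pair) {
    e <- pair$data$edges
    data.frame(lower = e[-length(e)], upper = e[-1],
               data_mass = pair$data$mass, model_mass = pair$model$mass)
  }
  wr <- function(df, name) {
    p <- file.path(out_dir, name)
    utils::write.csv(df, p, row.names = FALSE, quote = FALSE)
    p
  }
  paths <- c(paths, wr(pmf_df(report$dist_distribution), "dist_distribution.csv"))
  paths <- c(paths, wr(pmf_df(report$pop_distribution), "pop_distribution.csv"))
  paths <- c(paths, wr(report$flux_bins, "flux_bins.csv"))
  paths <- c(paths, wr(report$phase_grid, "phase_grid.csv"))
  summary <- list(
    sorensen = report$sorensen, pcc = report$pcc,
    ks_distance = report$ks_distance, ks_population = report$ks_population,
    pop_mode = report$pop_distribution$mode, alpha = report$alpha,
    flux_bins_covered = sum(report$flux_bins$covered),
    flux_bins_total = nrow(report$flux_bins)
  )
  p <- file.path(out_dir, "eval_report.json")
  jsonlite::write_json(summary, p, auto_unbox = TRUE, digits = NA)
  c(p, paths)
}

#' Read back a serialized fit result
#'
#' @param path `fit_result.json` path.
#' @return a `fit_result` object.
#' @export
read_fit_result <- function(path) {
  obj <- jsonlite::fromJSON(path)
  structure(obj, class = "fit_result")
}
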