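## Plain-text exports: feature matrices, solver energy traces and metric
## reports, for inspection outside R.

#' Export a feature matrix (and its scaler) as CSV
#'
#' Writes the per-voxel feature values with their documented column names;
#' if a scaler is fitted, a companion `<path>.scaler.csv` holds the
#' per-feature center and scale plus the global factor.
#'
#' @param features a [build_feature_matrix()] result.
#' @param path output CSV path.
#' @export
export_features <- function(features, path) {
  stopifnot(inherits(features, "feature_matrix"))
  utils::write.csv(
    data.frame(voxel = features$voxel_index, features$values,
               check.names = FALSE),
    path, row.names = FALSE)
  if (!is.null(features$scaler)) {
    utils::write.csv(
      data.frame(feature = features$feature_names,
                 center = features$scaler$center,
                 scale = features$scaler$scale,
                 global_factor = features$scaler$global_factor),
      paste0(path, ".scaler.csv"), row.names = FALSE)
  }
  invisible(path)
}

#' Export a solver energy trace as CSV
#'
#' One row per recorded objective value (every 10 iterations plus the
#' initial point), for convergence inspection.
#'
#' @param relaxed a [solve_cs()] result.
#' @param path output CSV path.
#' @export
export_energy_trace <- function(relaxed, path) {
  stopifnot(inherits(relaxed, "relaxed_labeling"))
  n <- length(relaxed$energy_trace)
  utils::write.csv(
    data.frame(iteration = c(0, seq_len(n - 1) * 10),
               energy = relaxed$energy_trace),
    path, row.names = FALSE)
  invisible(path)
}

#' Export a metrics report as JSON and CSV
#'
#' Writes `<prefix>.json` (global error, TP rate, per-class Dice, voxel
#' count, masked flag) and `<prefix>.confusion.csv` (truth rows,
#' prediction columns).
#'
#' @param metrics an [evaluate_segmentation()] result.
#' @param prefix output path prefix.
#' @export
export_metrics <- function(metrics, prefix) {
  jsonlite::write_json(
    list(global_error = metrics$global_error,
         tp_rate = metrics$tp_rate,
         dice = as.list(metrics$dice),
         n_voxels = metrics$n_voxels,
         masked = metrics$masked),
    paste0(prefix, ".json"), auto_unbox = TRUE, digits = NA)
  utils::write.csv(as.data.frame.matrix(unclass(metrics$confusion)),
                   paste0(prefix, ".confusion.csv"))
  invisible(prefix)
}
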