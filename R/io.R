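# Plain-text output: legacy-ASCII VTK structured-points files for grid
# fields, CSV for curves and traces, YAML round-trip for configurations.

#' Write grid fields as a legacy ASCII VTK structured-points file
#'
#' @param fields named list of N x N matrices (e.g. u, v, p, C).
#' @param h grid spacing (cm).
#' @param file output path.
#' @param origin grid origin.
#' @export
write_vtk_grid <- function(fields, h, file, origin = c(0, 0)) {
  N <- nrow(fields[[1]])
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "gliomaIB fields", "ASCII",
               "DATASET STRUCTURED_POINTS",
               sprintf("DIMENSIONS %d %d 1", N, N),
               sprintf("ORIGIN %g %g 0", origin[1], origin[2]),
               sprintf("SPACING %g %g 1", h, h),
               sprintf("POINT_DATA %d", N * N)), con)
  for (nm in names(fields)) {
    writeLines(c(sprintf("SCALARS %s double 1", nm),
                 "LOOKUP_TABLE default"), con)
    # VTK expects x varying fastest
    writeLines(format(as.vector(fields[[nm]]), digits = 9), con)
  }
  invisible(file)
}

#' Write all cell curves of a simulation as CSV
#'
#' Columns: node_id, x, y, curve, cell, t.
#'
#' @param sim an \code{ib_simulation}.
#' @param file output path.
#' @export
write_curves_csv <- function(sim, file) {
  rows <- list()
  add <- function(X, curve, cell) {
    data.frame(node_id = seq_len(nrow(X)), x = X[, 1], y = X[, 2],
               curve = curve, cell = cell, t = sim$t)
  }
  rows[[1]] <- add(sim$glioma$membrane$X, "membrane", "glioma")
  rows[[2]] <- add(sim$glioma$nucleus$X, "nucleus", "glioma")
  for (i in seq_along(sim$normals))
    rows[[2 + i]] <- add(sim$normals[[i]]$membrane$X, "membrane",
                         paste0("normal_", i))
  utils::write.csv(do.call(rbind, rows), file, row.names = FALSE)
  invisible(file)
}

#' Write a run trace as CSV
#' @param result an \code{ib_result} from [run_simulation()].
#' @param file output path.
#' @export
write_trace_csv <- function(result, file) {
  utils::write.csv(result$trace, file, row.names = FALSE)
  invisible(file)
}

#' Read a scenario configuration from YAML
#'
#' Values in the file override the [scenario_config()] defaults, so a file
#' needs to state only what differs from the published parameter set.
#'
#' @param file YAML path.
#' @return a [scenario_config()].
#' @export
read_config <- function(file) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the 'yaml' package is required to read configuration files")
  ov <- yaml::read_yaml(file)
  do.call(scenario_config, ov)
}

#' Write a scenario configuration to YAML
#' @param cfg a [scenario_config()].
#' @param file output path.
#' @export
write_config <- function(cfg, file) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the 'yaml' package is required to write configuration files")
  yaml::write_yaml(unclass(cfg), file)
  invisible(file)
}
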