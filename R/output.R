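#' Write a mesh with cell fields as legacy ASCII VTK
#'
#' Unstructured-grid file (quad cells in the r-z plane) with one `SCALARS`
#' record of cell data per field column; readable by ParaView and `pyvista`.
#'
#' @param mesh A `do_mesh`.
#' @param fields Data.frame (or named list) of per-element values; `NULL`
#'   writes the region label only.
#' @param path Output file path (conventionally `.vtk`).
#' @return The path, invisibly.
#' @export
write_vtk <- function(mesh, fields = NULL, path) {
  stopifnot(inherits(mesh, "do_mesh"))
  con <- file(path, "w")
  on.exit(close(con))
  n <- nrow(mesh$nodes); m <- nrow(mesh$elem)
  writeLines(c("# vtk DataFile Version 3.0",
               "axisymmetric distraction osteogenesis snapshot",
               "ASCII", "DATASET UNSTRUCTURED_GRID",
               paste("POINTS", n, "double")), con)
  utils::write.table(cbind(mesh$nodes, 0), con, row.names = FALSE,
                     col.names = FALSE)
  writeLines(paste("CELLS", m, 5 * m), con)
  utils::write.table(cbind(4L, mesh$elem - 1L), con, row.names = FALSE,
                     col.names = FALSE)
  writeLines(paste("CELL_TYPES", m), con)
  writeLines(as.character(rep(9L, m)), con)
  writeLines(paste("CELL_DATA", m), con)
  writeLines(c("SCALARS region int 1", "LOOKUP_TABLE default"), con)
  writeLines(as.character(as.integer(factor(
    mesh$region, levels = c("cortex", "marrow", "callus")))), con)
  if (!is.null(fields)) {
    fields <- as.data.frame(fields)
    for (nm in names(fields)) {
      writeLines(c(paste("SCALARS", nm, "double 1"),
                   "LOOKUP_TABLE default"), con)
      writeLines(format(fields[[nm]], digits = 9, trim = TRUE,
                        scientific = FALSE), con)
    }
  }
  invisible(path)
}

#' Write the standard output files of a run
#'
#' `ifm.csv` (day, ifm_mm), `bone_area.csv`, `concentrations.csv`, a VTK
#' snapshot per recorded day, and `result.json` with the headline numbers.
#'
#' @param result A [run_do()] result.
#' @param outdir Output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_result_outputs <- function(result, outdir) {
  stopifnot(inherits(result, "do_result"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(result$ifm_series))
    utils::write.csv(stats::setNames(result$ifm_series, c("day", "ifm_mm")),
                     file.path(outdir, "ifm.csv"), row.names = FALSE)
  utils::write.csv(result$bone_area_series,
                   file.path(outdir, "bone_area.csv"), row.names = FALSE)
  utils::write.csv(result$concentration_series,
                   file.path(outdir, "concentrations.csv"), row.names = FALSE)
  for (snap in result$snapshots)
    write_vtk(snap$mesh, snap$states,
              file.path(outdir, sprintf("snapshot_day%03d.vtk", snap$day)))
  summary_json <- list(
    protocol = result$config$protocol$label,
    bridging_day = if (is.na(result$bridging_day)) NULL else
      result$bridging_day,
    final_bone_area_mm2 = utils::tail(result$bone_area_series$bone_area, 1),
    final_mean_bone_pct = utils::tail(result$concentration_series$bone, 1),
    fixator_stiffness_N_mm = result$fixator$k0)
  jsonlite::write_json(summary_json, file.path(outdir, "result.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(outdir)
}
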