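#' Export voxel fields as a legacy VTK structured-points file
#'
#' Writes cell-centred fields (labels, temperature, potential, Joule
#' source, damage mask ...) as an ASCII VTK STRUCTURED_POINTS dataset for
#' inspection in ParaView or similar viewers.
#'
#' @param path output file.
#' @param grid a \code{\link{grid_spec}}.
#' @param fields named list of numeric/logical/integer arrays matching the
#'   grid.
#' @export
write_vtk_grid <- function(path, grid, fields) {
  stopifnot(length(fields) > 0, !is.null(names(fields)))
  n <- grid$n
  h <- grid$spacing
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "rfablate voxel fields",
               "ASCII",
               "DATASET STRUCTURED_POINTS",
               sprintf("DIMENSIONS %d %d %d", n[1], n[2], n[3]),
               sprintf("ORIGIN %g %g %g",
                       -grid$extents[1] + h / 2, -grid$extents[2] + h / 2,
                       -grid$extents[3] + h / 2),
               sprintf("SPACING %g %g %g", h, h, h),
               sprintf("POINT_DATA %d", prod(n))), con)
  for (nm in names(fields)) {
    f <- fields[[nm]]
    stopifnot(length(f) == prod(n))
    if (is.logical(f)) f <- as.integer(f)
    writeLines(c(sprintf("SCALARS %s %s 1", nm,
                         if (is.integer(f)) "int" else "float"),
                 "LOOKUP_TABLE default"), con)
    writeLines(format(as.vector(f), trim = TRUE, digits = 7,
                      scientific = TRUE), con)
  }
  invisible(path)
}
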