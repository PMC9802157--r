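#' Write cell fields to a legacy-ASCII VTK structured grid
#'
#' Writes a `STRUCTURED_GRID` file (plain text, legacy VTK format) with the
#' mesh points of a [cyl_mesh()] in the `(r, z)` plane and one `CELL_DATA`
#' scalar array per entry of `fields`. Readable by ParaView/VisIt.
#'
#' @param path output file path.
#' @param mesh a [cyl_mesh()].
#' @param fields named list of per-cell numeric vectors.
#' @return `path`, invisibly.
#' @export
write_vtk_structured <- function(path, mesh, fields) {
  stopifnot(is.list(fields), length(names(fields)) == length(fields))
  npts <- (mesh$nr + 1) * (mesh$nz + 1)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "porocav axisymmetric field snapshot",
               "ASCII",
               "DATASET STRUCTURED_GRID",
               sprintf("DIMENSIONS %d %d 1", mesh$nr + 1, mesh$nz + 1),
               sprintf("POINTS %d double", npts)), con)
  pts <- cbind(rep(mesh$r_faces, mesh$nz + 1),
               rep(mesh$z_faces, each = mesh$nr + 1), 0)
  writeLines(apply(pts, 1, function(p) paste(format(p, digits = 12),
                                             collapse = " ")), con)
  writeLines(sprintf("CELL_DATA %d", mesh$n_cells), con)
  for (nm in names(fields)) {
    v <- fields[[nm]]
    stopifnot(length(v) == mesh$n_cells)
    writeLines(c(sprintf("SCALARS %s double 1", nm),
                 "LOOKUP_TABLE default"), con)
    writeLines(format(v, digits = 12, trim = TRUE), con)
  }
  invisible(path)
}
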