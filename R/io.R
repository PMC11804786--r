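#' Write / read a labelled voxel volume as a TIFF stack with JSON sidecar
#'
#' The label grid is stored as a multi-page grayscale TIFF (one z slice per
#' page, labels scaled to 0/127/255 for viewability) and the metadata
#' (spacing, origin, label scheme, provenance, openings) in a JSON sidecar
#' next to it.
#'
#' @param geometry a [voxel_geometry()].
#' @param path output TIFF path; the sidecar is written at `<path>.json`.
#' @return `write_geometry()`: the path, invisibly. `read_geometry()`: the
#'   [voxel_geometry()].
#' @export
write_geometry <- function(geometry, path) {
  lab <- geometry$labels
  d <- dim(lab)
  pages <- lapply(seq_len(d[3]), function(z) t(lab[, , z]) / 2)
  tiff::writeTIFF(pages, path, bits.per.sample = 8L)
  meta <- list(dims = d, spacing = geometry$spacing, origin = geometry$origin,
               scheme = "canonical-0solid-1inner-2external",
               provenance = geometry$provenance,
               openings = geometry$openings)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_geometry
#' @param path TIFF path written by [write_geometry()].
#' @export
read_geometry <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  d <- as.integer(meta$dims)
  lab <- array(0L, d)
  for (z in seq_len(d[3]))
    lab[, , z] <- as.integer(round(t(pages[[z]]) * 2))
  openings <- NULL
  if (!is.null(meta$openings) && length(meta$openings))
    openings <- lapply(seq_len(nrow(meta$openings)), function(i)
      list(center = unlist(meta$openings$center[i]),
           radius = meta$openings$radius[i],
           kind = meta$openings$kind[i]))
  voxel_geometry(lab, spacing = meta$spacing, origin = meta$origin,
                 provenance = meta$provenance %||% paste("read from", path),
                 openings = openings)
}

#' Write a flow field as a legacy ASCII VTK structured-points file
#'
#' Emits velocity (VECTORS, m/s) and pressure (SCALARS) on the voxel grid in
#' the legacy VTK text format readable by ParaView.
#'
#' @param field a `coral_flow` object.
#' @param path output `.vtk` path.
#' @return The path, invisibly.
#' @export
write_field_vtk <- function(field, path) {
  d <- field$dims
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "coralflow field", "ASCII",
               "DATASET STRUCTURED_POINTS",
               sprintf("DIMENSIONS %d %d %d", d[1], d[2], d[3]),
               "ORIGIN 0 0 0",
               sprintf("SPACING %g %g %g", field$spacing, field$spacing,
                       field$spacing),
               sprintf("POINT_DATA %d", prod(d)),
               "VECTORS velocity float"), con)
  vel <- cbind(as.vector(field$ux), as.vector(field$uy), as.vector(field$uz))
  writeLines(sprintf("%g %g %g", vel[, 1], vel[, 2], vel[, 3]), con)
  p <- as.vector(field$p); p[!is.finite(p)] <- 0
  writeLines(c("SCALARS pressure float 1", "LOOKUP_TABLE default"), con)
  writeLines(sprintf("%g", p), con)
  invisible(path)
}
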