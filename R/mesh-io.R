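# Mesh export/import in standard text formats (OBJ, ASCII PLY, legacy VTK).
# Vertex order is preserved exactly so per-vertex fields stay aligned with
# files written alongside the mesh.

#' Write a surface mesh to OBJ, PLY or VTK
#'
#' @param mesh an `lv_surface_mesh` (validated before writing).
#' @param path output file.
#' @param format `"OBJ"`, `"PLY"` or `"VTK"`; inferred from the file
#'   extension when missing.
#' @param scalars optional named list of per-vertex numeric fields; written
#'   as POINT_DATA in VTK (ignored for OBJ/PLY).
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path, format = NULL, scalars = NULL) {
  if (is.null(format)) {
    format <- toupper(tools::file_ext(path))
    if (format == "") stop_lv("contour_io", "cannot infer mesh format")
  }
  format <- toupper(format)
  if (!format %in% c("OBJ", "PLY", "VTK"))
    stop_lv("contour_io", "unknown mesh format '", format,
            "' (use OBJ, PLY or VTK)")
  validate_mesh(mesh)
  v <- mesh$vertices; tr <- mesh$triangles
  con <- file(path, "w")
  on.exit(close(con))
  fmt_row <- function(x) sprintf("%.9g %.9g %.9g", x[, 1], x[, 2], x[, 3])
  if (format == "OBJ") {
    writeLines(c(paste("v", fmt_row(v)),
                 sprintf("f %d %d %d", tr[, 1], tr[, 2], tr[, 3])), con)
  } else if (format == "PLY") {
    writeLines(c("ply", "format ascii 1.0",
                 paste("element vertex", nrow(v)),
                 "property double x", "property double y",
                 "property double z",
                 paste("element face", nrow(tr)),
                 "property list uchar int vertex_indices", "end_header",
                 fmt_row(v),
                 sprintf("3 %d %d %d", tr[, 1] - 1L, tr[, 2] - 1L,
                         tr[, 3] - 1L)), con)
  } else {
    writeLines(c("# vtk DataFile Version 3.0", "lvcurve surface", "ASCII",
                 "DATASET POLYDATA",
                 paste("POINTS", nrow(v), "double"),
                 fmt_row(v),
                 paste("POLYGONS", nrow(tr), 4L * nrow(tr)),
                 sprintf("3 %d %d %d", tr[, 1] - 1L, tr[, 2] - 1L,
                         tr[, 3] - 1L)), con)
    if (!is.null(scalars)) {
      writeLines(paste("POINT_DATA", nrow(v)), con)
      for (nm in names(scalars)) {
        writeLines(c(paste("SCALARS", nm, "double 1"),
                     "LOOKUP_TABLE default",
                     sprintf("%.9g", scalars[[nm]])), con)
      }
    }
  }
  invisible(path)
}

#' Read a mesh written by [write_mesh()] (OBJ or PLY)
#'
#' Round-trip reader used for validation and downstream viewing checks.
#' @return an `lv_surface_mesh` (unvalidated structure metadata is absent).
#' @export
read_mesh <- function(path, surface = "endo", phase = "ED") {
  ext <- toupper(tools::file_ext(path))
  lines <- readLines(path)
  if (ext == "OBJ") {
    vl <- lines[startsWith(lines, "v ")]
    fl <- lines[startsWith(lines, "f ")]
    v <- do.call(rbind, lapply(strsplit(vl, "\\s+"), function(p)
      as.numeric(p[2:4])))
    tr <- do.call(rbind, lapply(strsplit(fl, "\\s+"), function(p)
      as.integer(p[2:4])))
  } else if (ext == "PLY") {
    hd_end <- which(lines == "end_header")
    nv <- as.integer(sub("element vertex ", "",
                         grep("^element vertex", lines, value = TRUE)))
    nf <- as.integer(sub("element face ", "",
                         grep("^element face", lines, value = TRUE)))
    v <- do.call(rbind, lapply(strsplit(lines[hd_end + seq_len(nv)], " "),
                               as.numeric))
    tr <- do.call(rbind,
                  lapply(strsplit(lines[hd_end + nv + seq_len(nf)], " "),
                         function(p) as.integer(p[2:4]) + 1L))
  } else {
    stop_lv("contour_io", "read_mesh supports OBJ and PLY")
  }
  surface_mesh(v, tr, surface, phase, validate = FALSE)
}
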