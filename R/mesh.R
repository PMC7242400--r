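# Triangle-mesh container and core mesh queries.
#
# An LV surface mesh is an open triangle mesh: edge-manifold, exactly one
# boundary loop (the open base), outward-consistent winding (normals away
# from the cavity for the endocardium). Meshes built by the reconstruction
# layer additionally carry structure metadata (ring index per vertex, apex
# vertex id) used to classify boundary vertices.

#' Construct a surface mesh
#'
#' @param vertices n x 3 matrix (mm).
#' @param triangles m x 3 integer matrix of 1-based vertex indices.
#' @param surface `"endo"` or `"epi"`.
#' @param phase `"ED"` or `"ES"`.
#' @param ring optional integer vector: ring index per vertex (0 = basal
#'   ring), NA for the apex vertex.
#' @param apex_id optional index of the apex (fan centre) vertex.
#' @param validate run the full invariant check (default TRUE).
#' @return an object of class `lv_surface_mesh`.
#' @export
surface_mesh <- function(vertices, triangles, surface = c("endo", "epi"),
                         phase = c("ED", "ES"), ring = NULL, apex_id = NULL,
                         validate = TRUE) {
  surface <- match.arg(surface)
  phase <- match.arg(phase)
  vertices <- as.matrix(vertices); storage.mode(vertices) <- "double"
  triangles <- as.matrix(triangles); storage.mode(triangles) <- "integer"
  if (ncol(vertices) != 3L || ncol(triangles) != 3L)
    stop_lv("reconstruct", "vertices must be n x 3 and triangles m x 3")
  m <- structure(list(vertices = vertices, triangles = triangles,
                      surface = surface, phase = phase,
                      ring = ring, apex_id = apex_id),
                 class = "lv_surface_mesh")
  if (validate) validate_mesh(m)
  m
}

#' @export
print.lv_surface_mesh <- function(x, ...) {
  cat("<lv_surface_mesh>", x$surface, x$phase, ":",
      nrow(x$vertices), "vertices,", nrow(x$triangles), "triangles\n")
  invisible(x)
}

#' Per-triangle areas
#' @keywords internal
triangle_areas <- function(mesh) {
  v <- mesh$vertices; tr <- mesh$triangles
  a <- v[tr[, 2], ] - v[tr[, 1], ]
  b <- v[tr[, 3], ] - v[tr[, 1], ]
  cx <- a[, 2] * b[, 3] - a[, 3] * b[, 2]
  cy <- a[, 3] * b[, 1] - a[, 1] * b[, 3]
  cz <- a[, 1] * b[, 2] - a[, 2] * b[, 1]
  sqrt(cx^2 + cy^2 + cz^2) / 2
}

#' Total mesh surface area (mm^2)
#' @export
mesh_surface_area <- function(mesh) sum(triangle_areas(mesh))

#' Per-vertex barycentric area shares (one third of incident triangle areas)
#'
#' Sums to the total surface area; the basis for vertex-weighted segment
#' areas and the area-strain calculation.
#' @return numeric vector, mm^2 per vertex.
#' @export
vertex_areas <- function(mesh) {
  ta <- triangle_areas(mesh) / 3
  va <- numeric(nrow(mesh$vertices))
  for (j in 1:3) {
    acc <- tapply(ta, mesh$triangles[, j], sum)
    idx <- as.integer(names(acc))
    va[idx] <- va[idx] + as.numeric(acc)
  }
  va
}

# Edge table: each undirected edge once, with incident triangle count.
#' @keywords internal
mesh_edges <- function(mesh) {
  tr <- mesh$triangles
  e <- rbind(tr[, c(1, 2)], tr[, c(2, 3)], tr[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  tab <- table(key)
  cnt <- as.integer(tab)
  uv <- do.call(rbind, strsplit(names(tab), " "))
  list(edges = cbind(as.integer(uv[, 1]), as.integer(uv[, 2])),
       count = cnt)
}

#' Validate surface-mesh invariants
#'
#' Checks edge-manifoldness, a single boundary loop, absence of degenerate
#' triangles, and index bounds. Stops with a validation error on failure.
#' @export
validate_mesh <- function(mesh) {
  v <- mesh$vertices; tr <- mesh$triangles
  if (min(tr) < 1L || max(tr) > nrow(v))
    stop_lv("reconstruct", "triangle index out of range")
  if (any(tr[, 1] == tr[, 2] | tr[, 2] == tr[, 3] | tr[, 1] == tr[, 3]))
    stop_lv("reconstruct", "triangle with repeated vertex")
  if (any(triangle_areas(mesh) < 1e-10))
    stop_lv("reconstruct", "zero-area (degenerate) triangle present")
  ed <- mesh_edges(mesh)
  if (any(ed$count > 2L))
    stop_lv("reconstruct", "non-manifold edge (more than 2 incident faces)")
  nb <- sum(ed$count == 1L)
  if (nb > 0L) {
    # boundary edges must form exactly one closed loop
    be <- ed$edges[ed$count == 1L, , drop = FALSE]
    deg <- table(c(be[, 1], be[, 2]))
    if (any(deg != 2L))
      stop_lv("reconstruct", "boundary is not a set of closed loops")
    # count loops by traversal
    adj <- split(c(be[, 2], be[, 1]), c(be[, 1], be[, 2]))
    seen <- character(0)
    loops <- 0L
    verts <- names(adj)
    while (length(setdiff(verts, seen))) {
      loops <- loops + 1L
      start <- setdiff(verts, seen)[1]
      cur <- start; prev <- NA_character_
      repeat {
        seen <- c(seen, cur)
        nxt <- as.character(adj[[cur]])
        nxt <- nxt[!(nxt %in% prev)][1]
        if (is.na(nxt) || nxt == start) break
        prev <- cur; cur <- nxt
      }
    }
    if (loops != 1L)
      stop_lv("reconstruct", "mesh has ", loops,
              " boundary loops; expected exactly 1 (open base)")
  }
  invisible(TRUE)
}

#' Boundary vertex indices (the open-base ring)
#' @export
mesh_boundary_vertices <- function(mesh) {
  ed <- mesh_edges(mesh)
  be <- ed$edges[ed$count == 1L, , drop = FALSE]
  sort(unique(as.integer(be)))
}

#' Vertex adjacency list (1-ring neighbours)
#' @keywords internal
vertex_adjacency <- function(mesh) {
  tr <- mesh$triangles
  from <- c(tr[, 1], tr[, 2], tr[, 3], tr[, 2], tr[, 3], tr[, 1])
  to   <- c(tr[, 2], tr[, 3], tr[, 1], tr[, 1], tr[, 2], tr[, 3])
  adj <- split(to, from)
  out <- vector("list", nrow(mesh$vertices))
  out[as.integer(names(adj))] <- lapply(adj, function(v) unique(v))
  out
}

#' Angle-weighted vertex normals
#'
#' Face normals averaged with weights equal to the face corner angle at the
#' vertex; the standard estimator for structured strip meshes.
#' @return n x 3 matrix of unit normals.
#' @export
vertex_normals <- function(mesh) {
  v <- mesh$vertices; tr <- mesh$triangles
  a <- v[tr[, 1], ]; b <- v[tr[, 2], ]; c_ <- v[tr[, 3], ]
  e1 <- b - a; e2 <- c_ - b; e3 <- a - c_
  crossp <- function(u, w) cbind(u[, 2] * w[, 3] - u[, 3] * w[, 2],
                                 u[, 3] * w[, 1] - u[, 1] * w[, 3],
                                 u[, 1] * w[, 2] - u[, 2] * w[, 1])
  fn <- crossp(e1, -e3)
  fn <- fn / sqrt(rowSums(fn^2))
  ang <- function(u, w) {
    cu <- sqrt(rowSums(u^2)); cw <- sqrt(rowSums(w^2))
    acos(pmin(1, pmax(-1, rowSums(u * w) / (cu * cw))))
  }
  w1 <- ang(e1, -e3); w2 <- ang(e2, -e1); w3 <- ang(e3, -e2)
  n <- matrix(0, nrow(v), 3)
  for (j in 1:3) {
    w <- list(w1, w2, w3)[[j]]
    for (d in 1:3) {
      acc <- tapply(fn[, d] * w, tr[, j], sum)
      idx <- as.integer(names(acc))
      n[idx, d] <- n[idx, d] + as.numeric(acc)
    }
  }
  n / sqrt(rowSums(n^2))
}

#' Chamber volume of a basally-capped mesh
#'
#' Closes the single boundary loop (the open base) with a flat triangle fan
#' onto the loop centroid and returns the divergence-theorem volume, in mm^3.
#' Mirrors planimetric (Simpson) volumetrics which treat the base as a flat
#' plane at the most basal contour.
#'
#' @param endo an `lv_surface_mesh` (any surface; named for the primary use).
#' @return volume in mm^3 (positive).
#' @export
chamber_volume <- function(endo) {
  v <- endo$vertices; tr <- endo$triangles
  ed <- mesh_edges(endo)
  be <- ed$edges[ed$count == 1L, , drop = FALSE]
  if (nrow(be) > 0L) {
    bz <- v[unique(as.integer(be)), 3]
    if (max(bz) - min(bz) > 0.5 * (max(v[, 3]) - min(v[, 3])))
      stop_lv("geometry", "open boundary is not basal; cannot cap")
    # order the loop
    adj <- split(c(be[, 2], be[, 1]), c(be[, 1], be[, 2]))
    start <- be[1, 1]; loop <- c(start)
    prev <- NA_integer_; cur <- start
    repeat {
      nxt <- adj[[as.character(cur)]]
      nxt <- nxt[!(nxt %in% prev)][1]
      if (is.na(nxt) || nxt == start) break
      loop <- c(loop, nxt); prev <- cur; cur <- nxt
    }
    centroid <- colMeans(v[loop, , drop = FALSE])
    nv <- rbind(v, centroid)
    ci <- nrow(nv)
    nxt <- c(loop[-1], loop[1])
    cap <- cbind(loop, nxt, ci)
    tr <- rbind(tr, cap)
    v <- nv
  }
  a <- v[tr[, 1], ]; b <- v[tr[, 2], ]; c_ <- v[tr[, 3], ]
  vol6 <- a[, 1] * (b[, 2] * c_[, 3] - b[, 3] * c_[, 2]) -
          a[, 2] * (b[, 1] * c_[, 3] - b[, 3] * c_[, 1]) +
          a[, 3] * (b[, 1] * c_[, 2] - b[, 2] * c_[, 1])
  abs(sum(vol6)) / 6
}

#' Interior vertices of a structured mesh
#'
#' Interior = not on the basal (boundary) ring, not the apex vertex, and not
#' on the apical fan ring. Regional means use interior vertices only: the
#' curvature fit is biased at boundaries and the true apex (segment 17) is
#' excluded from the regional model.
#' @return logical vector over vertices.
#' @export
mesh_interior <- function(mesh) {
  n <- nrow(mesh$vertices)
  keep <- rep(TRUE, n)
  keep[mesh_boundary_vertices(mesh)] <- FALSE
  if (!is.null(mesh$apex_id)) keep[mesh$apex_id] <- FALSE
  if (!is.null(mesh$ring)) {
    fan_ring <- max(mesh$ring, na.rm = TRUE)
    keep[!is.na(mesh$ring) & mesh$ring == fan_ring] <- FALSE
  }
  keep
}
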