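# Differential geometry on reconstructed meshes: principal curvatures by
# local quadric fitting, curvedness, ray-cast wall thickness, and the AHA
# 16-segment partition.

#' Per-vertex field container
#' @keywords internal
vertex_field <- function(mesh, name, values, units = "") {
  if (length(values) != nrow(mesh$vertices))
    stop_lv("geometry", "field length != vertex count")
  structure(list(mesh = mesh, name = name, values = values, units = units),
            class = "lv_vertex_field")
}

#' @export
print.lv_vertex_field <- function(x, ...) {
  v <- x$values[!is.na(x$values)]
  cat("<lv_vertex_field>", x$name,
      if (nzchar(x$units)) paste0("[", x$units, "]") else "",
      ": ", length(v), "assigned vertices, mean",
      signif(mean(v), 4), "\n")
  invisible(x)
}

# BFS n-ring neighbourhoods from the 1-ring adjacency
ring_neighbourhood <- function(adj, v, depth) {
  frontier <- v
  seen <- v
  for (d in seq_len(depth)) {
    frontier <- unique(unlist(adj[frontier], use.names = FALSE))
    frontier <- frontier[!(frontier %in% seen)]
    if (!length(frontier)) break
    seen <- c(seen, frontier)
  }
  seen[-1]
}

#' Principal curvatures by local quadric fitting
#'
#' For each vertex a cubic-augmented quadric height patch
#' h = b1 x + b2 y + (a x^2 + 2 b x y + c y^2) / 2 + cubic terms
#' is fitted by least squares over the `ring_depth`-ring neighbourhood in
#' the local tangent frame (height measured along the inward direction so
#' that a sphere with outward normals has positive curvature). Principal
#' curvatures are the eigenvalues of the shape operator obtained from the
#' first and second fundamental forms of the fitted patch. The linear
#' terms absorb the residual error of the estimated vertex normal and the
#' cubic terms absorb the third-order surface variation, which keeps the
#' quadratic coefficients unbiased where the sampling is one-sided or
#' anisotropic (near the apex of a structured LV mesh); neighbourhoods too
#' small for the cubic terms fall back to the plain quadric.
#'
#' Vertices with fewer than 6 neighbours, boundary-ring vertices and the
#' apex are flagged `NA` and excluded from regional means.
#'
#' @param mesh an `lv_surface_mesh`.
#' @param ring_depth neighbourhood depth (>= 2 recommended for structured
#'   strip meshes).
#' @return list of two `lv_vertex_field`s, `k1` and `k2` (k1 >= k2, mm^-1).
#' @export
principal_curvatures <- function(mesh, ring_depth = 2L) {
  if (ring_depth < 1L) stop_lv("geometry", "ring_depth >= 1 required")
  v <- mesh$vertices
  n <- nrow(v)
  adj <- vertex_adjacency(mesh)
  normals <- vertex_normals(mesh)
  interior <- mesh_interior(mesh)
  k1 <- k2 <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (!interior[i]) next
    nb <- ring_neighbourhood(adj, i, ring_depth)
    if (length(nb) < 6L) next
    nrm <- normals[i, ]
    # tangent frame
    e1 <- if (abs(nrm[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    e1 <- e1 - sum(e1 * nrm) * nrm
    e1 <- e1 / sqrt(sum(e1^2))
    e2 <- c(nrm[2] * e1[3] - nrm[3] * e1[2],
            nrm[3] * e1[1] - nrm[1] * e1[3],
            nrm[1] * e1[2] - nrm[2] * e1[1])
    d <- sweep(v[nb, , drop = FALSE], 2, v[i, ])
    x <- d %*% e1; y <- d %*% e2; h <- -(d %*% nrm)
    X <- cbind(x, y, x^2 / 2, x * y, y^2 / 2)
    if (length(nb) >= 12L)
      X <- cbind(X, x^3, x^2 * y, x * y^2, y^3)
    beta <- tryCatch(qr.solve(X, h), error = function(e) NULL)
    if (is.null(beta)) next
    fx <- beta[1]; fy <- beta[2]
    a <- beta[3]; b <- beta[4]; c_ <- beta[5]
    wsq <- 1 + fx^2 + fy^2
    II <- matrix(c(a, b, b, c_), 2, 2) / sqrt(wsq)
    I <- matrix(c(1 + fx^2, fx * fy, fx * fy, 1 + fy^2), 2, 2)
    S <- solve(I, II)
    ev <- eigen(S, only.values = TRUE)$values
    ev <- sort(Re(ev), decreasing = TRUE)
    k1[i] <- ev[1]; k2[i] <- ev[2]
  }
  list(k1 = vertex_field(mesh, "k1", k1, "mm^-1"),
       k2 = vertex_field(mesh, "k2", k2, "mm^-1"))
}

#' Curvedness (with mean and Gaussian curvature diagnostics)
#'
#' C = sqrt((k1^2 + k2^2) / 2). Unlike the mean curvature H = (k1 + k2)/2
#' (zero at saddles) or the Gaussian curvature K = k1 k2 (zero on parabolic
#' lines), curvedness vanishes only where the surface is flat.
#'
#' @param k1,k2 aligned `lv_vertex_field`s from [principal_curvatures()].
#' @return an `lv_vertex_field` for C with attributes `H` and `K`.
#' @export
curvedness <- function(k1, k2) {
  if (!identical(dim(k1$mesh$vertices), dim(k2$mesh$vertices)) ||
      length(k1$values) != length(k2$values))
    stop_lv("geometry", "k1 and k2 fields are not aligned")
  C <- sqrt((k1$values^2 + k2$values^2) / 2)
  out <- vertex_field(k1$mesh, "curvedness", C, "mm^-1")
  attr(out, "H") <- (k1$values + k2$values) / 2
  attr(out, "K") <- k1$values * k2$values
  out
}

# ---- wall thickness ----------------------------------------------------

#' Ray-cast wall thickness from the endocardium to the epicardium
#'
#' Per endocardial vertex, the length of the ray starting at the vertex,
#' directed along the outward vertex normal, up to its first intersection
#' with the epicardial surface. Rays that exit through the open base (no
#' intersection) are flagged `NA`.
#'
#' @param endo,epi `lv_surface_mesh`es, endo strictly inside epi.
#' @param vertices optional integer subset of endo vertices to compute.
#' @param check_coverage error when more than 5% of interior vertices have
#'   no intersection (surfaces inconsistent).
#' @return an `lv_vertex_field` (mm).
#' @export
wall_thickness_map <- function(endo, epi, vertices = NULL,
                               check_coverage = TRUE) {
  v <- endo$vertices
  normals <- vertex_normals(endo)
  interior <- mesh_interior(endo)
  idx <- vertices %||% seq_len(nrow(v))
  tr <- epi$triangles
  A <- epi$vertices[tr[, 1], , drop = FALSE]
  E1 <- epi$vertices[tr[, 2], , drop = FALSE] - A
  E2 <- epi$vertices[tr[, 3], , drop = FALSE] - A
  wt <- rep(NA_real_, nrow(v))
  eps <- 1e-9
  for (i in idx) {
    o <- v[i, ]; d <- normals[i, ]
    # Moller-Trumbore, vectorized over all epicardial triangles
    px <- d[2] * E2[, 3] - d[3] * E2[, 2]
    py <- d[3] * E2[, 1] - d[1] * E2[, 3]
    pz <- d[1] * E2[, 2] - d[2] * E2[, 1]
    det <- E1[, 1] * px + E1[, 2] * py + E1[, 3] * pz
    tx <- o[1] - A[, 1]; ty <- o[2] - A[, 2]; tz <- o[3] - A[, 3]
    u <- (tx * px + ty * py + tz * pz) / det
    qx <- ty * E1[, 3] - tz * E1[, 2]
    qy <- tz * E1[, 1] - tx * E1[, 3]
    qz <- tx * E1[, 2] - ty * E1[, 1]
    vv <- (d[1] * qx + d[2] * qy + d[3] * qz) / det
    tt <- (E2[, 1] * qx + E2[, 2] * qy + E2[, 3] * qz) / det
    hit <- abs(det) > 1e-12 & u >= -1e-9 & vv >= -1e-9 &
      (u + vv) <= 1 + 1e-9 & tt > eps
    if (any(hit)) wt[i] <- min(tt[hit])
  }
  if (check_coverage) {
    miss <- interior[idx] & is.na(wt[idx])
    if (mean(miss[interior[idx]]) > 0.05)
      stop_lv("geometry", "more than 5% of interior rays miss the ",
              "epicardium; surfaces inconsistent")
  }
  vertex_field(endo, "wall_thickness", wt, "mm")
}

# ---- AHA 16-segment partition -----------------------------------------

#' Partition the endocardial mesh into the AHA 16 segments
#'
#' The long axis runs from the basal plane (mean z of the open-base ring)
#' to the apex vertex; it is split into basal, mid-cavity and apical thirds
#' by normalized long-axis position. Basal and mid levels are divided into
#' six 60-degree sectors, the apical level into four 90-degree sectors, by
#' azimuth about the long axis measured from `reference_ray`
#' (counter-clockwise viewed from the apex). Segment 1 is basal anterior;
#' the true apex (segment 17) is not part of the model and the apex-fan
#' vertices are left unassigned, as are basal-ring vertices.
#'
#' @param endo endocardial `lv_surface_mesh` in the aligned frame
#'   (long axis approximately z).
#' @param reference_ray length-2 in-plane direction of the anterior
#'   (segment 1 / 7 / 13) sector centre-start; anatomically set from the RV
#'   insertion, default +x for phantoms.
#' @return object of class `lv_segment_labeling`: integer segment per
#'   vertex (NA = unassigned) plus the landmarks used.
#' @export
partition_16_segments <- function(endo, reference_ray = c(1, 0)) {
  v <- endo$vertices
  bv <- mesh_boundary_vertices(endo)
  z_base <- mean(v[bv, 3])
  apex_id <- endo$apex_id %||% which.min(v[, 3])
  apex <- v[apex_id, ]
  if (z_base - apex[3] < 1e-6)
    stop_lv("geometry", "degenerate long axis: apex on the basal plane")
  base_ctr <- colMeans(v[bv, 1:2, drop = FALSE])
  lpos <- (z_base - v[, 3]) / (z_base - apex[3])
  lpos <- pmin(pmax(lpos, 0), 1)
  # axis position interpolated base centroid -> apex at each vertex z
  ax <- cbind(base_ctr[1] + (apex[1] - base_ctr[1]) * lpos,
              base_ctr[2] + (apex[2] - base_ctr[2]) * lpos)
  ref_angle <- atan2(reference_ray[2], reference_ray[1])
  # small epsilon stabilises floor() for vertices sitting exactly on a
  # sector boundary (structured meshes place columns there)
  th <- (atan2(v[, 2] - ax[, 2], v[, 1] - ax[, 1]) - ref_angle +
           1e-9) %% (2 * pi)
  seg <- integer(nrow(v))
  basal <- lpos < 1 / 3
  mid <- lpos >= 1 / 3 & lpos < 2 / 3
  apical <- lpos >= 2 / 3
  seg[basal] <- 1L + (floor(th[basal] / (pi / 3)) %% 6)
  seg[mid] <- 7L + (floor(th[mid] / (pi / 3)) %% 6)
  seg[apical] <- 13L + (floor(th[apical] / (pi / 2)) %% 4)
  assigned <- mesh_interior(endo)
  seg[!assigned] <- NA_integer_
  structure(list(segment = seg, apex = apex, z_base = z_base,
                 reference_ray = reference_ray,
                 level_bounds = c(1 / 3, 2 / 3)),
            class = "lv_segment_labeling")
}

#' @export
print.lv_segment_labeling <- function(x, ...) {
  cat("<lv_segment_labeling>:",
      sum(!is.na(x$segment)), "assigned vertices in",
      length(unique(na.omit(x$segment))), "segments\n")
  invisible(x)
}

#' Vertex-weighted segment areas
#'
#' Sums the per-vertex barycentric area shares of the assigned vertices of
#' each segment; the 16 values partition the assigned endocardial area.
#'
#' @param mesh mesh whose geometry provides the areas (ED or ES phase).
#' @param labeling an `lv_segment_labeling` (shared across phases through
#'   the vertex correspondence).
#' @return named numeric vector of 16 areas (mm^2).
#' @export
segment_areas <- function(mesh, labeling) {
  va <- vertex_areas(mesh)
  seg <- labeling$segment
  out <- vapply(1:16, function(s) sum(va[!is.na(seg) & seg == s]),
                numeric(1))
  names(out) <- as.character(1:16)
  out
}

#' Segment means of a per-vertex field
#' @param field an `lv_vertex_field`.
#' @param labeling an `lv_segment_labeling`.
#' @return named numeric vector of 16 segment means.
#' @export
segment_means <- function(field, labeling) {
  seg <- labeling$segment
  vals <- field$values
  out <- vapply(1:16, function(s) {
    sel <- !is.na(seg) & seg == s & !is.na(vals)
    if (!any(sel))
      stop_lv("geometry", "segment ", s, " has no assigned vertices")
    mean(vals[sel])
  }, numeric(1))
  names(out) <- as.character(1:16)
  out
}
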