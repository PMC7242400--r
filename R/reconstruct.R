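# Surface reconstruction: slice misalignment correction, lofted structured
# triangle meshing of a contour stack, and thin-plate-spline ED/ES vertex
# correspondence.

# ---- misalignment correction ------------------------------------------

#' Correct in-plane slice misalignment against a straight long axis
#'
#' Breath-hold position differences translate individual short-axis slices
#' in-plane. The correction translates each slice (endo and epi together)
#' so that the epicardial area centroids minimise
#' E = sum_k || c_k + s_k - c_hat(z_k) ||^2, where c_hat is the
#' least-squares straight line through the (uncorrected) centroids: each
#' centroid is moved onto the fitted line. A common translation or a
#' linear-in-z tilt of all slices is a rigid repositioning of the stack and
#' is left untouched (it is unidentifiable from the contours alone).
#'
#' @param stack an `lv_contour_stack`.
#' @return list with `stack` (corrected) and `shifts` (n_slices x 2 matrix
#'   of applied in-plane translations, mm).
#' @export
correct_misalignment <- function(stack) {
  n <- length(stack$slices)
  if (n < 3L)
    stop_lv("reconstruct", "need >= 3 slices for axis line fit")
  z <- stack_z(stack)
  ctr <- t(vapply(stack$slices,
                  function(s) polygon_centroid(s$epi$points), numeric(2)))
  X <- cbind(1, z)
  beta <- solve(crossprod(X), crossprod(X, ctr))
  fitted <- X %*% beta
  shifts <- fitted - ctr
  slices <- lapply(seq_len(n), function(k) {
    sh <- shifts[k, ]
    move <- function(ct) {
      slice_contour(ct$slice_index, ct$z, ct$surface, ct$phase,
                    sweep(ct$points, 2, -sh), check = FALSE)
    }
    list(endo = move(stack$slices[[k]]$endo),
         epi = move(stack$slices[[k]]$epi))
  })
  list(stack = contour_stack(stack$subject_id, stack$phase, slices,
                             stack$slice_spacing),
       shifts = shifts)
}

# ---- thin-plate-spline morphing ---------------------------------------

#' Fit a 3D thin-plate-spline interpolant
#'
#' Kernel U(r) = r (the 3D biharmonic spline) with an affine part; maps
#' landmark set `X` exactly onto `Y`.
#'
#' @param X,Y n x 3 matrices of source and target landmarks.
#' @return an object of class `lv_tps`.
#' @export
tps_fit <- function(X, Y) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  n <- nrow(X)
  if (n != nrow(Y)) stop_lv("reconstruct", "landmark count mismatch")
  D <- as.matrix(dist(X))
  dup <- which(D + diag(Inf, n) < 1e-9, arr.ind = TRUE)
  if (nrow(dup))
    stop_lv("reconstruct", "duplicate landmarks (TPS system singular): ",
            "indices ", dup[1, 1], " and ", dup[1, 2])
  P <- cbind(1, X)
  M <- rbind(cbind(D, P), cbind(t(P), matrix(0, 4, 4)))
  rhs <- rbind(Y, matrix(0, 4, 3))
  sol <- solve(M, rhs)
  structure(list(X = X, W = sol[seq_len(n), , drop = FALSE],
                 A = sol[n + 1:4, , drop = FALSE]),
            class = "lv_tps")
}

#' Evaluate a thin-plate-spline at query points
#' @param tps an `lv_tps` from [tps_fit()].
#' @param Q m x 3 matrix of query points.
#' @return m x 3 matrix of mapped points.
#' @export
tps_apply <- function(tps, Q) {
  Q <- as.matrix(Q)
  # pairwise distances query x landmarks
  qq <- rowSums(Q^2); xx <- rowSums(tps$X^2)
  D2 <- outer(qq, xx, "+") - 2 * Q %*% t(tps$X)
  K <- sqrt(pmax(D2, 0))
  K %*% tps$W + cbind(1, Q) %*% tps$A
}

# ---- structured surface meshing ---------------------------------------

#' Loft a structured triangle mesh from one surface of a contour stack
#'
#' Each contour is re-sampled at `n_circumferential` equal azimuths about
#' its area centroid (angle 0 = `reference_ray`); meridians are then
#' interpolated with cubic splines through the contour ring points plus the
#' apex point, and sampled at `n_longitudinal` stations from base to apex.
#' Adjacent rings are joined by triangle strips and the apex is closed by a
#' fan; the base is left open. The apex vertex sits at the centroid of the
#' most apical contour, offset apically by `apex_offset_fraction` of the
#' slice spacing (or at `apex_z` when supplied, used for the epicardial
#' apical extension).
#'
#' @param stack an `lv_contour_stack`.
#' @param surface `"endo"` or `"epi"`.
#' @param n_circumferential points per ring (>= 32).
#' @param n_longitudinal number of rings base-to-apex (>= 4).
#' @param reference_ray length-2 in-plane direction of azimuth zero.
#' @param apex_offset_fraction fraction of slice spacing below the most
#'   apical contour at which the apex vertex is placed.
#' @param apex_z optional explicit apex z (overrides the offset rule).
#' @return an `lv_surface_mesh` with ring metadata.
#' @export
build_surface_mesh <- function(stack, surface = c("endo", "epi"),
                               n_circumferential = 96L,
                               n_longitudinal = 24L,
                               reference_ray = c(1, 0),
                               apex_offset_fraction = 0.5,
                               apex_z = NULL) {
  surface <- match.arg(surface)
  nc <- as.integer(n_circumferential); nl <- as.integer(n_longitudinal)
  if (nc < 32L) stop_lv("reconstruct", "n_circumferential >= 32 required")
  if (nl < 4L) stop_lv("reconstruct", "n_longitudinal >= 4 required")
  ref_angle <- atan2(reference_ray[2], reference_ray[1])
  contours <- lapply(stack$slices, `[[`, surface)
  ns <- length(contours)
  z <- vapply(contours, `[[`, numeric(1), "z")
  rings <- lapply(contours, resample_contour_angular, n = nc,
                  ref_angle = ref_angle)
  apex_xy <- polygon_centroid(contours[[ns]]$points)
  za <- apex_z %||% (z[ns] - apex_offset_fraction * stack$slice_spacing)
  if (za >= z[ns])
    stop_lv("reconstruct", "apex must lie apical of the last contour")

  # meridian spline per azimuth, parameterized by cumulative chord length
  verts <- matrix(0, nc * nl + 1L, 3)
  stations <- (seq_len(nl) - 1L) / nl
  for (j in seq_len(nc)) {
    pts <- rbind(cbind(t(vapply(rings, function(r) r[j, ], numeric(2))), z),
                 c(apex_xy, za))
    cl <- c(0, cumsum(sqrt(rowSums(diff(pts)^2))))
    tt <- cl / cl[length(cl)]
    for (d in 1:3) {
      verts[(seq_len(nl) - 1L) * nc + j, d] <-
        spline(tt, pts[, d], xout = stations, method = "fmm")$y
    }
  }
  apex_id <- nc * nl + 1L
  verts[apex_id, ] <- c(apex_xy, za)

  # strips between rings r and r+1 (ring-major vertex layout), apex fan
  tri <- matrix(0L, nc * (2L * (nl - 1L) + 1L), 3)
  row <- 1L
  for (r in seq_len(nl - 1L) - 1L) {
    for (j in seq_len(nc)) {
      jn <- if (j == nc) 1L else j + 1L
      v00 <- r * nc + j; v01 <- r * nc + jn
      v10 <- (r + 1L) * nc + j; v11 <- (r + 1L) * nc + jn
      tri[row, ] <- c(v00, v10, v11); row <- row + 1L
      tri[row, ] <- c(v00, v11, v01); row <- row + 1L
    }
  }
  last <- (nl - 1L) * nc
  for (j in seq_len(nc)) {
    jn <- if (j == nc) 1L else j + 1L
    tri[row, ] <- c(last + j, apex_id, last + jn); row <- row + 1L
  }
  surface_mesh(verts, tri, surface, stack$phase,
               ring = c(rep(0:(nl - 1L), each = nc), NA_integer_),
               apex_id = apex_id)
}

# ---- corresponded ED/ES pairs -----------------------------------------

#' Construct a corresponded mesh pair
#' @keywords internal
mesh_pair <- function(ed, es) {
  if (!identical(dim(ed$vertices), dim(es$vertices)) ||
      !identical(ed$triangles, es$triangles))
    stop_lv("reconstruct", "pair must share vertex count and connectivity")
  structure(list(ed = ed, es = es), class = "lv_mesh_pair")
}

#' @export
print.lv_mesh_pair <- function(x, ...) {
  cat("<lv_mesh_pair>", x$ed$surface, ":", nrow(x$ed$vertices),
      "corresponded vertices\n")
  invisible(x)
}

# Reference wall thickness for the epicardial apical extension, estimated
# as the median ray-cast thickness over the mid-cavity rings of a
# provisional mesh pair. Mid-cavity rays terminate on the well-sampled
# epicardial strip (they are unaffected by the provisional apex cap); the
# epicardial apex is then placed this thickness below the endocardial apex
# (wall-thickness continuity — the contour dialect never samples the
# epicardium below the last endo-bearing slice).
apical_wall_thickness <- function(endo, epi) {
  nl <- max(endo$ring, na.rm = TRUE) + 1L
  mid <- which(!is.na(endo$ring) & endo$ring >= floor(nl / 3) &
                 endo$ring < floor(2 * nl / 3) & mesh_interior(endo))
  if (!length(mid))
    stop_lv("reconstruct", "cannot estimate apical wall thickness")
  wt <- wall_thickness_map(endo, epi, vertices = mid,
                           check_coverage = FALSE)$values
  ok <- !is.na(wt[mid])
  if (!any(ok))
    stop_lv("reconstruct", "cannot estimate apical wall thickness")
  median(wt[mid][ok])
}

#' Build corresponded ED/ES endocardial and epicardial mesh pairs
#'
#' Lofts ED and ES meshes for both surfaces, extends the epicardial apex by
#' the estimated apical wall thickness, and generates the ES meshes by
#' morphing the ED meshes with a thin-plate-spline interpolant anchored at
#' the ring vertices (ES ring positions as targets), which guarantees
#' identical vertex count and connectivity across phases.
#'
#' @param ed_stack,es_stack aligned contour stacks for the two phases.
#' @param n_circumferential,n_longitudinal mesh resolution.
#' @param reference_ray azimuth-zero direction (same for both phases).
#' @param apex_offset_fraction apex-fan offset, fraction of slice spacing.
#' @return list with elements `endo` and `epi`, each an `lv_mesh_pair`.
#' @export
build_mesh_pair <- function(ed_stack, es_stack, n_circumferential = 96L,
                            n_longitudinal = 24L, reference_ray = c(1, 0),
                            apex_offset_fraction = 0.5) {
  build_phase <- function(stack) {
    endo <- build_surface_mesh(stack, "endo", n_circumferential,
                               n_longitudinal, reference_ray,
                               apex_offset_fraction)
    epi0 <- build_surface_mesh(stack, "epi", n_circumferential,
                               n_longitudinal, reference_ray,
                               apex_offset_fraction)
    t_ap <- apical_wall_thickness(endo, epi0)
    epi <- build_surface_mesh(stack, "epi", n_circumferential,
                              n_longitudinal, reference_ray,
                              apex_offset_fraction,
                              apex_z = endo$vertices[endo$apex_id, 3] - t_ap)
    list(endo = endo, epi = epi)
  }
  ed <- build_phase(ed_stack)
  es <- build_phase(es_stack)
  correspond <- function(med, mes) {
    ring_ids <- which(!is.na(med$ring))
    tps <- tps_fit(med$vertices[ring_ids, ], mes$vertices[ring_ids, ])
    v_es <- tps_apply(tps, med$vertices)
    es_mesh <- surface_mesh(v_es, med$triangles, med$surface, "ES",
                            ring = med$ring, apex_id = med$apex_id)
    mesh_pair(med, es_mesh)
  }
  list(endo = correspond(ed$endo, es$endo),
       epi = correspond(ed$epi, es$epi))
}
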