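# Thick-walled truncated ellipsoid-of-revolution phantoms.
#
# The phantom stands in for cine CMR geometry: a prolate endocardial
# spheroid (long semi-axis a along z, equatorial semi-axis b), an
# epicardial spheroid with semi-axes enlarged by the wall thickness, both
# truncated at the basal plane, sliced by equally spaced z-planes into
# contour stacks. End-systole is a uniform contraction of the endocardium
# by a factor lambda; the ES epicardium is scaled so myocardial volume is
# conserved (incompressibility). Every derived quantity has a closed-form
# or numerically-exact oracle, recorded in the GroundTruth.
#
# Frame: +z from apex toward base; apex of the ED endocardium at z = -a;
# basal plane at z = -a + 2a * truncation_fraction (default 0.5: the
# equator, z = 0). Slice planes are spaced so the most apical slice sits
# half a spacing above the apex, mirroring how a cine stack straddles the
# apex and making the reconstruction's default apex-fan offset land on the
# true apex.

#' Specify an LV phantom
#'
#' @param a,b endocardial ED long and equatorial semi-axes (mm), a >= b.
#' @param wall_thickness epicardial offset of the semi-axes (mm).
#' @param contraction uniform endocardial ED->ES scale factor in (0, 1].
#' @param truncation_fraction portion of the long axis retained from the
#'   apex (0.5 = truncate at the equator).
#' @param n_slices number of short-axis slices (>= 3).
#' @param points_per_contour points per closed contour polyline.
#' @param misalignment_sd SD (mm) of per-slice in-plane translation.
#' @param noise_sd SD (mm) of radial contour jitter per point.
#' @param seed RNG seed for misalignment and noise.
#' @return an object of class `lv_phantom_spec`.
#' @export
phantom_spec <- function(a = 45, b = 25, wall_thickness = 5,
                         contraction = 0.71, truncation_fraction = 0.5,
                         n_slices = 12, points_per_contour = 96,
                         misalignment_sd = 0, noise_sd = 0, seed = 1L) {
  if (!(a >= b && b > 0))
    stop_lv("phantom", "require a >= b > 0")
  if (!(contraction > 0 && contraction <= 1))
    stop_lv("phantom", "contraction must be in (0, 1]")
  if (n_slices < 3L) stop_lv("phantom", "n_slices >= 3 required")
  if (misalignment_sd < 0 || noise_sd < 0)
    stop_lv("phantom", "misalignment_sd and noise_sd must be >= 0")
  if (wall_thickness <= 0) stop_lv("phantom", "wall_thickness must be > 0")
  if (truncation_fraction <= 0 || truncation_fraction > 1)
    stop_lv("phantom", "truncation_fraction must be in (0, 1]")
  structure(list(a = a, b = b, wall_thickness = wall_thickness,
                 contraction = contraction,
                 truncation_fraction = truncation_fraction,
                 n_slices = as.integer(n_slices),
                 points_per_contour = as.integer(points_per_contour),
                 misalignment_sd = misalignment_sd, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "lv_phantom_spec")
}

# ---- spheroid closed forms --------------------------------------------

#' Volume of a spheroid truncated at plane z = h (kept from apex z = -a)
#' @keywords internal
spheroid_truncated_volume <- function(a, b, h) {
  stopifnot(h >= -a, h <= a)
  pi * b^2 * (h - h^3 / (3 * a^2) + 2 * a / 3)
}

#' Lateral surface area of a spheroid between z = z_lo and z = z_hi
#'
#' Computed by numerically exact quadrature of the surface of revolution
#' (serves as the area oracle for mesh-refinement checks).
#' @keywords internal
spheroid_zone_area <- function(a, b, z_lo, z_hi) {
  # pole-safe substitution z = -a cos(t): point (b sin t, 0, -a cos t),
  # meridian speed w = sqrt(b^2 cos^2 t + a^2 sin^2 t)
  t_lo <- acos(pmin(1, pmax(-1, -z_hi / a)))
  t_hi <- acos(pmin(1, pmax(-1, -z_lo / a)))
  g <- function(t) {
    r <- b * sin(t)
    w <- sqrt(b^2 * cos(t)^2 + a^2 * sin(t)^2)
    2 * pi * r * w  # |d(surface point)/dt| x circumference factor
  }
  integrate(g, min(t_lo, t_hi), max(t_lo, t_hi),
            rel.tol = 1e-10)$value
}

#' Principal curvatures of a spheroid at a surface point
#'
#' Closed forms for the ellipsoid of revolution x^2/b^2 + y^2/b^2 +
#' z^2/a^2 = 1: meridional curvature a*b/w^3 and circumferential normal
#' curvature a/(b*w) with w = sqrt(b^2 cos^2 t + a^2 sin^2 t), both
#' positive with the outward-normal sign convention.
#'
#' @param spec an `lv_phantom_spec` (ED endocardium is the surface).
#' @param point length-3 point on the surface (to `tol` mm).
#' @param tol on-surface tolerance in mm (default 1e-6; mesh vertices can
#'   be projected first with [ellipsoid_project()]).
#' @return list with `k1`, `k2` (k1 >= k2, mm^-1) and curvedness `C`.
#' @export
ellipsoid_curvature_oracle <- function(spec, point, tol = 1e-6) {
  a <- spec$a; b <- spec$b
  x <- point[1]; y <- point[2]; z <- point[3]
  f <- (x^2 + y^2) / b^2 + z^2 / a^2 - 1
  grad <- sqrt((2 * x / b^2)^2 + (2 * y / b^2)^2 + (2 * z / a^2)^2)
  if (abs(f) / max(grad, 1e-12) > tol)
    stop_lv("phantom", "point is not on the endocardial ellipsoid")
  s2 <- min(1, (x^2 + y^2) / b^2)          # sin^2 t
  c2 <- max(0, 1 - s2)                     # cos^2 t
  w <- sqrt(b^2 * c2 + a^2 * s2)
  km <- a * b / w^3
  kc <- a / (b * w)
  k1 <- max(km, kc); k2 <- min(km, kc)
  list(k1 = k1, k2 = k2, C = sqrt((k1^2 + k2^2) / 2))
}

#' Project a point radially onto the ED endocardial ellipsoid
#'
#' Central (origin-directed) projection; exact for points already near the
#' surface, used to evaluate oracles at mesh vertices.
#' @param spec an `lv_phantom_spec`.
#' @param point length-3 point.
#' @return projected point on the surface.
#' @export
ellipsoid_project <- function(spec, point) {
  s <- 1 / sqrt((point[1]^2 + point[2]^2) / spec$b^2 +
                  point[3]^2 / spec$a^2)
  point * s
}

#' Normal-ray wall thickness oracle on the ellipsoid phantom
#'
#' Distance from a point on the inner (endo) spheroid along its outward
#' normal to the outer (epi) spheroid, solved in closed form (quadratic).
#' This is the exact counterpart of the ray-cast thickness definition; it
#' equals the semi-axis offset only at the poles and on spheres.
#'
#' @param point point on the endo surface.
#' @param endo_axes,epi_axes c(a, b) semi-axes of the two spheroids.
#' @return thickness in mm.
#' @export
ellipsoid_normal_thickness <- function(point, endo_axes, epi_axes) {
  a <- endo_axes[1]; b <- endo_axes[2]
  ae <- epi_axes[1]; be <- epi_axes[2]
  p <- as.numeric(point)
  n <- c(p[1] / b^2, p[2] / b^2, p[3] / a^2)
  n <- n / sqrt(sum(n^2))
  A <- (n[1]^2 + n[2]^2) / be^2 + n[3]^2 / ae^2
  B <- 2 * ((p[1] * n[1] + p[2] * n[2]) / be^2 + p[3] * n[3] / ae^2)
  C0 <- (p[1]^2 + p[2]^2) / be^2 + p[3]^2 / ae^2 - 1
  disc <- B^2 - 4 * A * C0
  if (disc < 0) stop_lv("phantom", "normal ray misses the epicardium")
  (-B + sqrt(disc)) / (2 * A)
}

# ---- generation --------------------------------------------------------

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Residualize per-slice shifts against {1, z}: the constant and linear-in-z
# components of a slice-shift field are a rigid repositioning/tilt of the
# whole stack, which no straight-axis alignment can (or should) recover.
# The injected ground truth is therefore the identifiable component only.
detrend_shifts <- function(shifts, z) {
  X <- cbind(1, z)
  H <- X %*% solve(crossprod(X), t(X))
  shifts - H %*% shifts
}

phantom_slice_z <- function(a, z_base, n_slices) {
  h <- (z_base + a) / (n_slices - 0.5)
  list(z = z_base - h * (seq_len(n_slices) - 1L), spacing = h)
}

circle_contour_points <- function(r, center, n, noise_sd) {
  th <- 2 * pi * (seq_len(n) - 1L) / n
  rr <- r + if (noise_sd > 0) rnorm(n, 0, noise_sd) else 0
  cbind(center[1] + rr * cos(th), center[2] + rr * sin(th))
}

build_phantom_stack <- function(subject_id, phase, endo_axes, epi_axes,
                                z_base, n_slices, n_pts, shifts, noise_sd) {
  zs <- phantom_slice_z(endo_axes[1], z_base, n_slices)
  slices <- vector("list", n_slices)
  for (k in seq_len(n_slices)) {
    z <- zs$z[k]
    r_en <- endo_axes[2] * sqrt(max(0, 1 - z^2 / endo_axes[1]^2))
    r_ep <- epi_axes[2] * sqrt(max(0, 1 - z^2 / epi_axes[1]^2))
    ctr <- shifts[k, ]
    slices[[k]] <- list(
      endo = slice_contour(k - 1L, z, "endo", phase,
                           circle_contour_points(r_en, ctr, n_pts, noise_sd),
                           check = FALSE),
      epi = slice_contour(k - 1L, z, "epi", phase,
                          circle_contour_points(r_ep, ctr, n_pts, noise_sd),
                          check = FALSE))
  }
  contour_stack(subject_id, phase, slices, slice_spacing = zs$spacing)
}

#' Generate an ED/ES phantom contour-stack pair with ground truth
#'
#' Intersects the analytic endo/epi spheroids with equally spaced z-planes,
#' applies seeded per-slice translations (identifiable component only; see
#' the methods vignette) and radial point noise, and records the analytic
#' oracles: injected shifts, per-slice curvedness and normal-ray thickness,
#' truncated cavity and shell volumes, ejection fraction, and the exact
#' area strain 200*ln(1/lambda) %.
#'
#' @param spec an [phantom_spec()].
#' @param subject_id identifier written into the stacks.
#' @return list with elements `ed`, `es` (contour stacks) and `truth`.
#' @export
generate_phantom_pair <- function(spec, subject_id = "phantom") {
  a <- spec$a; b <- spec$b; wt <- spec$wall_thickness
  lam <- spec$contraction
  ae <- a + wt; be <- b + wt
  z_base <- -a + 2 * a * spec$truncation_fraction
  if (z_base > a - 1e-9) z_base <- a
  zs <- phantom_slice_z(a, z_base, spec$n_slices)
  if (length(zs$z) < 3L) stop_lv("phantom", "truncation yields < 3 slices")

  # ES endocardium: uniform scale by lambda. ES epicardium: scale epi by mu
  # chosen so the truncated myocardial shell volume is conserved.
  zb_es <- lam * z_base
  v_endo_ed <- spheroid_truncated_volume(a, b, z_base)
  v_epi_ed <- spheroid_truncated_volume(ae, be, z_base)
  shell <- v_epi_ed - v_endo_ed
  v_endo_es <- lam^3 * v_endo_ed
  g <- function(mu) {
    spheroid_truncated_volume(mu * ae, mu * be, zb_es) - v_endo_es - shell
  }
  mu <- if (abs(lam - 1) < 1e-12) 1 else
    stats::uniroot(g, c(lam, 1 + 1e-9), tol = 1e-12)$root

  shifts <- with_seed(spec$seed, {
    sh_ed <- matrix(rnorm(2L * spec$n_slices, 0, spec$misalignment_sd),
                    ncol = 2)
    sh_es <- matrix(rnorm(2L * spec$n_slices, 0, spec$misalignment_sd),
                    ncol = 2)
    list(ed = if (spec$misalignment_sd > 0) detrend_shifts(sh_ed, zs$z)
         else sh_ed * 0,
         es = if (spec$misalignment_sd > 0)
           detrend_shifts(sh_es, lam * zs$z) else sh_es * 0)
  })

  stacks <- with_seed(spec$seed + 1L, list(
    ed = build_phantom_stack(subject_id, "ED", c(a, b), c(ae, be),
                             z_base, spec$n_slices,
                             spec$points_per_contour, shifts$ed,
                             spec$noise_sd),
    es = build_phantom_stack(subject_id, "ES", c(lam * a, lam * b),
                             c(mu * ae, mu * be), zb_es, spec$n_slices,
                             spec$points_per_contour, shifts$es,
                             spec$noise_sd)))
  ed <- stacks$ed; es <- stacks$es

  slice_tab <- data.frame(z = zs$z)
  slice_tab$endo_radius <- b * sqrt(pmax(0, 1 - slice_tab$z^2 / a^2))
  slice_tab$curvedness <- vapply(seq_len(nrow(slice_tab)), function(i) {
    p <- c(slice_tab$endo_radius[i], 0, slice_tab$z[i])
    ellipsoid_curvature_oracle(spec, p)$C
  }, numeric(1))
  slice_tab$thickness <- vapply(seq_len(nrow(slice_tab)), function(i) {
    p <- c(slice_tab$endo_radius[i], 0, slice_tab$z[i])
    ellipsoid_normal_thickness(p, c(a, b), c(ae, be))
  }, numeric(1))

  truth <- list(
    spec = spec,
    shifts_ed = shifts$ed, shifts_es = shifts$es,
    z_base = z_base, slice_z = zs$z, slice_spacing = zs$spacing,
    endo_axes_ed = c(a = a, b = b), epi_axes_ed = c(a = ae, b = be),
    endo_axes_es = c(a = lam * a, b = lam * b),
    epi_axes_es = c(a = mu * ae, b = mu * be),
    cavity_volume_ed = v_endo_ed, cavity_volume_es = v_endo_es,
    shell_volume = shell, mass_g = 1.05 * shell / 1000,
    ef_pct = 100 * (1 - lam^3),
    area_strain_pct = 200 * log(1 / lam),
    per_slice = slice_tab,
    curvedness_at = function(point) ellipsoid_curvature_oracle(spec, point),
    thickness_at = function(point)
      ellipsoid_normal_thickness(point, c(a, b), c(ae, be)))
  list(ed = ed, es = es, truth = truth)
}
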