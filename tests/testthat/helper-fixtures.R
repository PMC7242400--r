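# Shared fixtures, built once per test run and cached. The two full
# pipeline runs (sphere and contracting prolate) are the study-condition
# phantoms used both by the module tests and the acceptance suite.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# Noiseless sphere phantom (r_endo 25 mm, WT 5 mm) through the full
# pipeline at the default 96 x 24 resolution.
sphere_fixture <- function() fixture("sphere", {
  spec <- phantom_spec(a = 25, b = 25, wall_thickness = 5, contraction = 1,
                       n_slices = 12)
  ph <- generate_phantom_pair(spec)
  # ESV equals EDV exactly (lambda = 1): the phase-mislabel warning is
  # expected for this static phantom
  res <- suppressWarnings(
    run_pipeline(ph$ed, ph$es,
                 list(subject_id = "sphere", sbp = 120,
                      height = 170, weight = 70)))
  list(spec = spec, ph = ph, res = res)
})

# Incompressible contraction phantom (prolate 45 x 25 mm, lambda = 0.8).
contraction_fixture <- function() fixture("contraction", {
  spec <- phantom_spec(a = 45, b = 25, wall_thickness = 5,
                       contraction = 0.8, n_slices = 12)
  ph <- generate_phantom_pair(spec)
  res <- run_pipeline(ph$ed, ph$es,
                      list(subject_id = "contraction", sbp = 120,
                           bsa = 1.7))
  list(spec = spec, ph = ph, res = res)
})

# Static prolate endocardial mesh with curvature fields (a = 45, b = 25).
prolate_fixture <- function() fixture("prolate", {
  spec <- phantom_spec(a = 45, b = 25, wall_thickness = 5, contraction = 1,
                       n_slices = 12)
  ph <- generate_phantom_pair(spec)
  st <- correct_misalignment(ph$ed)$stack
  mesh <- build_surface_mesh(st, "endo", 96, 24)
  ks <- principal_curvatures(mesh, 2)
  list(spec = spec, ph = ph, stack = st, mesh = mesh,
       k1 = ks$k1, k2 = ks$k2, C = curvedness(ks$k1, ks$k2))
})

# Closed UV-sphere mesh (no boundary), used for closed-volume checks.
uv_sphere_mesh <- function(r = 25, n_th = 48, n_ph = 96) {
  th <- seq(0, pi, length.out = n_th + 1)[2:n_th]  # exclude poles
  verts <- do.call(rbind, lapply(th, function(t)
    cbind(r * sin(t) * cos(2 * pi * (0:(n_ph - 1)) / n_ph),
          r * sin(t) * sin(2 * pi * (0:(n_ph - 1)) / n_ph),
          r * cos(t))))
  north <- nrow(verts) + 1L; south <- nrow(verts) + 2L
  verts <- rbind(verts, c(0, 0, r), c(0, 0, -r))
  tri <- list()
  nr <- n_th - 1L
  for (rr in seq_len(nr - 1L)) {
    for (j in seq_len(n_ph)) {
      jn <- if (j == n_ph) 1L else j + 1L
      v00 <- (rr - 1L) * n_ph + j; v01 <- (rr - 1L) * n_ph + jn
      v10 <- rr * n_ph + j; v11 <- rr * n_ph + jn
      tri[[length(tri) + 1L]] <- c(v00, v10, v11)
      tri[[length(tri) + 1L]] <- c(v00, v11, v01)
    }
  }
  for (j in seq_len(n_ph)) {
    jn <- if (j == n_ph) 1L else j + 1L
    tri[[length(tri) + 1L]] <- c(north, j, jn)
    tri[[length(tri) + 1L]] <- c((nr - 1L) * n_ph + j, south,
                                 (nr - 1L) * n_ph + jn)
  }
  surface_mesh(verts, do.call(rbind, tri), "endo", "ED", validate = FALSE)
}

# Square-ish closed contour sampled at a clinically realistic density.
square_contour <- function(n_side = 8L, half = 10) {
  s <- seq(-half, half, length.out = n_side + 1)[-(n_side + 1)]
  pts <- rbind(cbind(s, -half), cbind(half, s),
               cbind(rev(s), half), cbind(-half, rev(s)))
  slice_contour(0, 0, "endo", "ED", pts)
}
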