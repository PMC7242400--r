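# Phantom generation and its analytic oracles

test_that("sphere phantom contours are circles of radius sqrt(r^2 - z^2)", {
  spec <- phantom_spec(a = 25, b = 25, wall_thickness = 5, contraction = 1,
                       n_slices = 8)
  ph <- generate_phantom_pair(spec)
  for (s in ph$ed$slices) {
    r_expect <- sqrt(625 - s$endo$z^2)
    r_obs <- sqrt(rowSums(s$endo$points^2))
    expect_equal(r_obs, rep(r_expect, nrow(s$endo$points)),
                 tolerance = 1e-9, ignore_attr = TRUE)
  }
  expect_equal(ph$truth$per_slice$curvedness, rep(0.04, 8))
  expect_equal(ph$truth$per_slice$thickness, rep(5, 8), tolerance = 1e-9)
})

test_that("ground-truth identities: area strain, volumes, EF", {
  ph1 <- generate_phantom_pair(phantom_spec(contraction = 0.707))
  expect_equal(ph1$truth$area_strain_pct, 200 * log(1 / 0.707),
               tolerance = 1e-12)
  ph2 <- generate_phantom_pair(phantom_spec(a = 48, b = 25,
                                            contraction = 1))
  expect_equal(ph2$truth$cavity_volume_ed, 2 / 3 * pi * 48 * 25^2,
               tolerance = 1e-12)
  ph3 <- generate_phantom_pair(phantom_spec(contraction = 0.8))
  expect_equal(ph3$truth$ef_pct, 100 * (1 - 0.8^3), tolerance = 1e-12)
  # incompressibility: ES shell volume equals ED shell volume
  tr <- ph3$truth
  ves_epi <- lvcurve:::spheroid_truncated_volume(
    tr$epi_axes_es["a"], tr$epi_axes_es["b"], 0.8 * tr$z_base)
  expect_equal(ves_epi - tr$cavity_volume_es, tr$shell_volume,
               tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("curvature oracle matches sphere, pole and a finite-difference
           second-fundamental-form computation", {
  sph <- phantom_spec(a = 25, b = 25)
  o <- ellipsoid_curvature_oracle(sph, c(0, 25, 0))
  expect_equal(c(o$k1, o$k2, o$C), c(0.04, 0.04, 0.04))
  pro <- phantom_spec(a = 45, b = 25)
  o2 <- ellipsoid_curvature_oracle(pro, c(0, 0, -45))
  expect_equal(o2$k1, 45 / 25^2, tolerance = 1e-9)
  expect_equal(o2$k2, 45 / 25^2, tolerance = 1e-9)
  expect_error(ellipsoid_curvature_oracle(pro, c(0, 0, -40)),
               "not on the")

  # independent finite-difference oracle on the parametric surface
  fd_curvatures <- function(a, b, t0, p0, h = 1e-4) {
    S <- function(t, p) c(b * sin(t) * cos(p), b * sin(t) * sin(p),
                          -a * cos(t))
    St <- (S(t0 + h, p0) - S(t0 - h, p0)) / (2 * h)
    Sp <- (S(t0, p0 + h) - S(t0, p0 - h)) / (2 * h)
    Stt <- (S(t0 + h, p0) - 2 * S(t0, p0) + S(t0 - h, p0)) / h^2
    Spp <- (S(t0, p0 + h) - 2 * S(t0, p0) + S(t0, p0 - h)) / h^2
    Stp <- (S(t0 + h, p0 + h) - S(t0 + h, p0 - h) - S(t0 - h, p0 + h) +
              S(t0 - h, p0 - h)) / (4 * h^2)
    nrm <- c(St[2] * Sp[3] - St[3] * Sp[2], St[3] * Sp[1] - St[1] * Sp[3],
             St[1] * Sp[2] - St[2] * Sp[1])
    nrm <- nrm / sqrt(sum(nrm^2))
    E <- sum(St * St); FF <- sum(St * Sp); G <- sum(Sp * Sp)
    L <- sum(Stt * nrm); M <- sum(Stp * nrm); N <- sum(Spp * nrm)
    Imat <- matrix(c(E, FF, FF, G), 2)
    IImat <- matrix(c(L, M, M, N), 2)
    kk <- Re(eigen(solve(Imat, IImat), only.values = TRUE)$values)
    # differential-geometry sign (outward normal makes convex surfaces
    # negative) -> package convention (convex positive): negate when the
    # computed normal points outward
    if (sum(nrm * S(t0, p0)) > 0) kk <- -kk
    sort(kk, decreasing = TRUE)
  }
  for (t0 in c(pi / 6, pi / 3, pi / 2 - 1e-3)) {
    p <- c(25 * sin(t0) * 0.6, 25 * sin(t0) * 0.8, -45 * cos(t0))
    o3 <- ellipsoid_curvature_oracle(pro, p)
    kk <- fd_curvatures(45, 25, t0, atan2(0.8, 0.6))
    expect_equal(c(o3$k1, o3$k2), kk, tolerance = 1e-5)
  }
})

test_that("oracle curvedness is invariant under rotation about the axis", {
  pro <- phantom_spec(a = 45, b = 25)
  t0 <- pi / 4
  Cs <- sapply(seq(0, 2 * pi, length.out = 9), function(phi) {
    p <- c(25 * sin(t0) * cos(phi), 25 * sin(t0) * sin(phi),
           -45 * cos(t0))
    ellipsoid_curvature_oracle(pro, p)$C
  })
  expect_equal(max(Cs) - min(Cs), 0, tolerance = 1e-12)
})

test_that("generation is seed-reproducible and exact when noiseless", {
  spec <- phantom_spec(misalignment_sd = 2, noise_sd = 0.4, seed = 11)
  a <- generate_phantom_pair(spec)
  b <- generate_phantom_pair(spec)
  expect_identical(a$ed$slices[[3]]$endo$points,
                   b$ed$slices[[3]]$endo$points)
  expect_identical(a$truth$shifts_ed, b$truth$shifts_ed)
  # noiseless contours lie on the analytic surface to 1e-9
  clean <- generate_phantom_pair(phantom_spec(a = 45, b = 25))
  for (s in clean$ed$slices) {
    res <- (s$endo$points[, 1]^2 + s$endo$points[, 2]^2) / 25^2 +
      s$endo$z^2 / 45^2 - 1
    expect_lt(max(abs(res)), 1e-9)
  }
})

test_that("normal-thickness oracle is exact on concentric spheres", {
  p <- c(0, 20, 0)
  expect_equal(ellipsoid_normal_thickness(p, c(20, 20), c(25, 25)), 5,
               tolerance = 1e-12)
  # prolate: pole thickness equals the semi-axis offset
  expect_equal(ellipsoid_normal_thickness(c(0, 0, -45), c(45, 25),
                                          c(50, 30)), 5, tolerance = 1e-9)
})

test_that("phantom spec rejects invalid parameters", {
  expect_error(phantom_spec(a = 20, b = 25), "a >= b")
  expect_error(phantom_spec(contraction = 0), "contraction")
  expect_error(phantom_spec(n_slices = 2), "n_slices")
  expect_error(phantom_spec(noise_sd = -1), ">= 0")
})
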