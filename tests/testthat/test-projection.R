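test_that("analytic projection: chord values, symmetry, linearity", {
  geom <- scan_geometry(n_angles = 8, n_detectors = 64, det_pitch = 2 / 64)
  ## empty model -> zero sinogram
  p0 <- project_vector(vector_model(), dict, geom, 80)
  expect_true(all(p0$values == 0))
  ## centered disk: every ray value equals the chord-length formula
  R <- 0.5
  ps <- project_vector(water_disk(R), dict, geom, 80)
  u <- detector_coords(geom)
  chord <- ifelse(abs(u) < R, 2 * sqrt(pmax(R^2 - u^2, 0)), 0)
  for (a in seq_along(geom$angles))
    expect_equal(ps$values[a, ], chord * mu_of(dict, "water", 80), tolerance = 1e-12)
  ## parallel-beam symmetry: p(theta, u) = p(theta + pi, -u)
  off <- vector_model(list(vm_ellipse(c(0.3, -0.2), c(0.4, 0.25), "skull", angle = 0.5)))
  g2 <- scan_geometry(angles = c(0.7, 0.7 + pi), n_detectors = 64, det_pitch = 2 / 64)
  p2 <- project_vector(off, dict, g2, 80)
  expect_equal(p2$values[1, ], rev(p2$values[2, ]), tolerance = 1e-10)
  ## linearity over disjoint primitives
  v1 <- vector_model(list(vm_ellipse(c(-0.5, 0), c(0.3, 0.3), "water")))
  v2 <- vector_model(list(vm_ellipse(c(0.5, 0), c(0.3, 0.3), "skull")))
  v12 <- vector_model(c(v1$primitives, v2$primitives))
  expect_equal(project_vector(v12, dict, geom, 80)$values,
               project_vector(v1, dict, geom, 80)$values +
               project_vector(v2, dict, geom, 80)$values, tolerance = 1e-12)
  ## painter order: overlapping primitives resolved by the topmost material
  vo <- vector_model(list(vm_ellipse(c(0, 0), c(0.5, 0.5), "water"),
                          vm_ellipse(c(0, 0), c(0.25, 0.25), "skull")))
  po <- project_vector(vo, dict, geom, 80)
  cray <- which.min(abs(u))
  expected <- 2 * sqrt(0.5^2 - u[cray]^2) * mu_of(dict, "water", 80) +
    2 * sqrt(0.25^2 - u[cray]^2) * (mu_of(dict, "skull", 80) - mu_of(dict, "water", 80))
  expect_equal(po$values[1, cray], expected, tolerance = 1e-12)
})

test_that("voxel projector matches the analytic oracle and the Beer-Lambert mix", {
  geom <- scan_geometry(n_angles = 90, n_detectors = 256, det_pitch = 2 / 256)
  v <- water_disk(0.5)
  ps <- project_vector(v, dict, geom, 80)
  w <- voxelize_weights(v, dict, 128, 2 / 128)
  ## vacuum phantom -> counts = I0 everywhere
  w0 <- voxelize_weights(vector_model(), dict, 32, 2 / 32)
  p0 <- project_weights(w0, dict, geom, monochromatic(80), I0 = 1234)
  expect_true(all(p0$counts == 1234))
  ## monochromatic: relative L2 error vs the analytic sinogram <= 2%
  pr <- log_normalize(project_weights(w, dict, geom, monochromatic(80),
                                      I0 = 1e6, supersample = 2))
  rel <- sqrt(sum((pr$values - ps$values)^2) / sum(ps$values^2))
  expect_lt(rel, 0.02)
  ## supersampling self-converges: error vs a fine (s = 8) reference at least
  ## halves from 1 -> 2 -> 4
  pref <- log_normalize(project_weights(w, dict, geom, monochromatic(80),
                                        I0 = 1e6, supersample = 8))
  rels <- vapply(c(1, 2, 4), function(s) {
    p <- log_normalize(project_weights(w, dict, geom, monochromatic(80),
                                       I0 = 1e6, supersample = s))
    sqrt(sum((p$values - pref$values)^2) / sum(pref$values^2))
  }, numeric(1))
  expect_lt(rels[2], rels[1] / 2)
  expect_lt(rels[3], rels[2])
  ## and the oracle error halves as the phantom grid refines at fixed supersample
  g45 <- scan_geometry(n_angles = 45, n_detectors = 256, det_pitch = 2 / 256)
  ps45 <- project_vector(v, dict, g45, 80)
  grid_err <- vapply(c(64, 128, 256), function(n) {
    wk <- voxelize_weights(v, dict, n, 2 / n)
    pk <- log_normalize(project_weights(wk, dict, g45, monochromatic(80),
                                        I0 = 1e6, supersample = 2))
    sqrt(sum((pk$values - ps45$values)^2) / sum(ps45$values^2))
  }, numeric(1))
  expect_true(all(grid_err[-1] < 0.6 * grid_err[-3]))
  ## two-bin spectrum on a full-coverage slab: counts follow the scalar mix
  slab <- voxelize_weights(vector_model(list(vm_ellipse(c(0, 0), c(50, 50), "water"))),
                           dict, 32, 2 / 32)
  gslab <- scan_geometry(angles = 0, n_detectors = 16, det_pitch = 0.1)
  sp <- xray_spectrum(c(60, 100), c(0.3, 0.7))
  pslab <- project_weights(slab, dict, gslab, sp, I0 = 1e6, supersample = 1)
  L <- 32 * (2 / 32)   # vertical path fully inside the slab
  expected <- 1e6 * (0.3 * exp(-mu_of(dict, "water", 60) * L) +
                     0.7 * exp(-mu_of(dict, "water", 100) * L))
  expect_equal(unname(pslab$counts[1, 8]), expected, tolerance = 1e-9)
  ## monochromatic projection is linear in the phantom
  wsum <- w; wsum$values <- w$values * 0.5
  pa <- log_normalize(project_weights(w, dict, geom, monochromatic(80), I0 = 1e6))
  ph <- log_normalize(project_weights(wsum, dict, geom, monochromatic(80), I0 = 1e6))
  expect_equal(2 * ph$values, pa$values, tolerance = 1e-9)
})

test_that("Poisson noise is seeded, reproducible, refuses double application", {
  geom <- scan_geometry(n_angles = 10, n_detectors = 32, det_pitch = 0.1)
  w <- voxelize_weights(water_disk(0.5), dict, 32, 2 / 32)
  p <- project_weights(w, dict, geom, monochromatic(80), I0 = 100)
  p$counts[1, 1] <- 0                       # zero-mean element stays zero
  n1 <- add_poisson_noise(p, seed = 5)
  n2 <- add_poisson_noise(p, seed = 5)
  expect_identical(n1$counts, n2$counts)
  expect_equal(n1$counts[1, 1], 0)
  expect_error(add_poisson_noise(n1, seed = 6), "force")
  expect_silent(add_poisson_noise(n1, seed = 6, force = TRUE))
  ## CLT: mean of 10^4 draws at mean 100 within 100 +- 3 * sqrt(100/1e4)
  pm <- p; pm$counts <- matrix(100, 100, 100)
  nm <- add_poisson_noise(pm, seed = 7)
  expect_lt(abs(mean(nm$counts) - 100), 3 * sqrt(100 / 1e4))
})

test_that("deterministic angle subsampling keeps the documented index sets", {
  geom <- scan_geometry(n_angles = 360, n_detectors = 8, det_pitch = 0.1)
  w <- voxelize_weights(water_disk(0.2), dict, 16, 1 / 16)
  p <- log_normalize(project_weights(w, dict, geom, monochromatic(80), I0 = 1e5))
  expect_equal(subsample_angles_deterministic(p, keep_every_k = 1)$values, p$values)
  sp <- subsample_angles_deterministic(p, keep_every_k = 4)
  expect_equal(length(sp$geometry$angles), 90)
  expect_equal(sp$geometry$angles, geom$angles[seq(1, 360, by = 4)])
  g180 <- scan_geometry(n_angles = 180, n_detectors = 8, det_pitch = 0.1)
  p180 <- log_normalize(project_weights(w, dict, g180, monochromatic(80), I0 = 1e5))
  la <- subsample_angles_deterministic(p180, angle_range = c(0, pi / 2 - 1e-9))
  expect_equal(length(la$geometry$angles), 90)
  expect_error(subsample_angles_deterministic(p, angle_range = c(10, 11)), "every projection")
})

test_that("random angle subsampling is seeded and unbiased", {
  geom <- scan_geometry(n_angles = 180, n_detectors = 4, det_pitch = 0.1)
  w <- voxelize_weights(water_disk(0.1), dict, 8, 0.1)
  p <- log_normalize(project_weights(w, dict, geom, monochromatic(80), I0 = 1e5))
  full <- subsample_angles_random(p, m = 180, seed = 1)
  expect_equal(full$geometry$angles, geom$angles)
  s1 <- subsample_angles_random(p, m = 45, seed = 2)
  s2 <- subsample_angles_random(p, m = 45, seed = 2)
  expect_identical(s1$geometry$angles, s2$geometry$angles)
  expect_false(is.unsorted(s1$geometry$angles, strictly = TRUE))
  expect_error(subsample_angles_random(p, m = 0, seed = 1), "1, 180")
  ## selection frequency m/N within 5 percentage points over 1000 seeded draws
  counts <- numeric(180)
  for (s in 1:1000) {
    sel <- subsample_angles_random(p, m = 90, seed = s)
    counts[match(sel$geometry$angles, geom$angles)] <-
      counts[match(sel$geometry$angles, geom$angles)] + 1
  }
  expect_true(all(abs(counts / 1000 - 0.5) < 0.05))
})

test_that("log-normalization handles the photon floor and records it", {
  geom <- scan_geometry(n_angles = 4, n_detectors = 8, det_pitch = 0.1)
  w <- voxelize_weights(water_disk(0.2), dict, 16, 1 / 16)
  p <- project_weights(w, dict, geom, monochromatic(80), I0 = 1000)
  p$counts[1, 1] <- 1000        # counts = air scan -> 0
  p$counts[2, 1] <- 1000 * exp(-1)
  p$counts[3, 1] <- 0           # floored element
  r <- log_normalize(p)
  expect_equal(r$values[1, 1], 0)
  expect_equal(r$values[2, 1], 1, tolerance = 1e-12)
  expect_equal(r$values[3, 1], -log(1 / 1000))
  floored <- Filter(function(s) identical(s$op, "P2P"), r$provenance)[[1]]$floored_elements
  expect_gte(floored, 1)
  pb <- p; pb$air_scan <- matrix(0, 4, 8)
  expect_error(log_normalize(pb), "air scan")
})

test_that("water correction is exact for water and identity for monochromatic input", {
  geom <- scan_geometry(n_angles = 30, n_detectors = 128, det_pitch = 9 / 128)
  w <- voxelize_weights(water_disk(2), dict, 96, 6 / 96)
  sp <- xray_spectrum(c(60, 100), c(0.5, 0.5))
  corrected <- water_correct(log_normalize(
    project_weights(w, dict, geom, sp, I0 = 1e6, supersample = 2)), dict, 80)
  mono <- log_normalize(project_weights(w, dict, geom, monochromatic(80),
                                        I0 = 1e6, supersample = 2))
  expect_lt(max(abs(corrected$values - mono$values)), 1e-6)
  pcorr <- water_correct(mono, dict, 80)
  expect_lt(max(abs(pcorr$values - mono$values)), 1e-9)
  expect_equal(pcorr$energy, 80)
})

test_that("beam hardening: polychromatic integrals fall inside the per-bin envelope,
           and the calibration curve is increasing and concave", {
  sp <- xray_spectrum(c(60, 100), c(0.5, 0.5))
  mu <- mu_of(dict, "water", c(60))  # scalar lookups below
  L <- c(0.5, 2, 5, 10)
  q <- -log(0.5 * exp(-mu_of(dict, "water", 60) * L) +
            0.5 * exp(-mu_of(dict, "water", 100) * L))
  expect_true(all(q < mu_of(dict, "water", 60) * L))
  expect_true(all(q > mu_of(dict, "water", 100) * L))
  Lg <- seq(0, 20, length.out = 400)
  qg <- -log(0.5 * exp(-mu_of(dict, "water", 60) * Lg) +
             0.5 * exp(-mu_of(dict, "water", 100) * Lg))
  expect_true(all(diff(qg) > 0))
  expect_true(all(diff(diff(qg)) < 1e-12))
})
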