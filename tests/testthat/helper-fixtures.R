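## Shared fixtures: everything is generated in code at test time.

dict <- material_dictionary()

## a centered water disk model (radius in cm)
water_disk <- function(radius = 0.5)
  vector_model(list(vm_ellipse(c(0, 0), c(radius, radius), "water")),
               coord_sys(id = "phantom"))

## a small head-like slice: skull ring (painter order), water interior,
## two soft-tissue inserts
head_phantom <- function()
  vector_model(list(
    vm_ellipse(c(0, 0), c(2.9, 2.9), "skull"),
    vm_ellipse(c(0, 0), c(2.6, 2.6), "water"),
    vm_ellipse(c(0.9, 0.2), c(0.9, 0.6), "pancreas", angle = 0.4),
    vm_ellipse(c(-1.0, 0.4), c(0.7, 0.7), "lung")),
    coord_sys(id = "phantom"))

desk_geom <- function(n_angles = 180, n_detectors = 192)
  scan_geometry(n_angles = n_angles, n_detectors = n_detectors,
                det_pitch = 9 / n_detectors)

## default desk-scale truect config (the packaged study conditions)
truect_test_config <- function(...) {
  workflow_config("truect",
    phantom = list(primitives = head_phantom()$primitives),
    sides = 96, pitch = 6 / 96,
    geometry = list(n_angles = 180, n_detectors = 192, det_pitch = 9 / 192),
    spectrum = list(energies = c(60, 80, 100), weights = c(0.25, 0.5, 0.25)),
    e_ref = 80, I0 = 1e5, n_boot = 50,
    seeds = list(noise = 11, boot = 12), ...)
}

## independent SSIM oracle: direct per-pixel loops with an explicit Gaussian
## window, defined only where the window is fully inside the image
ssim_oracle <- function(x, y, win = 11L, sigma = 1.5, k1 = 0.01, k2 = 0.03) {
  r <- (win - 1) / 2
  k1d <- exp(-((-r:r)^2) / (2 * sigma^2)); k1d <- k1d / sum(k1d)
  K <- outer(k1d, k1d)
  n1 <- nrow(x); n2 <- ncol(x)
  c1 <- k1^2; c2 <- k2^2
  vals <- c()
  for (i in (r + 1):(n1 - r)) for (j in (r + 1):(n2 - r)) {
    wx <- x[(i - r):(i + r), (j - r):(j + r)]
    wy <- y[(i - r):(i + r), (j - r):(j + r)]
    mx <- sum(K * wx); my <- sum(K * wy)
    vx <- sum(K * wx^2) - mx^2; vy <- sum(K * wy^2) - my^2
    cxy <- sum(K * wx * wy) - mx * my
    vals <- c(vals, ((2 * mx * my + c1) * (2 * cxy + c2)) /
                    ((mx^2 + my^2 + c1) * (vx + vy + c2)))
  }
  mean(vals)
}

## random rigid transform about the z axis (slice-friendly)
random_rigid_z <- function(src = "a", tgt = "b") {
  rigid_transform(rot_z(runif(1, 0, 2 * pi)), c(runif(2, -1, 1), 0),
                  source = src, target = tgt)
}
rot_z <- vctbench:::rot_z
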