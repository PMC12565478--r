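## The vCT scanner: parallel-beam geometry, spectra, analytic and voxel-driven
## forward projection, photon noise, angle subsampling, log-normalization and
## water (beam-hardening) correction.

#' Parallel-beam scan geometry
#'
#' 2D parallel-beam geometry with a centered linear detector array. The
#' detector axis passes through the rotation axis; element `j` (0-based)
#' sits at `(j - (n_detectors - 1)/2) * det_pitch` cm.
#'
#' @param n_angles number of uniformly spaced angles over `[0, pi)`; ignored
#'   when `angles` is given.
#' @param angles explicit strictly increasing angle list in radians,
#'   within `[0, 2*pi)`.
#' @param n_detectors number of detector elements.
#' @param det_pitch detector element pitch (cm).
#' @param object_radius optional support radius of the phantom (cm); a
#'   detector span smaller than the support triggers a truncation warning.
#' @return object of class `scan_geometry`.
#' @export
scan_geometry <- function(n_angles = NULL, angles = NULL, n_detectors,
                          det_pitch, object_radius = NULL) {
  if (is.null(angles)) {
    if (is.null(n_angles)) stop_contract("give n_angles or an explicit angle list")
    angles <- seq(0, pi, length.out = n_angles + 1)[seq_len(n_angles)]
  }
  angles <- as.numeric(angles)
  if (any(angles < 0) || any(angles >= 2 * pi) || is.unsorted(angles, strictly = TRUE))
    stop_contract("angles must be strictly increasing within [0, 2*pi)")
  n_detectors <- as.integer(n_detectors)
  if (n_detectors < 2 || det_pitch <= 0)
    stop_contract("need >= 2 detectors with positive pitch")
  span <- n_detectors * det_pitch / 2
  if (!is.null(object_radius) && object_radius > span)
    warning(sprintf("detector half-span %.3g cm does not cover object radius %.3g cm",
                    span, object_radius))
  structure(list(beam = "parallel", angles = angles, n_detectors = n_detectors,
                 det_pitch = det_pitch), class = "scan_geometry")
}

#' Detector element coordinates
#' @param geom a `scan_geometry`.
#' @return numeric vector of detector coordinates (cm), centered on the axis.
#' @export
detector_coords <- function(geom)
  (seq_len(geom$n_detectors) - 1 - (geom$n_detectors - 1) / 2) * geom$det_pitch

#' X-ray source spectrum
#'
#' Discrete spectrum of (energy, weight) bins; weights are normalized to sum
#' to one. A single bin is a monochromatic source.
#'
#' @param energies energies in keV.
#' @param weights non-negative relative weights (default equal).
#' @return object of class `xray_spectrum`.
#' @export
xray_spectrum <- function(energies, weights = rep(1, length(energies))) {
  energies <- as.numeric(energies); weights <- as.numeric(weights)
  if (length(energies) != length(weights) || !length(energies))
    stop_contract("energies and weights must be non-empty and of equal length")
  if (any(weights < 0) || sum(weights) <= 0)
    stop_contract("spectrum weights must be non-negative with positive sum")
  structure(list(energies = energies, weights = weights / sum(weights)),
            class = "xray_spectrum")
}

#' @rdname xray_spectrum
#' @param e energy in keV.
#' @export
monochromatic <- function(e) xray_spectrum(e, 1)

is_monochromatic <- function(spec) length(spec$energies) == 1L

new_sinogram_raw <- function(counts, I0, air_scan, dark, geom, spectrum, provenance) {
  structure(list(counts = counts, I0 = I0, air_scan = air_scan, dark = dark,
                 geometry = geom, spectrum = spectrum, provenance = provenance),
            class = "sinogram_raw")
}

new_sinogram_ready <- function(values, geom, energy = NULL, spectrum = NULL,
                               provenance = list()) {
  if (!length(provenance)) stop_contract("a ready sinogram requires a provenance chain")
  structure(list(values = values, geometry = geom, energy = energy,
                 spectrum = spectrum, provenance = provenance),
            class = "sinogram_ready")
}

prov_step <- function(op, ...) c(list(op = op), list(...))

#' @export
print.sinogram_ready <- function(x, ...) {
  cat(sprintf("<sinogram_ready %d angles x %d detectors%s  [%s]>\n",
              length(x$geometry$angles), x$geometry$n_detectors,
              if (!is.null(x$energy)) sprintf("  e=%g keV", x$energy) else "",
              paste(vapply(x$provenance, `[[`, "", "op"), collapse = " -> ")))
  invisible(x)
}

#' @export
print.sinogram_raw <- function(x, ...) {
  cat(sprintf("<sinogram_raw %d angles x %d detectors  I0=%g  %d-bin spectrum>\n",
              length(x$geometry$angles), x$geometry$n_detectors, x$I0,
              length(x$spectrum$energies)))
  invisible(x)
}

## ------------------------------------------------------- analytic projector

## ray/ellipse chord interval in ray parameter t; NULL when the ray misses
ellipse_chord <- function(p, ox, oy, dx, dy) {
  ca <- cos(p$angle); sa <- sin(p$angle)
  rx <- ox - p$center[1]; ry <- oy - p$center[2]
  ou <- rx * ca + ry * sa;  ov <- -rx * sa + ry * ca
  du <- dx * ca + dy * sa;  dv <- -dx * sa + dy * ca
  a <- (du / p$semi_axes[1])^2 + (dv / p$semi_axes[2])^2
  b <- 2 * (ou * du / p$semi_axes[1]^2 + ov * dv / p$semi_axes[2]^2)
  cc <- (ou / p$semi_axes[1])^2 + (ov / p$semi_axes[2])^2 - 1
  disc <- b^2 - 4 * a * cc
  if (a == 0 || disc <= 0) return(NULL)
  sq <- sqrt(disc)
  sort(c((-b - sq) / (2 * a), (-b + sq) / (2 * a)))
}

#' Analytic projection of a vector phantom
#'
#' Exact monochromatic line integrals of an ellipse phantom: for every ray
#' the union of primitive chord intervals is partitioned at interval
#' endpoints, the topmost primitive (painter's order) owns each segment, and
#' the segment length times `weight * mu(material, e)` is accumulated. There
#' is no discretization error, which makes this the oracle the voxel-driven
#' projector is validated against.
#'
#' @param v a `vector_model` of ellipse primitives.
#' @param dict a `material_dictionary`.
#' @param geom a `scan_geometry`.
#' @param e monochromatic energy in keV.
#' @return a `sinogram_ready` of line integrals tagged with `e`.
#' @export
project_vector <- function(v, dict, geom, e) {
  for (p in v$primitives)
    if (p$shape != "ellipse")
      stop_contract("analytic projection supports ellipse primitives only (got '%s')",
                    p$shape)
  check_materials_known(v, dict)
  mus <- vapply(v$primitives, function(p) p$weight * mu_of(dict, p$material, e),
                numeric(1))
  dets <- detector_coords(geom)
  na <- length(geom$angles); nd <- length(dets)
  vals <- matrix(0, na, nd)
  np <- length(v$primitives)
  if (np) {
    for (a in seq_len(na)) {
      ct <- cos(geom$angles[a]); st <- sin(geom$angles[a])
      dx <- -st; dy <- ct
      for (d in seq_len(nd)) {
        ox <- dets[d] * ct; oy <- dets[d] * st
        ints <- vector("list", np)
        hit <- logical(np)
        for (k in seq_len(np)) {
          ch <- ellipse_chord(v$primitives[[k]], ox, oy, dx, dy)
          if (!is.null(ch)) { ints[[k]] <- ch; hit[k] <- TRUE }
        }
        if (!any(hit)) next
        kh <- which(hit)
        if (length(kh) == 1L) {
          vals[a, d] <- diff(ints[[kh]]) * mus[kh]
        } else {
          cuts <- sort(unique(unlist(ints[kh])))
          mid <- (cuts[-1] + cuts[-length(cuts)]) / 2
          len <- diff(cuts)
          seg_mu <- numeric(length(mid))
          for (k in kh) {   # ascending: later primitives overwrite
            inside <- mid >= ints[[k]][1] & mid <= ints[[k]][2]
            seg_mu[inside] <- mus[k]
          }
          vals[a, d] <- sum(len * seg_mu)
        }
      }
    }
  }
  new_sinogram_ready(vals, geom, energy = e, spectrum = monochromatic(e),
                     provenance = list(prov_step("V2P", energy_keV = e)))
}

## ------------------------------------------------------ voxel-driven scanner

## channel-wise bilinear upsampling of a weight grid by an integer factor,
## preserving the physical extent (pitch / s); the anti-inverse-crime
## resolution mismatch between phantom and reconstruction grids
upsample_weights <- function(w, s) {
  if (s == 1L) return(w)
  n1 <- w$sides[1]; n2 <- w$sides[2]; nm <- length(w$materials)
  m1 <- n1 * s; m2 <- n2 * s
  ci <- ((seq_len(m1) - 0.5) / s) - 0.5   # continuous source index, axis 1
  cj <- ((seq_len(m2) - 0.5) / s) - 0.5
  f1 <- pmin(pmax(floor(ci), 0), n1 - 2); a1 <- pmin(pmax(ci - f1, 0), 1)
  f2 <- pmin(pmax(floor(cj), 0), n2 - 2); a2 <- pmin(pmax(cj - f2, 0), 1)
  out <- array(0, dim = c(m1, m2, 1, nm))
  for (m in seq_len(nm)) {
    src <- w$values[, , 1, m]
    v00 <- src[cbind(rep(f1 + 1, m2), rep(f2 + 1, each = m1))]
    v10 <- src[cbind(rep(f1 + 2, m2), rep(f2 + 1, each = m1))]
    v01 <- src[cbind(rep(f1 + 1, m2), rep(f2 + 2, each = m1))]
    v11 <- src[cbind(rep(f1 + 2, m2), rep(f2 + 2, each = m1))]
    wa <- rep(a1, m2); wb <- rep(a2, each = m1)
    out[, , 1, m] <- matrix((1 - wa) * (1 - wb) * v00 + wa * (1 - wb) * v10 +
                            (1 - wa) * wb * v01 + wa * wb * v11, m1, m2)
  }
  structure(list(values = out, sides = c(m1, m2, 1L), pitch = w$pitch / c(s, s, 1),
                 cs = w$cs, materials = w$materials, domain = "weights"),
            class = "material_weight_mask")
}

#' Voxel-driven polychromatic projection of a weight phantom
#'
#' Ray-driven line integration with exact voxel-intersection (Siddon) chord
#' lengths on a bilinearly upsampled copy of the phantom grid. Per ray the
#' per-material path lengths `L_i` are accumulated once; expected photon
#' counts follow Beer-Lambert under the spectrum:
#' `counts = dark + I0 * sum_b S(e_b) * exp(-sum_i L_i mu_i(e_b))`.
#' `supersample >= 2` projects on a finer grid than the phantom raster,
#' avoiding the inverse crime of testing reconstruction on data generated at
#' the very same discretization.
#'
#' @param w a 2D `material_weight_mask` (n3 = 1).
#' @param dict a `material_dictionary`.
#' @param geom a `scan_geometry`.
#' @param spectrum an `xray_spectrum`; every bin must lie inside the
#'   dictionary's tabulated span.
#' @param I0 photons per detector element in the unattenuated beam.
#' @param supersample integer >= 1 phantom upsampling factor (default 2).
#' @param dark constant dark-field offset in counts (default 0).
#' @return a `sinogram_raw` of noise-free expected counts with air scan.
#' @export
project_weights <- function(w, dict, geom, spectrum, I0, supersample = 2L, dark = 0) {
  if (w$sides[3] != 1L)
    stop_contract("voxel-driven projection is implemented for 2D slices (n3 = 1)")
  s <- as.integer(supersample)
  if (s < 1) stop_contract("supersample must be an integer >= 1")
  wu <- upsample_weights(w, s)
  mu_tab <- vapply(spectrum$energies, function(e) mu_of(dict, wu$materials, e),
                   numeric(length(wu$materials)))
  mu_tab <- matrix(mu_tab, nrow = length(wu$materials))
  dets <- detector_coords(geom)
  L <- cpp_siddon_paths(as.vector(wu$values), wu$sides[1], wu$sides[2],
                        length(wu$materials), wu$pitch[1], wu$pitch[2],
                        geom$angles, dets)
  atten <- exp(-L %*% mu_tab)                       # rays x bins
  counts <- dark + I0 * as.vector(atten %*% spectrum$weights)
  counts <- matrix(counts, length(geom$angles), length(dets), byrow = TRUE)
  new_sinogram_raw(counts, I0 = I0,
                   air_scan = matrix(dark + I0, length(geom$angles), length(dets)),
                   dark = dark, geom = geom, spectrum = spectrum,
                   provenance = list(prov_step("W2P", supersample = s, I0 = I0,
                                               dark = dark, noise = "none")))
}

#' Poisson photon noise
#'
#' Replaces every expected count by a Poisson draw with that mean, through a
#' dedicated seeded random stream (low-dose / photon-starvation model). A
#' sinogram whose provenance already records noise is refused unless
#' `force = TRUE`.
#'
#' @param p a `sinogram_raw` of noise-free expected counts.
#' @param seed integer seed (required; recorded in provenance).
#' @param force re-noise an already-noised sinogram.
#' @return a `sinogram_raw` with sampled counts.
#' @export
add_poisson_noise <- function(p, seed, force = FALSE) {
  noised <- any(vapply(p$provenance, function(s) identical(s$op, "NOI"), logical(1)))
  if (noised && !force)
    stop_contract("sinogram provenance already records Poisson noise; use force = TRUE")
  out <- p
  out$counts[] <- with_seed(seed, rpois(length(p$counts), lambda = p$counts))
  out$provenance <- c(p$provenance, list(prov_step("NOI", model = "poisson", seed = seed)))
  out
}

sino_values <- function(p) if (inherits(p, "sinogram_raw")) p$counts else p$values

sino_replace <- function(p, vals, keep) {
  out <- p
  if (inherits(p, "sinogram_raw")) {
    out$counts <- vals[keep, , drop = FALSE]
    if (is.matrix(out$air_scan)) out$air_scan <- out$air_scan[keep, , drop = FALSE]
  } else out$values <- vals[keep, , drop = FALSE]
  out$geometry$angles <- p$geometry$angles[keep]
  out
}

#' Deterministic angle subsampling (sparse / limited angle)
#'
#' Sparse mode keeps every `keep_every_k`-th angle starting at index 0
#' (`ceil(N / k)` angles). Limited-angle mode keeps angles inside the closed
#' `angle_range`. The geometry's angle list is updated accordingly.
#'
#' @param p a `sinogram_raw` or `sinogram_ready`.
#' @param keep_every_k integer stride `k >= 1`.
#' @param angle_range numeric `c(lo, hi)` in radians (closed interval).
#' @return a sinogram of the same class with reduced angles.
#' @export
subsample_angles_deterministic <- function(p, keep_every_k = NULL, angle_range = NULL) {
  ang <- p$geometry$angles
  if (!is.null(keep_every_k)) {
    k <- as.integer(keep_every_k)
    if (k < 1) stop_contract("keep_every_k must be >= 1")
    keep <- seq(1, length(ang), by = k)
    rec <- prov_step("DSS", mode = "sparse", keep_every_k = k)
  } else if (!is.null(angle_range)) {
    keep <- which(ang >= angle_range[1] & ang <= angle_range[2])
    rec <- prov_step("DSS", mode = "limited_angle", range = angle_range)
  } else stop_contract("give keep_every_k or angle_range")
  if (!length(keep)) stop_contract("angle subsampling removed every projection")
  out <- sino_replace(p, sino_values(p), keep)
  out$provenance <- c(p$provenance, list(rec))
  out
}

#' Randomized angle subsampling (any-time CT)
#'
#' Draws `m` distinct angle indices without replacement through a seeded
#' stream; the surviving angles stay in ascending order.
#'
#' @param p a `sinogram_raw` or `sinogram_ready`.
#' @param m number of angles to keep, `1 <= m <= N`.
#' @param seed integer seed (recorded in provenance).
#' @return a sinogram of the same class with `m` angles.
#' @export
subsample_angles_random <- function(p, m, seed) {
  n <- length(p$geometry$angles)
  m <- as.integer(m)
  if (m < 1 || m > n) stop_contract("m must lie in [1, %d]", n)
  keep <- sort(with_seed(seed, sample.int(n, m)))
  out <- sino_replace(p, sino_values(p), keep)
  out$provenance <- c(p$provenance, list(prov_step("RSS", m = m, seed = seed)))
  out
}

#' Log-normalize raw counts to line integrals
#'
#' `value = -log(max(counts - dark, count_floor) / (air_scan - dark))`. The
#' photon-count floor (default 1) guards the logarithm against zero counts;
#' the number of floored elements is recorded in provenance.
#'
#' @param p a `sinogram_raw`.
#' @param count_floor minimum accepted net count (default 1 photon).
#' @return a `sinogram_ready`; monochromatic inputs keep their energy tag.
#' @export
log_normalize <- function(p, count_floor = 1) {
  air_net <- p$air_scan - p$dark
  if (any(air_net <= 0)) stop_contract("air scan must exceed the dark scan everywhere")
  net <- p$counts - p$dark
  floored <- sum(net < count_floor)
  net <- pmax(net, count_floor)
  vals <- -log(net / air_net)
  new_sinogram_ready(vals, p$geometry,
                     energy = if (is_monochromatic(p$spectrum)) p$spectrum$energies else NULL,
                     spectrum = p$spectrum,
                     provenance = c(p$provenance,
                                    list(prov_step("P2P", step = "log_normalize",
                                                   count_floor = count_floor,
                                                   floored_elements = floored))))
}

#' Water (beam-hardening) correction
#'
#' Builds the polychromatic water calibration curve
#' `q(L) = -log(sum_b S(e_b) exp(-mu_w(e_b) L))` on a path-length grid,
#' inverts it monotonically by interpolation, and maps every sinogram value
#' `q` to `mu_w(e_ref) * q^{-1}(q)` - the classic water correction that makes
#' water paths behave as at the single reference energy. Values beyond
#' `q(L_max)` are clamped and counted in provenance.
#'
#' @param p a `sinogram_ready` produced under `spectrum`.
#' @param dict a `material_dictionary` (must contain water).
#' @param e_ref reference energy in keV.
#' @param spectrum the acquisition `xray_spectrum`; defaults to the one the
#'   sinogram carries.
#' @param L_max calibration path-length span (cm); default: detector span.
#' @param n_grid calibration grid size (default 4096).
#' @return a `sinogram_ready` tagged with `e_ref`.
#' @export
water_correct <- function(p, dict, e_ref, spectrum = NULL,
                          L_max = NULL, n_grid = 4096L) {
  spectrum <- spectrum %||% p$spectrum
  if (is.null(spectrum)) stop_contract("the acquisition spectrum is required")
  mu_w <- vapply(spectrum$energies, function(e) mu_of(dict, "water", e), numeric(1))
  qcurve <- function(L) -log(as.vector(exp(-outer(L, mu_w)) %*% spectrum$weights))
  if (is.null(L_max)) {
    ## detector span, extended until the calibration curve covers the data
    ## (highly attenuating inclusions map to long water-equivalent paths)
    L_max <- p$geometry$n_detectors * p$geometry$det_pitch
    vmax <- max(p$values, 0)
    for (i in 1:8) {
      if (qcurve(L_max) >= vmax) break
      L_max <- 2 * L_max
    }
  }
  Lg <- seq(0, L_max, length.out = n_grid)
  qg <- qcurve(Lg)
  clamped <- sum(p$values > qg[n_grid])
  x <- pmin(pmax(p$values, 0), qg[n_grid])
  Lhat <- approx(qg, Lg, xout = as.vector(x))$y
  out_vals <- matrix(mu_of(dict, "water", e_ref) * Lhat, nrow(p$values), ncol(p$values))
  new_sinogram_ready(out_vals, p$geometry, energy = e_ref, spectrum = spectrum,
                     provenance = c(p$provenance,
                                    list(prov_step("BHC", method = "water_correction",
                                                   e_ref_keV = e_ref, L_max = L_max,
                                                   n_grid = n_grid,
                                                   clamped_elements = clamped))))
}
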