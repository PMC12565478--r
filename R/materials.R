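## Digital object model: material dictionaries, vector phantoms, voxelization,
## weight/segmentation masks, HU <-> LAC conversion, windowing, soft-threshold
## material decomposition and object composition.

#' Load a material dictionary
#'
#' A material dictionary maps material identifiers to tables of
#' (energy keV, linear attenuation coefficient cm^-1) pairs. The reserved
#' identifiers `"water"` and `"air"` must be present: they anchor the
#' Hounsfield scale. The dictionary shipped with the package carries seven
#' reference materials (air, lung, water, pancreas, skull, aluminum,
#' titanium) with tabulated values at 80 and 120 keV and a synthetic log-log
#' extension over 20-150 keV for spectrum integration.
#'
#' @param path JSON file `{meta: ..., materials: {id: [[keV, cm^-1], ...]}}`;
#'   default: the shipped dictionary.
#' @return an object of class `material_dictionary`.
#' @export
material_dictionary <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "materials_ct_synthetic.json", package = "vctbench")
  raw <- read_json_file(path)
  entries <- lapply(raw$materials, function(tab) {
    m <- if (is.matrix(tab)) matrix(as.numeric(tab), ncol = 2)
         else matrix(as.numeric(unlist(tab)), ncol = 2, byrow = TRUE)
    colnames(m) <- c("energy_keV", "lac_cm1")
    m[order(m[, 1]), , drop = FALSE]
  })
  dict <- structure(list(entries = entries, meta = raw$meta, source = path),
                    class = "material_dictionary")
  validate_dictionary(dict)
  dict
}

validate_dictionary <- function(dict) {
  ids <- names(dict$entries)
  for (req in c("water", "air"))
    if (!req %in% ids) stop_contract("material dictionary must contain '%s'", req)
  for (id in ids) {
    tab <- dict$entries[[id]]
    if (is.unsorted(tab[, 1], strictly = TRUE))
      stop_contract("energy grid for '%s' must be strictly ascending", id)
    lo <- if (id == "air") 0 else .Machine$double.xmin
    if (any(tab[, 2] < lo) || (id != "air" && any(tab[, 2] <= 0)))
      stop_contract("LAC values for '%s' must be strictly positive", id)
  }
  invisible(dict)
}

#' @export
print.material_dictionary <- function(x, ...) {
  cat(sprintf("<material_dictionary: %s>\n", paste(names(x$entries), collapse = ", ")))
  invisible(x)
}

#' Material list of a dictionary
#' @param dict a `material_dictionary`.
#' @return character vector of material identifiers.
#' @export
materials <- function(dict) names(dict$entries)

#' Tabulated energy span of a material
#' @param dict a `material_dictionary`.
#' @param material material identifier.
#' @return numeric `c(min, max)` in keV.
#' @export
energy_span <- function(dict, material) {
  tab <- dict$entries[[material]]
  if (is.null(tab)) stop_contract("unknown material '%s'", material)
  range(tab[, 1])
}

#' Linear attenuation coefficient lookup
#'
#' Off-grid energies are interpolated log-linearly (linear in
#' `log(mu)` against `log(e)`), which is monotone between grid points and
#' matches the physics-motivated power-law decay of attenuation with energy.
#'
#' @param dict a `material_dictionary`.
#' @param material material identifier (vectorized).
#' @param e energy in keV (scalar).
#' @return LAC in cm^-1 (vector along `material`).
#' @export
mu_of <- function(dict, material, e) {
  vapply(material, function(m) {
    tab <- dict$entries[[m]]
    if (is.null(tab)) stop_contract("unknown material '%s'", m)
    sp <- range(tab[, 1])
    if (e < sp[1] || e > sp[2])
      stop_contract("energy %g keV outside tabulated span [%g, %g] of '%s'",
                    e, sp[1], sp[2], m)
    if (any(tab[, 2] == 0)) {          # air may tabulate exact zeros
      return(approx(tab[, 1], tab[, 2], xout = e)$y)
    }
    exp(approx(log(tab[, 1]), log(tab[, 2]), xout = log(e))$y)
  }, numeric(1), USE.NAMES = FALSE)
}

## ---------------------------------------------------------------- phantoms

#' Vector phantom model
#'
#' An ordered list of ellipse/ellipsoid primitives with material labels.
#' Later primitives overwrite earlier ones where they overlap (painter's
#' order). Use [vm_ellipse()] to build 2D primitives.
#'
#' @param primitives list of primitive lists (see [vm_ellipse()]).
#' @param cs the phantom coordinate system.
#' @return object of class `vector_model`.
#' @export
vector_model <- function(primitives = list(), cs = coord_sys(id = "phantom")) {
  for (p in primitives) {
    if (!p$shape %in% c("ellipse", "ellipsoid"))
      stop_contract("unsupported primitive shape '%s'", p$shape)
    if (any(p$semi_axes <= 0)) stop_contract("semi-axes must be strictly positive")
    if (p$weight < 0 || p$weight > 1) stop_contract("primitive weight must lie in [0,1]")
  }
  structure(list(primitives = primitives, cs = cs), class = "vector_model")
}

#' @rdname vector_model
#' @param center 2- or 3-vector, primitive center in phantom coordinates (cm).
#' @param semi_axes 2- or 3-vector of semi-axis lengths (cm).
#' @param angle in-plane rotation of the primitive in radians.
#' @param material material identifier.
#' @param weight material weight carried by the primitive, in `[0, 1]`.
#' @export
vm_ellipse <- function(center, semi_axes, material, angle = 0, weight = 1) {
  center <- c(as.numeric(center), 0)[1:3]
  semi_axes <- c(as.numeric(semi_axes), Inf)[1:3]  # ellipse = z-invariant
  list(shape = "ellipse", center = center, semi_axes = semi_axes,
       angle = angle, material = material, weight = weight)
}

## signed "inside" test for a primitive at points (m x 3, phantom coords)
prim_inside <- function(p, pts) {
  d <- sweep(pts, 2, p$center, `-`)
  ca <- cos(p$angle); sa <- sin(p$angle)
  u <- d[, 1] * ca + d[, 2] * sa
  v <- -d[, 1] * sa + d[, 2] * ca
  q <- (u / p$semi_axes[1])^2 + (v / p$semi_axes[2])^2
  if (is.finite(p$semi_axes[3])) q <- q + (d[, 3] / p$semi_axes[3])^2
  q <= 1
}

#' Serialize / load a vector model as JSON
#' @param v a `vector_model`.
#' @param path file path.
#' @export
write_vector_model <- function(v, path) {
  prims <- lapply(v$primitives, function(p)
    list(shape = p$shape, center = p$center, semi_axes = p$semi_axes,
         angle = p$angle, material = p$material, weight = p$weight))
  write_json_file(list(cs_id = v$cs$id, primitives = prims), path)
}

#' @rdname write_vector_model
#' @export
read_vector_model <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  prims <- lapply(raw$primitives, function(p) {
    p$center <- as.numeric(unlist(p$center))
    p$semi_axes <- as.numeric(unlist(p$semi_axes))
    p
  })
  vector_model(prims, cs = coord_sys(id = raw$cs_id))
}

check_materials_known <- function(v, dict) {
  for (p in v$primitives)
    if (!p$material %in% materials(dict))
      stop_contract("unknown material id '%s' in vector model", p$material)
}

#' Voxelize a vector model into a material weight mask
#'
#' Per-voxel weight of a material is the fraction of the voxel area covered
#' by primitives of that material (topmost in painter's order), scaled by the
#' primitive weight, estimated by `subsample x subsample` sampling of voxel
#' interiors. Weights therefore sum to the voxel coverage, at most 1.
#'
#' @param v a `vector_model` (2D: slice rasters with n3 = 1).
#' @param dict a `material_dictionary`; every primitive material must exist.
#' @param sides integer 2- or 3-vector of raster sides.
#' @param pitch voxel pitch (cm).
#' @param subsample sampling density per axis (default 4).
#' @return a `material_weight_mask`: a `voxel_volume` whose `values` is an
#'   `n1 x n2 x n3 x n_materials` array with a `materials` field.
#'
#' @details The raster is centered on the model's coordinate origin: a
#' primitive at center `(0, 0)` sits in the middle of the raster, which is
#' also the rotation center used by the projector. The returned mask's
#' coordinate system is shifted accordingly so that voxel `(i, j, k)` keeps
#' coordinates `(i, j, k) * pitch` in its own system.
#' @export
voxelize_weights <- function(v, dict, sides, pitch, subsample = 4L) {
  check_materials_known(v, dict)
  sides <- norm_sides(sides)
  pitch <- rep(as.numeric(pitch), length.out = 3)
  s <- as.integer(subsample)
  if (s < 1) stop_contract("subsample must be >= 1")
  mats <- materials(dict)
  nm <- length(mats)
  nvox <- prod(sides)
  wt <- matrix(0, nvox, nm)
  if (length(v$primitives)) {
    offs <- ((seq_len(s) - 0.5) / s - 0.5)  # subcell centers in [-0.5, 0.5)
    grid2 <- expand.grid(ox = offs, oy = offs)
    vox <- centered_raster_points(sides, pitch)
    top <- matrix(0L, nvox, nrow(grid2))      # topmost primitive per sample
    for (g in seq_len(nrow(grid2))) {
      pts <- vox
      pts[, 1] <- pts[, 1] + grid2$ox[g] * pitch[1]
      pts[, 2] <- pts[, 2] + grid2$oy[g] * pitch[2]
      for (k in seq_along(v$primitives)) {
        ins <- prim_inside(v$primitives[[k]], pts)
        top[ins, g] <- k
      }
    }
    for (k in seq_along(v$primitives)) {
      p <- v$primitives[[k]]
      cov <- rowMeans(top == k) * p$weight
      mi <- match(p$material, mats)
      wt[, mi] <- wt[, mi] + cov
    }
  }
  structure(list(values = array(wt, c(sides, nm)), sides = sides, pitch = pitch,
                 cs = raster_cs(v$cs, sides, pitch),
                 materials = mats, domain = "weights"),
            class = c("material_weight_mask"))
}

## voxel centers of a raster centered on the model origin, model coordinates
centered_raster_points <- function(sides, pitch) {
  idx <- as.matrix(expand.grid(i = 0:(sides[1] - 1), j = 0:(sides[2] - 1),
                               k = 0:(sides[3] - 1)))
  sweep(sweep(idx, 2, (sides - 1) / 2, `-`), 2, pitch, `*`)
}

## CS of a voxelized raster: origin shifted so index*pitch coordinates hold
raster_cs <- function(model_cs, sides, pitch) {
  rc <- (sides - 1) / 2 * pitch
  coord_sys(origin = model_cs$origin - as.vector(model_cs$basis %*% rc),
            basis = model_cs$basis, id = paste0(model_cs$id, ":raster"))
}

#' @export
print.material_weight_mask <- function(x, ...) {
  cat(sprintf("<material_weight_mask %s  %d materials  pitch %s cm>\n",
              paste(x$sides, collapse = "x"), length(x$materials),
              paste(signif(x$pitch, 4), collapse = "x")))
  invisible(x)
}

#' Voxelize a vector model into a segmentation mask
#'
#' Labels each voxel with the material of the topmost primitive covering the
#' voxel center; `0` is the background label.
#'
#' @inheritParams voxelize_weights
#' @return a `segmentation_mask`: integer-labelled `voxel_volume` with a
#'   `labels` field mapping label index to material id.
#' @export
voxelize_seg <- function(v, dict, sides, pitch) {
  check_materials_known(v, dict)
  sides <- norm_sides(sides)
  pitch <- rep(as.numeric(pitch), length.out = 3)
  mats <- materials(dict)
  lab <- integer(prod(sides))
  if (length(v$primitives)) {
    vox <- centered_raster_points(sides, pitch)
    for (k in seq_along(v$primitives)) {
      p <- v$primitives[[k]]
      ins <- prim_inside(p, vox)
      lab[ins] <- match(p$material, mats)
    }
  }
  structure(list(values = array(lab, sides), sides = sides, pitch = pitch,
                 cs = raster_cs(v$cs, sides, pitch),
                 labels = mats, domain = "segmentation"),
            class = "segmentation_mask")
}

#' One-hot material weights from a segmentation mask
#'
#' Every labelled voxel receives weight 1 on its material channel; background
#' (label 0) and sentinel voxels map to the all-zero weight vector.
#'
#' @param s a `segmentation_mask`.
#' @return a `material_weight_mask` over the same material list.
#' @export
weights_from_seg <- function(s) {
  mats <- s$labels
  nm <- length(mats)
  lab <- as.vector(s$values)
  bad <- !is.na(lab) & (lab < 0 | lab > nm)
  if (any(bad)) stop_contract("segmentation contains labels outside the dictionary")
  wt <- matrix(0, length(lab), nm)
  for (k in seq_len(nm)) wt[!is.na(lab) & lab == k, k] <- 1
  structure(list(values = array(wt, c(s$sides, nm)),
                 sides = s$sides, pitch = s$pitch, cs = s$cs,
                 materials = mats, domain = "weights"),
            class = "material_weight_mask")
}

#' Synthesize a LAC volume from material weights
#'
#' `r(x) = sum_i w_i(x) * mu_i(e)`: linear in the weights.
#'
#' @param w a `material_weight_mask`.
#' @param dict the `material_dictionary` the weights refer to.
#' @param e energy in keV; must lie inside every material's tabulated span.
#' @return `voxel_volume` of LAC (cm^-1) carrying an `energy` attribute.
#' @export
lac_from_weights <- function(w, dict, e) {
  mu <- mu_of(dict, w$materials, e)
  nm <- length(w$materials)
  flat <- matrix(w$values, ncol = nm)
  r <- as.vector(flat %*% mu)
  out <- voxel_volume(array(r, w$sides), pitch = w$pitch, cs = w$cs, domain = "lac")
  attr(out, "energy") <- e
  out
}

## reference LACs for the HU scale; errors on a degenerate reference
hu_refs <- function(dict, e, convention) {
  mu_w <- mu_of(dict, "water", e)
  mu_a <- mu_of(dict, "air", e)
  if (mu_w <= mu_a) stop_contract("degenerate HU reference: mu_water <= mu_air at %g keV", e)
  den <- if (convention == "air_ref") mu_w - mu_a else mu_w
  list(mu_w = mu_w, mu_a = mu_a, den = den)
}

#' Convert LAC to Hounsfield units
#'
#' `HU = 1000 * (mu - mu_water) / d` with `d = mu_water - mu_air` for the
#' air-referenced convention and `d = mu_water` for the vacuum-referenced
#' convention. Water maps to exactly 0 under both conventions and air to
#' exactly -1000 under `air_ref`. HU values are energy-dependent: the
#' conversion energy and convention are attached to the result and must be
#' chosen explicitly.
#'
#' @param r LAC `voxel_volume` (cm^-1), or a bare numeric vector.
#' @param dict a `material_dictionary` supplying the water/air references.
#' @param e energy in keV.
#' @param convention `"air_ref"` or `"vac_ref"`.
#' @return HU volume (or numeric vector) with `energy` and `convention`
#'   attributes.
#' @export
hu_from_lac <- function(r, dict, e, convention = c("air_ref", "vac_ref")) {
  convention <- match.arg(convention)
  refs <- hu_refs(dict, e, convention)
  conv <- function(mu) 1000 * (mu - refs$mu_w) / refs$den
  if (is.numeric(r)) return(conv(r))
  out <- voxel_volume(conv(r$values), pitch = r$pitch, cs = r$cs, domain = "hu")
  attr(out, "energy") <- e
  attr(out, "convention") <- convention
  attr(out, "fov_radius") <- attr(r, "fov_radius")
  out
}

#' Convert Hounsfield units back to LAC
#'
#' The exact algebraic inverse of [hu_from_lac()]. With `dequantize = TRUE`
#' the HU values are treated as quantized integers and uniform `[0, 1)` noise
#' is added before inversion (seeded through a dedicated random stream), the
#' standard dequantization step when deriving phantoms from stored integer HU
#' volumes.
#'
#' @param h HU `voxel_volume` or numeric vector.
#' @inheritParams hu_from_lac
#' @param dequantize add seeded uniform `[0, 1)` noise before inversion.
#' @param seed integer seed, required when `dequantize = TRUE`.
#' @return LAC volume (or numeric vector) with an `energy` attribute.
#' @export
lac_from_hu <- function(h, dict, e, convention = c("air_ref", "vac_ref"),
                        dequantize = FALSE, seed = NULL) {
  convention <- match.arg(convention)
  refs <- hu_refs(dict, e, convention)
  vals <- if (is.numeric(h)) h else h$values
  if (dequantize) {
    vals <- with_seed(seed, vals + runif(length(vals))) # NA + noise stays NA
  }
  mu <- vals / 1000 * refs$den + refs$mu_w
  if (is.numeric(h)) return(mu)
  out <- voxel_volume(array(mu, h$sides), pitch = h$pitch, cs = h$cs, domain = "lac")
  attr(out, "energy") <- e
  out
}

#' HU display/normalization window
#' @param level window level l (HU).
#' @param width window width w (HU), strictly positive.
#' @return object of class `hu_window`.
#' @export
hu_window <- function(level, width) {
  if (!is.finite(width) || width <= 0) stop_contract("window width must be > 0")
  structure(list(level = level, width = width), class = "hu_window")
}

#' Window an HU volume to [0, 1]
#'
#' `i = clip((h - (l - w/2)) / w, 0, 1)`: monotone non-decreasing in `h`,
#' saturating at the window edges. Sentinels pass through.
#'
#' @param h HU `voxel_volume` or numeric vector.
#' @param w an `hu_window`.
#' @return windowed volume (domain `"windowed"`) or numeric vector in [0,1].
#' @export
apply_window <- function(h, w) {
  f <- function(x) clip01((x - (w$level - w$width / 2)) / w$width)
  if (is.numeric(h)) return(f(h))
  out <- voxel_volume(f(h$values), pitch = h$pitch, cs = h$cs, domain = "windowed")
  attr(out, "window") <- w
  attr(out, "fov_radius") <- attr(h, "fov_radius")
  out
}

#' Soft-threshold material decomposition of a LAC volume
#'
#' Piecewise-linear decomposition over materials ordered by ascending nominal
#' LAC at energy `e`. A voxel whose LAC equals a nominal value receives a
#' one-hot weight; between two adjacent nominal values the two weights
#' interpolate linearly and sum to 1; below the first / above the last value
#' the nearest material takes weight 1. The breakpoints are the nominal LACs
#' of the explicit, caller-supplied material sequence: published threshold
#' schemes are rarely detailed enough to reproduce, so nothing is inferred.
#'
#' @param r LAC `voxel_volume`.
#' @param dict a `material_dictionary`.
#' @param decomposition_materials character vector of material ids, e.g.
#'   `c("air", "water", "skull")`.
#' @param e energy in keV.
#' @return a `material_weight_mask` over the full dictionary material list.
#' @export
soft_threshold_decompose <- function(r, dict, decomposition_materials, e) {
  mus <- mu_of(dict, decomposition_materials, e)
  if (is.unsorted(mus, strictly = TRUE))
    stop_contract("decomposition materials must have strictly increasing LAC at %g keV", e)
  mats <- materials(dict)
  x <- as.vector(r$values)
  k <- length(mus)
  wt <- matrix(0, length(x), length(mats))
  idx <- findInterval(x, mus)                 # 0 .. k
  col_of <- match(decomposition_materials, mats)
  lo <- !is.na(x) & idx == 0
  hi <- !is.na(x) & idx == k
  wt[lo, col_of[1]] <- 1
  wt[hi, col_of[k]] <- 1
  mid <- !is.na(x) & idx > 0 & idx < k
  if (any(mid)) {
    i <- idx[mid]
    t <- (x[mid] - mus[i]) / (mus[i + 1] - mus[i])
    wt[cbind(which(mid), col_of[i])] <- 1 - t
    wt[cbind(which(mid), col_of[i + 1])] <-
      wt[cbind(which(mid), col_of[i + 1])] + t
  }
  structure(list(values = array(wt, c(r$sides, length(mats))),
                 sides = r$sides, pitch = r$pitch, cs = r$cs,
                 materials = mats, domain = "weights"),
            class = "material_weight_mask")
}

#' Insert an inclusion into a base phantom
#'
#' Resamples the inclusion segmentation into the base raster (nearest
#' neighbor, labels never blend) through the placement transform; labelled
#' inclusion voxels overwrite the base weights with a one-hot vector of the
#' inclusion material, all other voxels are untouched. The placement is
#' recorded on the result for provenance. A placement that maps the inclusion
#' entirely outside the base raster yields a warning and the unchanged base.
#'
#' @param base a `material_weight_mask`.
#' @param inclusion_seg a `segmentation_mask` of the inclusion; its labels
#'   must exist in the base's material list.
#' @param placement `rigid_transform` from the inclusion CS to the base CS
#'   (default identity).
#' @return the combined `material_weight_mask` with a `placement` attribute.
#' @export
compose_objects <- function(base, inclusion_seg, placement = NULL) {
  if (is.null(placement))
    placement <- rigid_transform(source = inclusion_seg$cs$id, target = base$cs$id)
  used <- inclusion_seg$labels[sort(unique(inclusion_seg$values[inclusion_seg$values > 0]))]
  miss <- setdiff(used, base$materials)
  if (length(miss))
    stop_contract("inclusion material(s) %s missing from base dictionary",
                  paste(miss, collapse = ", "))
  src <- voxel_volume(inclusion_seg$values + 0, pitch = inclusion_seg$pitch,
                      cs = inclusion_seg$cs, domain = "segmentation")
  res <- resample(src, base$sides, base$pitch, target_cs = base$cs,
                  transform = placement, interpolation = "nearest")
  lab <- res$values
  hit <- !is.na(lab) & lab > 0
  if (!any(hit)) {
    warning("inclusion placement maps entirely outside the base raster; base unchanged")
    out <- base
  } else {
    out <- base
    nm <- length(base$materials)
    flat <- matrix(out$values, ncol = nm)
    hm <- which(as.vector(hit))
    flat[hm, ] <- 0
    cols <- match(inclusion_seg$labels[lab[hit]], base$materials)
    flat[cbind(hm, cols)] <- 1
    out$values <- array(flat, dim = dim(base$values))
  }
  attr(out, "placement") <- placement
  attr(out, "inclusion_support") <- array(as.numeric(hit), base$sides)
  out
}
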