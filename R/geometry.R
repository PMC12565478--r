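## Cartesian coordinate systems, rigid transforms, voxel rasters and masks.
## Conventions: 0-based voxel coordinates, half-open rasters [0, n_i), a voxel
## integer coordinate names the voxel CENTER, all lengths in cm. 2D slices are
## volumes with n3 = 1. The missing-value sentinel is NA/NaN for floating
## volumes and a reserved 0 / NA label for integer volumes.

ORTHO_TOL <- 1e-9

#' Cartesian coordinate system
#'
#' A coordinate system is an origin (a point in the global frame) plus three
#' orthonormal, right-handed basis vectors. A point with coordinates `q` in
#' this system sits at `origin + basis %*% q` in the global frame.
#'
#' @param origin numeric 3-vector, global-frame position of the origin (cm).
#' @param basis 3x3 matrix whose columns are the basis vectors.
#' @param id optional identifier string.
#' @return an object of class `coord_sys`.
#' @export
coord_sys <- function(origin = c(0, 0, 0), basis = diag(3), id = "cs") {
  origin <- as.numeric(origin)
  basis <- matrix(as.numeric(basis), 3, 3)
  if (length(origin) != 3) stop_contract("origin must be a 3-vector")
  gram <- crossprod(basis)
  if (max(abs(gram - diag(3))) > ORTHO_TOL)
    stop_contract("basis vectors must be orthonormal (tolerance %g)", ORTHO_TOL)
  e3 <- c(basis[2, 1] * basis[3, 2] - basis[3, 1] * basis[2, 2],
          basis[3, 1] * basis[1, 2] - basis[1, 1] * basis[3, 2],
          basis[1, 1] * basis[2, 2] - basis[2, 1] * basis[1, 2])
  if (max(abs(e3 - basis[, 3])) > ORTHO_TOL)
    stop_contract("basis must be right-handed: e3 = cross(e1, e2)")
  structure(list(origin = origin, basis = basis, id = id), class = "coord_sys")
}

#' Rigid transform between two coordinate systems
#'
#' Maps point coordinates expressed in the source system to coordinates in
#' the target system: `p_target = rotation %*% p_source + translation`.
#'
#' @param rotation 3x3 rotation matrix (orthonormal, determinant +1).
#' @param translation numeric 3-vector (cm).
#' @param source,target identifiers of the source and target systems.
#' @return an object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0),
                            source = "src", target = "tgt") {
  rotation <- matrix(as.numeric(rotation), 3, 3)
  translation <- as.numeric(translation)
  if (max(abs(crossprod(rotation) - diag(3))) > ORTHO_TOL ||
      abs(det(rotation) - 1) > ORTHO_TOL)
    stop_contract("rotation must be orthonormal with determinant +1")
  structure(list(rotation = rotation, translation = translation,
                 source = source, target = target),
            class = "rigid_transform")
}

#' @rdname rigid_transform
#' @param cs_id identifier used for both ends of the identity transform.
#' @export
transform_identity <- function(cs_id = "cs") {
  rigid_transform(diag(3), c(0, 0, 0), source = cs_id, target = cs_id)
}

#' Rotation about the third axis
#' @param theta angle in radians.
#' @keywords internal
rot_z <- function(theta) {
  matrix(c(cos(theta), sin(theta), 0,
           -sin(theta), cos(theta), 0,
           0, 0, 1), 3, 3)
}

#' Compose two rigid transforms
#'
#' `compose_transforms(outer, inner)` maps any point exactly as applying
#' `inner` first and `outer` second; the chain identifiers must match.
#'
#' @param outer,inner `rigid_transform` objects with
#'   `inner$target == outer$source`.
#' @return a `rigid_transform` from `inner$source` to `outer$target`.
#' @export
compose_transforms <- function(outer, inner) {
  if (!identical(inner$target, outer$source))
    stop_contract("transform chain mismatch: inner targets '%s' but outer sources '%s'",
                  inner$target, outer$source)
  rigid_transform(outer$rotation %*% inner$rotation,
                  as.vector(outer$rotation %*% inner$translation) + outer$translation,
                  source = inner$source, target = outer$target)
}

#' Invert a rigid transform
#' @param g a `rigid_transform`.
#' @return the inverse transform (target and source swapped).
#' @export
invert_transform <- function(g) {
  rt <- t(g$rotation)
  rigid_transform(rt, -as.vector(rt %*% g$translation),
                  source = g$target, target = g$source)
}

#' Apply a rigid transform to points
#' @param g a `rigid_transform`.
#' @param pts numeric matrix with one point per row (n x 3) or a 3-vector.
#' @return transformed points, same shape.
#' @export
apply_transform <- function(g, pts) {
  v <- is.null(dim(pts))
  p <- if (v) matrix(pts, 1, 3) else as.matrix(pts)
  out <- p %*% t(g$rotation) + matrix(g$translation, nrow(p), 3, byrow = TRUE)
  if (v) as.vector(out) else out
}

#' Voxel volume
#'
#' A raster of typed voxel values attached to a coordinate system. Voxel
#' `(i, j, k)` (0-based) has coordinates `(i*pitch1, j*pitch2, k*pitch3)` in
#' the attached system, naming the voxel center. The sentinel for "no
#' information" is `NA`/`NaN`; it never participates in arithmetic.
#'
#' @param values numeric or integer array; a matrix is promoted to an
#'   `n1 x n2 x 1` slice volume.
#' @param pitch per-axis voxel edge length (cm); scalar recycled.
#' @param cs a `coord_sys` (default: global frame).
#' @param domain free-form tag for the value domain, e.g. "lac", "hu".
#' @return an object of class `voxel_volume`.
#' @export
voxel_volume <- function(values, pitch = 1, cs = coord_sys(), domain = NULL) {
  if (is.matrix(values)) values <- array(values, dim = c(dim(values), 1L))
  if (length(dim(values)) != 3) stop_contract("values must be a 3D array (or a matrix slice)")
  pitch <- rep(as.numeric(pitch), length.out = 3)
  if (any(!is.finite(pitch)) || any(pitch <= 0))
    stop_contract("voxel pitch must be strictly positive")
  structure(list(values = values, sides = dim(values), pitch = pitch,
                 cs = cs, domain = domain),
            class = "voxel_volume")
}

#' @export
print.voxel_volume <- function(x, ...) {
  cat(sprintf("<voxel_volume %s  %s  pitch %s cm  cs '%s'%s>\n",
              paste(x$sides, collapse = "x"),
              x$domain %||% "untyped",
              paste(signif(x$pitch, 4), collapse = "x"),
              x$cs$id,
              if (anyNA(x$values)) sprintf("  %d sentinel", sum(is.na(x$values))) else ""))
  invisible(x)
}

#' Center of the raster in volume coordinates
#'
#' Reconstructions and phantoms rotate about this point: the midpoint of the
#' raster, `((n-1)/2) * pitch` per axis.
#' @param vol a `voxel_volume`.
#' @return numeric 3-vector in the volume's own coordinate system (cm).
#' @export
raster_center <- function(vol) (vol$sides - 1) / 2 * vol$pitch

#' World/CS coordinates of every voxel center
#' @param vol a `voxel_volume`.
#' @param frame `"cs"` for coordinates in the volume's own system, `"global"`
#'   for the global frame.
#' @return an `prod(sides) x 3` matrix, voxels in column-major raster order.
#' @export
voxel_centers <- function(vol, frame = c("cs", "global")) {
  frame <- match.arg(frame)
  n <- vol$sides
  idx <- as.matrix(expand.grid(i = 0:(n[1] - 1), j = 0:(n[2] - 1), k = 0:(n[3] - 1)))
  pts <- sweep(idx, 2, vol$pitch, `*`)
  if (frame == "global")
    pts <- pts %*% t(vol$cs$basis) + matrix(vol$cs$origin, nrow(pts), 3, byrow = TRUE)
  pts
}

#' Binary voxel mask
#'
#' @param values array/matrix of 0/1 (logical accepted).
#' @inheritParams voxel_volume
#' @return `binary_mask`, a `voxel_volume` subclass with values in {0, 1}.
#' @export
binary_mask <- function(values, pitch = 1, cs = coord_sys()) {
  values[] <- as.numeric(values != 0)
  v <- voxel_volume(values, pitch = pitch, cs = cs, domain = "mask")
  class(v) <- c("binary_mask", class(v))
  v
}

#' Mask algebra
#'
#' Voxelwise intersection / union of two masks on the same raster, and the
#' number of set voxels.
#' @param a,b `binary_mask` objects on identical rasters.
#' @return a `binary_mask` (or an integer count for [mask_count()]).
#' @export
mask_intersect <- function(a, b) {
  stopifnot(identical(a$sides, b$sides))
  m <- a; m$values <- a$values * b$values; m
}

#' @rdname mask_intersect
#' @export
mask_union <- function(a, b) {
  stopifnot(identical(a$sides, b$sides))
  m <- a; m$values <- pmax(a$values, b$values); m
}

#' @rdname mask_intersect
#' @export
mask_count <- function(a) sum(a$values != 0, na.rm = TRUE)

#' Erode a mask by a square structuring element
#'
#' In-plane erosion by `radius` voxels (Chebyshev metric): a voxel survives
#' when every voxel of its `(2r+1)^2` neighborhood is set. Used to build
#' interior regions free of partial-volume boundary voxels and to restrict
#' windowed metrics to fully-inside windows.
#'
#' @param mask a `binary_mask` (slice volume, n3 = 1).
#' @param radius non-negative integer.
#' @return eroded `binary_mask`.
#' @export
mask_erode <- function(mask, radius) {
  r <- as.integer(radius)
  if (r < 0) stop_contract("erosion radius must be >= 0")
  if (r == 0) return(mask)
  m <- mask$values[, , 1]
  n1 <- nrow(m); n2 <- ncol(m)
  out <- m
  for (dx in -r:r) for (dy in -r:r) {
    shifted <- matrix(0, n1, n2)
    xs <- max(1, 1 - dx):min(n1, n1 - dx)
    ys <- max(1, 1 - dy):min(n2, n2 - dy)
    shifted[xs, ys] <- m[xs + dx, ys + dy]
    out <- pmin(out, shifted)
  }
  binary_mask(out, pitch = mask$pitch, cs = mask$cs)
}

#' @rdname mask_erode
#' @export
mask_dilate <- function(mask, radius) {
  inv <- mask
  inv$values[] <- 1 - (mask$values != 0)
  er <- mask_erode(binary_mask(inv$values, pitch = mask$pitch, cs = mask$cs), radius)
  er$values[] <- 1 - er$values
  er
}

## continuous (0-based) fractional index of physical cs-coordinates
coords_to_index <- function(coords, pitch) sweep(coords, 2, pitch, `/`)

#' Resample a voxel volume into a target raster
#'
#' Maps every target voxel center through the inverse of `transform` into the
#' source volume's coordinate system and interpolates. Points outside the
#' source raster receive the sentinel `NA`. Linear interpolation is the
#' default for continuous-valued volumes; `"nearest"` must be used for label
#' volumes so classes never blend.
#'
#' @param src source `voxel_volume`.
#' @param target_sides integer 3-vector.
#' @param target_pitch per-axis pitch (cm), scalar recycled.
#' @param target_cs target `coord_sys`.
#' @param transform `rigid_transform` mapping source-CS coordinates to
#'   target-CS coordinates (default identity).
#' @param interpolation `"linear"` or `"nearest"`.
#' @return resampled `voxel_volume` carrying a `resample_record` attribute
#'   (the RES parameter record for provenance).
#' @export
resample <- function(src, target_sides, target_pitch,
                     target_cs = src$cs, transform = NULL,
                     interpolation = c("linear", "nearest")) {
  interpolation <- match.arg(interpolation)
  target_sides <- norm_sides(target_sides)
  target_pitch <- rep(as.numeric(target_pitch), length.out = 3)
  if (any(target_sides <= 0) || any(target_pitch <= 0))
    stop_contract("target sides and pitch must be strictly positive")
  if (is.null(transform))
    transform <- rigid_transform(source = src$cs$id, target = target_cs$id)

  n <- target_sides
  idx <- as.matrix(expand.grid(i = 0:(n[1] - 1), j = 0:(n[2] - 1), k = 0:(n[3] - 1)))
  tgt_pts <- sweep(idx, 2, target_pitch, `*`)
  src_pts <- apply_transform(invert_transform(transform), tgt_pts)
  ci <- coords_to_index(src_pts, src$pitch)
  vals <- interp_raster(src$values, ci, interpolation)
  out <- voxel_volume(array(vals, dim = n), pitch = target_pitch,
                      cs = target_cs, domain = src$domain)
  attr(out, "resample_record") <- list(
    op = "RES", interpolation = interpolation,
    source_sides = src$sides, source_pitch = src$pitch,
    target_sides = n, target_pitch = target_pitch,
    rotation = transform$rotation, translation = transform$translation)
  out
}

## trilinear / nearest interpolation at continuous 0-based indices; outside
## the raster (or touching a sentinel neighbor) -> NA
interp_raster <- function(arr, ci, interpolation) {
  n <- dim(arr)
  m <- nrow(ci)
  if (interpolation == "nearest") {
    r <- round(ci)
    ok <- r[, 1] >= 0 & r[, 1] <= n[1] - 1 &
          r[, 2] >= 0 & r[, 2] <= n[2] - 1 &
          r[, 3] >= 0 & r[, 3] <= n[3] - 1
    vals <- rep(NA_real_, m)
    if (any(ok)) vals[ok] <- arr[cbind(r[ok, 1] + 1, r[ok, 2] + 1, r[ok, 3] + 1)]
    return(vals)
  }
  f <- floor(ci)
  w <- ci - f
  ## degenerate axes (n_i = 1): collapse to plane 0
  for (ax in 1:3) if (n[ax] == 1) { f[, ax] <- 0; w[, ax] <- 0 }
  ok <- f[, 1] >= 0 & (f[, 1] + (w[, 1] > 0)) <= n[1] - 1 &
        f[, 2] >= 0 & (f[, 2] + (w[, 2] > 0)) <= n[2] - 1 &
        f[, 3] >= 0 & (f[, 3] + (w[, 3] > 0)) <= n[3] - 1
  vals <- rep(NA_real_, m)
  if (!any(ok)) return(vals)
  fo <- f[ok, , drop = FALSE]; wo <- w[ok, , drop = FALSE]
  acc <- numeric(sum(ok))
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    wt <- (if (dx) wo[, 1] else 1 - wo[, 1]) *
          (if (dy) wo[, 2] else 1 - wo[, 2]) *
          (if (dz) wo[, 3] else 1 - wo[, 3])
    ix <- pmin(fo[, 1] + dx, n[1] - 1) + 1
    iy <- pmin(fo[, 2] + dy, n[2] - 1) + 1
    iz <- pmin(fo[, 3] + dz, n[3] - 1) + 1
    v <- arr[cbind(ix, iy, iz)]
    contrib <- wt * v
    contrib[wt == 0 & is.na(v)] <- 0  # zero-weight corners may be sentinels
    acc <- acc + contrib
  }
  vals[ok] <- acc
  vals
}

#' Field-of-view mask of a reconstruction
#'
#' Returns a binary mask that is 1 exactly on informative voxels. For volumes
#' carrying an `fov_radius` attribute (every reconstruction produced by this
#' toolkit's FBP does) the mask is the inscribed disk/cylinder about the
#' raster center; otherwise sentinel voxels (`NA`) define the non-informative
#' region. A volume with neither is rejected: supply an explicit mask.
#'
#' @param rec a `voxel_volume`.
#' @return a `binary_mask` on the same raster.
#' @export
fov_mask <- function(rec) {
  radius <- attr(rec, "fov_radius")
  if (!is.null(radius)) {
    ctr <- raster_center(rec)
    n <- rec$sides
    x <- (0:(n[1] - 1)) * rec$pitch[1] - ctr[1]
    y <- (0:(n[2] - 1)) * rec$pitch[2] - ctr[2]
    d2 <- outer(x^2, y^2, `+`)
    m <- array(rep(as.numeric(d2 <= radius^2), n[3]), dim = n)
    return(binary_mask(m, pitch = rec$pitch, cs = rec$cs))
  }
  if (anyNA(rec$values))
    return(binary_mask(!is.na(rec$values), pitch = rec$pitch, cs = rec$cs))
  stop_contract(paste0("volume carries neither an 'fov_radius' attribute nor sentinel ",
                       "voxels; supply an explicit FOV mask"))
}
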