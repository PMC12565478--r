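## End-to-end benchmarking workflow drivers: sinogram-degradation, metal
## artifact reduction (MAR), and the analytic-ground-truth (TrueCT-style)
## scheme, plus dataset packaging with a checklist manifest.

#' Workflow configuration
#'
#' Fully serializable description of a benchmark run: phantom, geometry,
#' spectrum, degradation, reconstruction, metric plan and one named seed per
#' stochastic stage. Re-running a serialized config reproduces the dataset
#' package bit-for-bit.
#'
#' @param scheme `"degradation"`, `"mar"` or `"truect"`.
#' @param phantom list with `primitives` (see [vm_ellipse()]).
#' @param sides,pitch phantom raster (2D desk scale: `sides` scalar or pair).
#' @param geometry list: `n_angles`, `n_detectors`, `det_pitch`.
#' @param spectrum list: `energies`, `weights`.
#' @param e_ref reference energy (keV) for calibration and ground truth.
#' @param I0 photons per detector element.
#' @param supersample projection grid upsampling factor (>= 2 avoids the
#'   inverse crime).
#' @param voxelize_subsample voxelization subsampling density.
#' @param degradation list for the degradation scheme: `type`
#'   (`"NOI"`, `"DSS"`, `"RSS"`), plus `dose_fraction` / `keep_every_k` /
#'   `angle_range` / `m`.
#' @param inclusion for the MAR scheme: list `primitives`, `sides`, `offset`.
#' @param bhc apply water correction (polychromatic schemes).
#' @param recon list: `filter` (`"ramlak"`/`"hann"`), optional `sides`,
#'   `pitch`.
#' @param hu_convention `"air_ref"` or `"vac_ref"`.
#' @param window HU normalization window `list(level, width)`.
#' @param metrics metric plan metric ids.
#' @param n_boot bootstrap replicates for uncertainty.
#' @param seeds named list of integer seeds (`noise`, `rss`, `boot`,
#'   `dequant`) - one per stochastic stage.
#' @param calibration list: `radius` (cm) of the water calibration disk.
#' @return object of class `workflow_config`.
#' @export
workflow_config <- function(scheme, phantom, sides, pitch, geometry, spectrum,
                            e_ref, I0 = 1e5, supersample = 2L,
                            voxelize_subsample = 4L,
                            degradation = NULL, inclusion = NULL, bhc = TRUE,
                            recon = list(filter = "ramlak"),
                            hu_convention = "air_ref",
                            window = list(level = 0, width = 2000),
                            metrics = c("rmse", "psnr", "ssim", "regional"),
                            n_boot = 100L, seeds = list(),
                            calibration = list(radius = 2)) {
  cfg <- list(scheme = match.arg(scheme, c("degradation", "mar", "truect")),
              phantom = phantom, sides = sides, pitch = pitch,
              geometry = geometry, spectrum = spectrum, e_ref = e_ref,
              I0 = I0, supersample = supersample,
              voxelize_subsample = voxelize_subsample,
              degradation = degradation, inclusion = inclusion, bhc = bhc,
              recon = recon, hu_convention = hu_convention, window = window,
              metrics = metrics, n_boot = n_boot, seeds = seeds,
              calibration = calibration,
              scatter_model = "none", detector_model = "ideal")
  class(cfg) <- "workflow_config"
  cfg
}

#' Serialize / load a workflow configuration (JSON)
#' @param cfg a `workflow_config`.
#' @param path file path.
#' @export
write_workflow_config <- function(cfg, path) write_json_file(unclass(cfg), path)

#' @rdname write_workflow_config
#' @export
read_workflow_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE,
                             simplifyMatrix = FALSE)
  raw$phantom$primitives <- lapply(raw$phantom$primitives, function(p) {
    p$center <- as.numeric(unlist(p$center)); p$semi_axes <- as.numeric(unlist(p$semi_axes)); p
  })
  if (!is.null(raw$inclusion))
    raw$inclusion$primitives <- lapply(raw$inclusion$primitives, function(p) {
      p$center <- as.numeric(unlist(p$center)); p$semi_axes <- as.numeric(unlist(p$semi_axes)); p
    })
  class(raw) <- "workflow_config"
  raw
}

cfg_model <- function(prims, id = "phantom")
  vector_model(prims, cs = coord_sys(id = id))

cfg_geometry <- function(cfg)
  scan_geometry(n_angles = cfg$geometry$n_angles,
                n_detectors = cfg$geometry$n_detectors,
                det_pitch = cfg$geometry$det_pitch)

cfg_spectrum <- function(cfg)
  xray_spectrum(unlist(cfg$spectrum$energies), unlist(cfg$spectrum$weights))

cfg_window <- function(cfg) hu_window(cfg$window$level, cfg$window$width)

require_seed <- function(cfg, name) {
  s <- cfg$seeds[[name]]
  if (is.null(s))
    stop_contract("stochastic stage '%s' requires a seed in cfg$seeds$%s", name, name)
  as.integer(s)
}

## identity-rotation placement between two centered rasters: voxel-(0,0,0)
## coordinates differ by the raster-center difference plus a physical offset
centered_placement <- function(from_sides, from_pitch, to_sides, to_pitch,
                               offset = c(0, 0, 0), source = "src", target = "tgt") {
  rc_from <- (c(from_sides, 1)[1:3] - 1) / 2 * rep(from_pitch, length.out = 3)
  rc_to <- (c(to_sides, 1)[1:3] - 1) / 2 * rep(to_pitch, length.out = 3)
  rigid_transform(diag(3), rc_to - rc_from + c(offset, 0)[1:3],
                  source = source, target = target)
}

## VOI masks from a segmentation: one eroded support per non-background label
vois_from_seg <- function(seg, erode = 1L) {
  out <- list()
  for (k in seq_along(seg$labels)) {
    sup <- binary_mask(seg$values == k, pitch = seg$pitch, cs = seg$cs)
    if (mask_count(sup) == 0) next
    er <- mask_erode(sup, erode)
    if (mask_count(er) > 0) out[[seg$labels[k]]] <- er
  }
  out
}

simulate_and_reconstruct <- function(cfg, w, dict, geom, spectrum, noise_seed = NULL) {
  praw <- project_weights(w, dict, geom, spectrum, I0 = cfg$I0,
                          supersample = cfg$supersample)
  pnoise <- if (!is.null(noise_seed)) add_poisson_noise(praw, seed = noise_seed) else praw
  plog <- log_normalize(pnoise)
  pready <- if (isTRUE(cfg$bhc) && length(spectrum$energies) > 1)
    water_correct(plog, dict, cfg$e_ref) else plog
  rsides <- norm_sides(unlist(cfg$recon$sides %||% cfg$sides))
  rpitch <- cfg$recon$pitch %||% cfg$pitch
  rec <- fbp_reconstruct(pready, rsides, rpitch, filter = cfg$recon$filter %||% "ramlak")
  list(raw = praw, noised = if (!is.null(noise_seed)) pnoise else NULL,
       log = plog, ready = pready, rec = rec)
}

#' Run the analytic-ground-truth vCT benchmark workflow
#'
#' Voxelizes a vector phantom, takes the analytic monoenergetic
#' reconstruction at the reference energy as ground truth (in HU), simulates
#' raw polychromatic counts, water-corrects, reconstructs with the baseline
#' FBP, resamples into the phantom coordinate system, converts to HU, and
#' evaluates with masked metrics inside per-material VOIs. A water
#' calibration disk is simulated alongside with its own sinogram and
#' expected reconstruction, and everything is packaged with a checklist
#' manifest.
#'
#' @param cfg a `workflow_config` with `scheme = "truect"`.
#' @param out_dir package output directory.
#' @return invisibly, a list: `package_dir`, `report`, `audit`,
#'   `calibration_hu_mean`, plus the main artifacts.
#' @export
run_truect_workflow <- function(cfg, out_dir) {
  stopifnot(cfg$scheme == "truect")
  dict <- material_dictionary()
  v <- cfg_model(cfg$phantom$primitives)
  geom <- cfg_geometry(cfg)
  spectrum <- cfg_spectrum(cfg)
  w <- voxelize_weights(v, dict, cfg$sides, cfg$pitch,
                        subsample = cfg$voxelize_subsample)
  seg <- voxelize_seg(v, dict, cfg$sides, cfg$pitch)
  r_syn <- analytic_gt(w, dict, cfg$e_ref)
  h_syn <- hu_from_lac(r_syn, dict, cfg$e_ref, cfg$hu_convention)
  attr(h_syn, "fov_radius") <- Inf

  noise_seed <- if (!is.null(cfg$seeds$noise)) require_seed(cfg, "noise")
  sim <- simulate_and_reconstruct(cfg, w, dict, geom, spectrum, noise_seed)

  ## RES into the phantom coordinate system (recorded), then R2H
  g_rec <- centered_placement(sim$rec$sides, sim$rec$pitch, w$sides, w$pitch,
                              source = "recon", target = w$cs$id)
  r_tgt <- resample(sim$rec, w$sides, w$pitch, target_cs = w$cs,
                    transform = g_rec, interpolation = "linear")
  attr(r_tgt, "energy") <- attr(sim$rec, "energy")
  attr(r_tgt, "fov_radius") <- attr(sim$rec, "fov_radius")
  attr(r_tgt, "method") <- attr(sim$rec, "method")
  h_rec <- hu_from_lac(r_tgt, dict, cfg$e_ref, cfg$hu_convention)

  vois <- vois_from_seg(seg)
  plan <- list(metrics = cfg$metrics, normalization = cfg_window(cfg),
               eval_cs = w$cs$id, n_boot = cfg$n_boot,
               seed = if (cfg$n_boot > 0) require_seed(cfg, "boot"),
               res_record = attr(r_tgt, "resample_record"))
  report <- evaluate(h_rec, h_syn, vois = vois, plan = plan)
  report$gt_method <- "analytic"

  ## calibration object: water disk with known expected reconstruction
  cal <- run_calibration_object(cfg, dict, geom, spectrum)

  artifacts <- list(dict = dict, vector_model = v, weights = w, seg = seg,
                    gt = list(r_syn = r_syn, h_syn = h_syn),
                    sinograms = list(raw = sim$raw,
                                     intermediate = Filter(Negate(is.null),
                                       list(log_normalize = sim$log)),
                                     ready = sim$ready),
                    recon = list(baseline = sim$rec, resampled = r_tgt,
                                 baseline_hu = h_rec),
                    masks = list(fov = list(fov_rec = fov_mask(r_tgt)),
                                 voi = vois),
                    transforms = list(g_rec = g_rec),
                    reports = list(quality_report = report),
                    calibration = cal)
  pkg <- package_dataset(artifacts, cfg, out_dir)
  invisible(c(pkg, list(report = report, h_syn = h_syn, h_rec = h_rec,
                        calibration_hu_mean = cal$hu_mean)))
}

run_calibration_object <- function(cfg, dict, geom, spectrum) {
  vcal <- cfg_model(list(vm_ellipse(c(0, 0), rep(cfg$calibration$radius, 2), "water")),
                    id = "calibration")
  wcal <- voxelize_weights(vcal, dict, cfg$sides, cfg$pitch,
                           subsample = cfg$voxelize_subsample)
  sim <- simulate_and_reconstruct(cfg, wcal, dict, geom, spectrum, noise_seed = NULL)
  expected <- analytic_gt(wcal, dict, cfg$e_ref)
  hu <- hu_from_lac(sim$rec, dict, cfg$e_ref, cfg$hu_convention)
  interior <- mask_erode(binary_mask(wcal$values[, , , match("water", wcal$materials),
                                                 drop = FALSE][, , 1, 1] >= 0.999,
                                     pitch = wcal$pitch, cs = wcal$cs), 2L)
  list(raw = sim$raw, ready = sim$ready, rec = sim$rec, expected = expected,
       hu_mean = mean(hu$values[interior$values == 1], na.rm = TRUE))
}

#' Run the sinogram-degradation benchmark workflow
#'
#' Simulates a high-quality reference sinogram, derives a degraded sinogram
#' by the configured operator (Poisson low dose `NOI`, deterministic
#' subsampling `DSS`, or randomized subsampling `RSS`), reconstructs both
#' with the baseline method, and evaluates the degraded reconstruction
#' against both the reference reconstruction (the classic scheme) and the
#' analytic ground truth.
#'
#' @param cfg a `workflow_config` with `scheme = "degradation"`.
#' @param out_dir package output directory.
#' @return invisibly: `package_dir`, both reports, reconstructions.
#' @export
run_degradation_workflow <- function(cfg, out_dir) {
  stopifnot(cfg$scheme == "degradation")
  dict <- material_dictionary()
  v <- cfg_model(cfg$phantom$primitives)
  geom <- cfg_geometry(cfg)
  spectrum <- cfg_spectrum(cfg)
  w <- voxelize_weights(v, dict, cfg$sides, cfg$pitch,
                        subsample = cfg$voxelize_subsample)
  seg <- voxelize_seg(v, dict, cfg$sides, cfg$pitch)
  r_syn <- analytic_gt(w, dict, cfg$e_ref)
  attr(r_syn, "fov_radius") <- Inf

  praw <- project_weights(w, dict, geom, spectrum, I0 = cfg$I0,
                          supersample = cfg$supersample)
  p_ref <- log_normalize(praw)
  deg <- cfg$degradation
  if (is.null(deg)) stop_contract("degradation config required")
  p_low_raw <- NULL
  if (deg$type == "NOI") {
    scaled <- praw
    frac <- deg$dose_fraction %||% 1
    scaled$counts <- scaled$dark + (scaled$counts - scaled$dark) * frac
    scaled$I0 <- scaled$I0 * frac
    scaled$air_scan <- scaled$dark + (scaled$air_scan - scaled$dark) * frac
    scaled$provenance <- c(scaled$provenance,
                           list(prov_step("P2P", step = "dose_scale",
                                          dose_fraction = frac)))
    p_low_raw <- add_poisson_noise(scaled, seed = require_seed(cfg, "noise"))
    p_low <- log_normalize(p_low_raw)
  } else if (deg$type == "DSS") {
    p_low <- subsample_angles_deterministic(p_ref,
                                            keep_every_k = deg$keep_every_k,
                                            angle_range = if (!is.null(deg$angle_range))
                                              unlist(deg$angle_range))
  } else if (deg$type == "RSS") {
    p_low <- subsample_angles_random(p_ref, m = deg$m, seed = require_seed(cfg, "rss"))
  } else stop_contract("unknown degradation type '%s'", deg$type)

  rsides <- norm_sides(unlist(cfg$recon$sides %||% cfg$sides))
  rpitch <- cfg$recon$pitch %||% cfg$pitch
  r_ref <- fbp_reconstruct(p_ref, rsides, rpitch, filter = cfg$recon$filter %||% "ramlak")
  r_low <- fbp_reconstruct(p_low, rsides, rpitch, filter = cfg$recon$filter %||% "ramlak")

  norm <- c(0, 1.2 * mu_of(dict, "skull", cfg$e_ref))  # LAC-domain display range
  vois <- vois_from_seg(seg)
  plan <- list(metrics = cfg$metrics, normalization = norm, eval_cs = r_low$cs$id,
               n_boot = cfg$n_boot,
               seed = if (cfg$n_boot > 0) require_seed(cfg, "boot"))
  report_syn <- evaluate(r_low, r_syn, vois = vois, plan = plan)
  report_syn$gt_method <- "analytic"
  report_ref <- evaluate(r_low, r_ref, vois = vois, plan = plan)
  report_ref$gt_method <- "reference_reconstruction"

  artifacts <- list(dict = dict, vector_model = v, weights = w, seg = seg,
                    gt = list(r_syn = r_syn),
                    sinograms = list(raw = praw,
                                     intermediate = list(log_normalize = p_ref),
                                     ready = p_low),
                    recon = list(baseline = r_low, reference = r_ref),
                    masks = list(fov = list(fov_rec = fov_mask(r_low)), voi = vois),
                    transforms = list(),
                    reports = list(quality_report = report_syn,
                                   quality_report_vs_ref = report_ref),
                    calibration = NULL)
  pkg <- package_dataset(artifacts, cfg, out_dir)
  invisible(c(pkg, list(report_syn = report_syn, report_ref = report_ref,
                        r_ref = r_ref, r_low = r_low, r_syn = r_syn)))
}

#' Run the metal-artifact (MAR) benchmark workflow
#'
#' Builds paired phantoms differing only by a highly attenuating inclusion,
#' projects both under the polychromatic spectrum, optionally water-corrects,
#' reconstructs both, derives the volume-of-interest masks from the recorded
#' inclusion placement (dilated inclusion support and its complement within
#' the FOV), and evaluates with masked metrics.
#'
#' @param cfg a `workflow_config` with `scheme = "mar"`, an `inclusion`
#'   entry, and a polychromatic spectrum.
#' @param out_dir package output directory.
#' @return invisibly: `package_dir`, `report`, paired reconstructions and
#'   the background RMSE outside the inclusion neighborhood.
#' @export
run_mar_workflow <- function(cfg, out_dir) {
  stopifnot(cfg$scheme == "mar")
  dict <- material_dictionary()
  v <- cfg_model(cfg$phantom$primitives)
  geom <- cfg_geometry(cfg)
  spectrum <- cfg_spectrum(cfg)
  w_ref <- voxelize_weights(v, dict, cfg$sides, cfg$pitch,
                            subsample = cfg$voxelize_subsample)
  seg <- voxelize_seg(v, dict, cfg$sides, cfg$pitch)

  inc <- cfg$inclusion
  vinc <- cfg_model(inc$primitives, id = "inclusion")
  inc_seg <- voxelize_seg(vinc, dict, inc$sides, cfg$pitch)
  placement <- centered_placement(inc_seg$sides, inc_seg$pitch,
                                  w_ref$sides, w_ref$pitch,
                                  offset = unlist(inc$offset %||% c(0, 0)),
                                  source = inc_seg$cs$id, target = w_ref$cs$id)
  ## warn when the inclusion is not strictly the most attenuating material
  inc_mats <- unique(unlist(lapply(vinc$primitives, `[[`, "material")))
  base_mats <- unique(unlist(lapply(v$primitives, `[[`, "material")))
  for (e in spectrum$energies)
    if (any(mu_of(dict, inc_mats, e) <= max(mu_of(dict, base_mats, e))))
      warning(sprintf("inclusion is not strictly more attenuating than the base at %g keV", e))
  w_low <- compose_objects(w_ref, inc_seg, placement)

  r_syn <- analytic_gt(w_ref, dict, cfg$e_ref)   # metal-free analytic reference
  attr(r_syn, "fov_radius") <- Inf
  sim_ref <- simulate_and_reconstruct(cfg, w_ref, dict, geom, spectrum)
  sim_low <- simulate_and_reconstruct(cfg, w_low, dict, geom, spectrum)

  support <- binary_mask(attr(w_low, "inclusion_support"),
                         pitch = w_ref$pitch, cs = w_ref$cs)
  voi_in <- mask_dilate(support, 2L)
  fov <- fov_mask(sim_low$rec)
  voi_out <- fov
  voi_out$values <- pmax(fov$values - voi_in$values, 0)
  vois <- list(inclusion_neighborhood = voi_in, background = voi_out)

  norm <- c(0, 1.2 * mu_of(dict, "skull", cfg$e_ref))
  plan <- list(metrics = cfg$metrics, normalization = norm,
               eval_cs = sim_low$rec$cs$id, n_boot = cfg$n_boot,
               seed = if (cfg$n_boot > 0) require_seed(cfg, "boot"))
  report <- evaluate(sim_low$rec, sim_ref$rec, vois = vois, plan = plan)
  report$gt_method <- "reference_reconstruction"

  bg <- eval_mask(fov_mask(sim_ref$rec), fov, voi = voi_out, id = "f_QTF:background")
  rmse_bg <- masked_rmse_psnr(sim_low$rec, sim_ref$rec, bg, norm)$rmse

  artifacts <- list(dict = dict, vector_model = v, weights = w_low, seg = seg,
                    gt = list(r_syn = r_syn),
                    sinograms = list(raw = sim_low$raw,
                                     intermediate = Filter(Negate(is.null), list(
                                       log_normalize = sim_low$log,
                                       bhc = if (isTRUE(cfg$bhc)) sim_low$ready)),
                                     ready = sim_low$ready),
                    recon = list(baseline = sim_low$rec, reference = sim_ref$rec),
                    masks = list(fov = list(fov_rec = fov),
                                 voi = vois),
                    transforms = list(inclusion_placement = placement),
                    reports = list(quality_report = report),
                    calibration = NULL)
  pkg <- package_dataset(artifacts, cfg, out_dir)
  invisible(c(pkg, list(report = report, r_ref = sim_ref$rec, r_low = sim_low$rec,
                        rmse_background = rmse_bg, placement = placement)))
}

## -------------------------------------------------------------- packaging

transform_record <- function(g)
  list(rotation = as.vector(g$rotation), translation = g$translation,
       source = g$source, target = g$target)

#' Package workflow artifacts into an audited dataset
#'
#' Writes the documented directory layout (phantoms, ground truth, raw /
#' intermediate / ready sinograms, baseline reconstructions, masks,
#' transforms, config, seeds, reports), verifies the provenance chain is
#' connected before writing, auto-fills the verifiable checklist manifest
#' items from the written contents, and leaves the judgment items (27-33)
#' with evidence slots for the author.
#'
#' @param artifacts structured artifact list as assembled by the workflow
#'   drivers.
#' @param cfg the `workflow_config` that produced the artifacts.
#' @param dir output directory (created; must not already contain a package).
#' @return list with `package_dir`, `manifest`, `checksums`.
#' @export
package_dataset <- function(artifacts, cfg, dir) {
  ## provenance connectivity: refuse to package a broken chain
  if (!is.null(artifacts$recon$baseline) && is.null(artifacts$sinograms$ready))
    stop_contract("broken provenance edge: recon/baseline without sinograms/ready")
  if (!is.null(artifacts$sinograms$ready) && is.null(artifacts$sinograms$raw)) {
    ops <- vapply(artifacts$sinograms$ready$provenance, `[[`, "", "op")
    if (!identical(ops[1], "V2P"))
      stop_contract("broken provenance edge: sinograms/ready without sinograms/raw")
  }
  if (!is.null(artifacts$gt$h_syn) && is.null(artifacts$weights))
    stop_contract("broken provenance edge: gt/h_syn without phantoms/weights")

  if (dir.exists(dir) && file.exists(file.path(dir, "manifest.json")))
    stop_contract("'%s' already holds a dataset package", dir)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)

  write_json_file(list(format = PACKAGE_FORMAT,
                       platform = R.version$platform,
                       sentinel_encoding = "NA/NaN in TSV arrays"),
                  file.path(dir, "package_info.json"))
  dir.create(file.path(dir, "config"), showWarnings = FALSE)
  write_workflow_config(cfg, file.path(dir, "config", "workflow.json"))
  dir.create(file.path(dir, "seeds"), showWarnings = FALSE)
  write_json_file(cfg$seeds %||% list(), file.path(dir, "seeds", "seeds.json"))

  ph <- file.path(dir, "phantoms")
  dir.create(ph, showWarnings = FALSE)
  file.copy(artifacts$dict$source, file.path(ph, "materials.json"))
  if (!is.null(artifacts$vector_model))
    write_vector_model(artifacts$vector_model, file.path(ph, "vector_model.json"))
  if (!is.null(artifacts$weights))
    write_weights_group(artifacts$weights, ph, "weights",
                        producer = list(op = "V2W", subsample = cfg$voxelize_subsample),
                        inputs = "phantoms/vector_model.json")
  if (!is.null(artifacts$seg))
    write_seg_group(artifacts$seg, ph, "seg",
                    producer = list(op = "V2S"),
                    inputs = "phantoms/vector_model.json")

  if (!is.null(artifacts$gt)) {
    gtd <- file.path(dir, "gt")
    if (!is.null(artifacts$gt$r_syn))
      write_volume_group(artifacts$gt$r_syn, gtd, "r_syn",
                         producer = list(op = "W2R", e_ref_keV = cfg$e_ref),
                         inputs = "phantoms/weights")
    if (!is.null(artifacts$gt$h_syn))
      write_volume_group(artifacts$gt$h_syn, gtd, "h_syn",
                         producer = list(op = "R2H", e_ref_keV = cfg$e_ref,
                                         convention = cfg$hu_convention),
                         inputs = "gt/r_syn")
  }

  sd <- file.path(dir, "sinograms")
  if (!is.null(artifacts$sinograms$raw))
    write_sinogram_group(artifacts$sinograms$raw, file.path(sd, "raw"),
                         inputs = "phantoms/weights")
  ints <- artifacts$sinograms$intermediate %||% list()
  i <- 0
  for (nm in names(ints)) {
    i <- i + 1
    write_sinogram_group(ints[[nm]],
                         file.path(sd, "intermediate", sprintf("%02d_%s", i, nm)),
                         inputs = "sinograms/raw")
  }
  if (!is.null(artifacts$sinograms$ready))
    write_sinogram_group(artifacts$sinograms$ready, file.path(sd, "ready"),
                         inputs = if (length(ints)) "sinograms/intermediate" else "sinograms/raw")

  for (nm in names(artifacts$recon %||% list()))
    write_volume_group(artifacts$recon[[nm]], file.path(dir, "recon", nm), "r",
                       producer = list(op = "P2R",
                                       method = attr(artifacts$recon[[nm]], "method")),
                       inputs = "sinograms/ready")

  for (nm in names(artifacts$masks$fov %||% list()))
    write_mask_group(artifacts$masks$fov[[nm]], file.path(dir, "masks", "fov"), nm,
                     producer = list(op = "FOV"))
  for (nm in names(artifacts$masks$voi %||% list()))
    write_mask_group(artifacts$masks$voi[[nm]], file.path(dir, "masks", "voi"), nm,
                     producer = list(op = "V2S", derived = "VOI support"))

  dir.create(file.path(dir, "transforms"), showWarnings = FALSE)
  write_json_file(lapply(artifacts$transforms %||% list(), transform_record),
                  file.path(dir, "transforms", "g_records.json"))

  rd <- file.path(dir, "reports")
  dir.create(rd, showWarnings = FALSE)
  for (nm in names(artifacts$reports %||% list()))
    write_quality_report(artifacts$reports[[nm]], file.path(rd, paste0(nm, ".json")))

  if (!is.null(artifacts$calibration)) {
    cd <- file.path(dir, "calibration")
    write_sinogram_group(artifacts$calibration$raw,
                         file.path(cd, "sinograms", "raw"), inputs = "calibration object")
    write_sinogram_group(artifacts$calibration$ready,
                         file.path(cd, "sinograms", "ready"),
                         inputs = "calibration/sinograms/raw")
    write_volume_group(artifacts$calibration$rec, file.path(cd, "recon"), "r",
                       producer = list(op = "P2R"),
                       inputs = "calibration/sinograms/ready")
    write_volume_group(artifacts$calibration$expected, file.path(cd, "expected"),
                       "r_expected",
                       producer = list(op = "W2R", e_ref_keV = cfg$e_ref),
                       inputs = "calibration object")
  }

  manifest <- auto_fill_manifest(dir)
  write_manifest(manifest, file.path(dir, "manifest.json"))
  list(package_dir = dir, manifest = manifest, checksums = package_checksums(dir))
}
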