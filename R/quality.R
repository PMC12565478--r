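## Masked full-reference metrics (QFR), regional task metrics (QTF), and
## model/physics metrics (QTM), with mandatory mask, normalization and
## hyperparameter recording.

#' Evaluation mask with construction record
#'
#' Full-reference metrics are only meaningful where both volumes are
#' informative: `f_QFR = FOV(gt) & FOV(rec)`, and task metrics additionally
#' intersect a VOI: `f_QTF = f_QFR & VOI`. The construction record proves
#' which masks were intersected.
#'
#' @param fov_gt,fov_rec `binary_mask`s (FOV of ground truth / reconstruction).
#' @param voi optional `binary_mask` volume of interest.
#' @param id mask identifier recorded in reports.
#' @return object of class `eval_mask`.
#' @export
eval_mask <- function(fov_gt, fov_rec, voi = NULL, id = "f_QFR") {
  m <- mask_intersect(fov_gt, fov_rec)
  parts <- c("FOV(gt)", "FOV(rec)")
  if (!is.null(voi)) {
    m <- mask_intersect(m, voi)
    parts <- c(parts, "VOI")
  }
  structure(list(mask = m, id = id, construction = parts), class = "eval_mask")
}

norm_record <- function(normalization) {
  if (inherits(normalization, "hu_window"))
    list(type = "hu_window", level = normalization$level, width = normalization$width)
  else list(type = "range", lo = normalization[1], hi = normalization[2])
}

normalize_to_unit <- function(vals, normalization) {
  if (inherits(normalization, "hu_window")) {
    apply_window(vals, normalization)
  } else {
    lo <- normalization[1]; hi <- normalization[2]
    if (hi <= lo) stop_contract("normalization range must have hi > lo")
    clip01((vals - lo) / (hi - lo))
  }
}

check_same_raster <- function(rec, gt) {
  if (!identical(rec$sides, gt$sides) || max(abs(rec$pitch - gt$pitch)) > 1e-12)
    stop_contract(paste0("volumes live on different rasters; resample explicitly ",
                         "(and record the RES parameters) before evaluation"))
}

#' Masked RMSE and PSNR
#'
#' Both volumes are windowed to `[0, 1]` by the stated normalization; RMSE is
#' taken over masked voxels only, and `PSNR = -20 log10(RMSE)` with peak
#' fixed at 1 after normalization (removing the peak-choice degree of freedom
#' that varies across implementations). A perfect match reports `Inf` PSNR.
#'
#' @param rec,gt `voxel_volume`s on the same raster.
#' @param mask an `eval_mask` (or `binary_mask`), non-empty.
#' @param normalization an [hu_window()] or numeric `c(lo, hi)` range.
#' @return list with `rmse`, `psnr`, `n_voxels`, `normalization`, `mask_id`.
#' @export
masked_rmse_psnr <- function(rec, gt, mask, normalization) {
  check_same_raster(rec, gt)
  m <- if (inherits(mask, "eval_mask")) mask$mask else mask
  sel <- m$values != 0
  if (!any(sel)) stop_contract("evaluation mask is empty")
  a <- normalize_to_unit(rec$values[sel], normalization)
  b <- normalize_to_unit(gt$values[sel], normalization)
  if (anyNA(a) || anyNA(b))
    stop_contract("sentinel voxels inside the evaluation mask; fix the mask")
  rmse <- sqrt(mean((a - b)^2))
  list(rmse = rmse, psnr = if (rmse == 0) Inf else -20 * log10(rmse),
       n_voxels = sum(sel), normalization = norm_record(normalization),
       mask_id = if (inherits(mask, "eval_mask")) mask$id else "explicit")
}

## separable Gaussian local moments over a 2D field (slice volumes)
local_moments <- function(x, y, win, sigma) {
  r <- (win - 1) / 2
  k <- exp(-((-r:r)^2) / (2 * sigma^2)); k <- k / sum(k)
  sep <- function(m) {
    n1 <- nrow(m); n2 <- ncol(m)
    acc <- matrix(0, n1, n2)
    for (d in -r:r) {
      idx <- pmin(pmax(seq_len(n1) + d, 1), n1)   # replicate borders
      acc <- acc + k[d + r + 1] * m[idx, ]
    }
    out <- matrix(0, n1, n2)
    for (d in -r:r) {
      idx <- pmin(pmax(seq_len(n2) + d, 1), n2)
      out <- out + k[d + r + 1] * acc[, idx]
    }
    out
  }
  list(mx = sep(x), my = sep(y), mxx = sep(x * x), myy = sep(y * y), mxy = sep(x * y))
}

#' Masked structural similarity (SSIM)
#'
#' SSIM map with a Gaussian window (default 11 x 11, sigma 1.5) and the usual
#' stabilization constants, aggregated as the mean over voxels whose full
#' local window lies inside the mask - the mask is eroded by the window
#' radius, so boundary and out-of-mask voxels provably cannot contaminate the
#' score. Hyperparameters are part of the return value.
#'
#' @inheritParams masked_rmse_psnr
#' @param window_size odd window side (default 11).
#' @param sigma Gaussian window sigma in voxels (default 1.5).
#' @param k1,k2 stabilization constants (defaults 0.01, 0.03; peak 1).
#' @return list with `ssim`, `n_voxels`, hyperparameters, `mask_id`.
#' @export
masked_ssim <- function(rec, gt, mask, normalization, window_size = 11L,
                        sigma = 1.5, k1 = 0.01, k2 = 0.03) {
  check_same_raster(rec, gt)
  if (window_size %% 2 == 0) stop_contract("window_size must be odd")
  m <- if (inherits(mask, "eval_mask")) mask$mask else mask
  r <- (window_size - 1L) / 2L
  core <- mask_erode(m, r)
  sel <- core$values[, , 1] != 0
  if (!any(sel))
    stop_contract("mask too small: nothing remains after erosion by %d (need > %d wide)",
                  r, window_size)
  x <- normalize_to_unit(rec$values[, , 1], normalization)
  y <- normalize_to_unit(gt$values[, , 1], normalization)
  x[is.na(x)] <- 0; y[is.na(y)] <- 0   # sentinels only ever outside eroded core
  mo <- local_moments(x, y, window_size, sigma)
  c1 <- (k1 * 1)^2; c2 <- (k2 * 1)^2
  vx <- mo$mxx - mo$mx^2; vy <- mo$myy - mo$my^2; cxy <- mo$mxy - mo$mx * mo$my
  smap <- ((2 * mo$mx * mo$my + c1) * (2 * cxy + c2)) /
          ((mo$mx^2 + mo$my^2 + c1) * (vx + vy + c2))
  list(ssim = mean(smap[sel]), n_voxels = sum(sel),
       hyperparameters = list(window_size = window_size, sigma = sigma,
                              k1 = k1, k2 = k2, aggregation = "erode_by_window_radius"),
       normalization = norm_record(normalization),
       mask_id = if (inherits(mask, "eval_mask")) mask$id else "explicit")
}

#' Regional error statistics and SNR per VOI
#'
#' For each volume of interest: mean and standard deviation of `rec - gt`
#' and `SNR = mean(rec) / sd(rec - gt)` inside the region. A VOI disjoint
#' from the informative region is reported as not evaluable, never dropped.
#'
#' @param rec,gt `voxel_volume`s on the same raster.
#' @param vois named list of `binary_mask`s (already intersected with the
#'   FOVs, e.g. via [eval_mask()]).
#' @return named list; per VOI either statistics or `evaluable = FALSE`.
#' @export
regional_stats <- function(rec, gt, vois) {
  check_same_raster(rec, gt)
  lapply(vois, function(v) {
    m <- if (inherits(v, "eval_mask")) v$mask else v
    sel <- m$values != 0 & !is.na(rec$values) & !is.na(gt$values)
    if (!any(sel)) return(list(evaluable = FALSE, reason = "VOI disjoint from informative region"))
    err <- rec$values[sel] - gt$values[sel]
    s <- sd(err)
    list(evaluable = TRUE, n_voxels = sum(sel),
         mean_error = mean(err), sd_error = s,
         snr = if (s > 0) mean(rec$values[sel]) / s else Inf)
  })
}

#' Contrast-to-noise ratio between two regions
#'
#' `CNR = |mean_A - mean_B| / sqrt((var_A + var_B) / 2)`, invariant under
#' global affine intensity changes with positive gain. The two VOIs must be
#' disjoint and non-empty.
#'
#' @param rec a `voxel_volume`.
#' @param voi_a,voi_b disjoint `binary_mask`s.
#' @return list with `cnr`, the formula string and region sizes.
#' @export
cnr <- function(rec, voi_a, voi_b) {
  if (mask_count(mask_intersect(voi_a, voi_b)) > 0)
    stop_contract("CNR regions must be disjoint")
  sa <- voi_a$values != 0 & !is.na(rec$values)
  sb <- voi_b$values != 0 & !is.na(rec$values)
  if (!any(sa) || !any(sb)) stop_contract("both CNR regions must be non-empty")
  va <- rec$values[sa]; vb <- rec$values[sb]
  pooled <- sqrt((stats::var(va) + stats::var(vb)) / 2)
  list(cnr = if (pooled > 0) abs(mean(va) - mean(vb)) / pooled else Inf,
       formula = "|mean_A - mean_B| / sqrt((var_A + var_B)/2)",
       n_a = sum(sa), n_b = sum(sb))
}

#' Radially averaged noise power spectrum
#'
#' Per-realization mean-subtracted 2D periodogram over a rectangular VOI,
#' normalized as `NPS(f) = pitch_x * pitch_y / (Nx * Ny) * |FFT(noise)|^2`,
#' ensemble-averaged across realizations and radially binned. With this
#' normalization the spectrum integrates (sum times the frequency-bin area
#' `1/(Nx px) * 1/(Ny py)`) to the noise variance.
#'
#' @param realizations list of >= 2 `voxel_volume`s of the same homogeneous
#'   region (same raster).
#' @param voi rectangular `binary_mask` selecting the extraction window.
#' @return data.frame `freq` (cycles/cm), `nps`; attributes `normalization`
#'   and `variance` (direct estimate, for Parseval checks).
#' @export
nps <- function(realizations, voi) {
  if (length(realizations) < 2) stop_contract("need >= 2 noise realizations")
  sel <- which(voi$values[, , 1] != 0, arr.ind = TRUE)
  if (!nrow(sel)) stop_contract("empty VOI")
  rx <- range(sel[, 1]); ry <- range(sel[, 2])
  if (nrow(sel) != (diff(rx) + 1) * (diff(ry) + 1))
    stop_contract("NPS extraction requires a rectangular VOI")
  px <- realizations[[1]]$pitch[1]; py <- realizations[[1]]$pitch[2]
  nx <- diff(rx) + 1; ny <- diff(ry) + 1
  acc <- matrix(0, nx, ny)
  v <- 0
  for (rv in realizations) {
    sub <- rv$values[rx[1]:rx[2], ry[1]:ry[2], 1]
    sub <- sub - mean(sub)
    v <- v + stats::var(as.vector(sub))
    acc <- acc + (px * py) / (nx * ny) * Mod(fft(sub))^2
  }
  acc <- acc / length(realizations)
  fx <- c(0:(floor(nx / 2)), -(ceiling(nx / 2) - 1):-1)[1:nx] / (nx * px)
  fy <- c(0:(floor(ny / 2)), -(ceiling(ny / 2) - 1):-1)[1:ny] / (ny * py)
  fr <- sqrt(outer(fx^2, fy^2, `+`))
  nb <- max(8L, floor(min(nx, ny) / 2))
  breaks <- seq(0, max(fr) + 1e-12, length.out = nb + 1)
  bin <- cut(as.vector(fr), breaks, include.lowest = TRUE, labels = FALSE)
  out <- data.frame(freq = (breaks[-1] + breaks[-(nb + 1)]) / 2,
                    nps = as.vector(tapply(as.vector(acc), factor(bin, levels = 1:nb),
                                           mean)))
  attr(out, "normalization") <- list(pitch = c(px, py), window = c(nx, ny),
                                     convention = "pitch^2/N * |FFT|^2, ensemble mean")
  attr(out, "variance") <- v / length(realizations)
  attr(out, "integral") <- sum(acc) / (nx * px * ny * py)  # Parseval: ~ variance
  out
}

## ----------------------------------------------------------- report driver

#' Run a metric plan and produce a quality report
#'
#' Builds the evaluation masks (`FOV(gt) & FOV(rec)`, plus per-VOI masks),
#' runs the planned metrics, attaches seeded bootstrap confidence intervals
#' where defined, and returns a report in which every entry carries its mask
#' id, normalization record and hyperparameters; a metric whose precondition
#' fails is reported as failed with the reason, and the report is still
#' produced.
#'
#' @param rec,gt `voxel_volume`s on the same raster (resample first if not;
#'   the resampling record can be passed via `plan$res_record`).
#' @param vois optional named list of `binary_mask` VOIs.
#' @param plan list: `metrics` (subset of `"rmse"`, `"psnr"`, `"ssim"`,
#'   `"regional"`, `"cnr"`), `normalization` ([hu_window()] or range),
#'   `eval_cs` (id of the evaluation coordinate system), `n_boot`
#'   (bootstrap replicates, default 200), `seed` (required when `n_boot` >
#'   0), `ssim` (optional hyperparameter overrides), `cnr_pair` (names of
#'   the two VOIs to contrast).
#' @return object of class `quality_report`.
#' @export
evaluate <- function(rec, gt, vois = NULL, plan) {
  stopifnot(is.list(plan), !is.null(plan$metrics), !is.null(plan$normalization))
  eval_cs <- plan$eval_cs %||% rec$cs$id
  n_boot <- plan$n_boot %||% 200L
  fg <- fov_mask(gt); fr <- fov_mask(rec)
  fqfr <- eval_mask(fg, fr, id = "f_QFR")
  entries <- list()
  add <- function(e) entries[[length(entries) + 1]] <<- e
  fail_safe <- function(metric, class_id, fn) {
    tryCatch(fn(), error = function(err)
      add(list(metric = metric, class = class_id, failed = TRUE,
               reason = conditionMessage(err), eval_cs = eval_cs)))
  }
  nrm <- norm_record(plan$normalization)
  sel <- fqfr$mask$values != 0
  boot_ci <- function(errs2) {
    if (n_boot <= 0) return(NULL)
    reps <- with_seed(plan$seed, vapply(seq_len(n_boot), function(i)
      sqrt(mean(sample(errs2, replace = TRUE))), numeric(1)))
    list(method = "nonparametric_bootstrap_voxels", n_boot = n_boot,
         seed = plan$seed, ci95 = unname(quantile(reps, c(0.025, 0.975))))
  }
  if (any(c("rmse", "psnr") %in% plan$metrics)) fail_safe("rmse_psnr", "QFR", function() {
    res <- masked_rmse_psnr(rec, gt, fqfr, plan$normalization)
    a <- normalize_to_unit(rec$values[sel], plan$normalization)
    b <- normalize_to_unit(gt$values[sel], plan$normalization)
    ci <- boot_ci((a - b)^2)
    if ("rmse" %in% plan$metrics)
      add(list(metric = "rmse", class = "QFR", value = res$rmse,
               uncertainty = ci, mask_id = res$mask_id, normalization = nrm,
               hyperparameters = list(peak = 1), eval_cs = eval_cs))
    if ("psnr" %in% plan$metrics)
      add(list(metric = "psnr", class = "QFR",
               value = if (is.infinite(res$psnr)) "Inf" else res$psnr,
               uncertainty = NULL, mask_id = res$mask_id, normalization = nrm,
               hyperparameters = list(peak = 1), eval_cs = eval_cs))
  })
  if ("ssim" %in% plan$metrics) fail_safe("ssim", "QFR", function() {
    args <- c(list(rec = rec, gt = gt, mask = fqfr,
                   normalization = plan$normalization), plan$ssim %||% list())
    res <- do.call(masked_ssim, args)
    add(list(metric = "ssim", class = "QFR", value = res$ssim,
             uncertainty = NULL, mask_id = res$mask_id, normalization = nrm,
             hyperparameters = res$hyperparameters, eval_cs = eval_cs))
  })
  if ("regional" %in% plan$metrics && length(vois)) fail_safe("regional", "QTF", function() {
    ems <- lapply(names(vois), function(nm)
      eval_mask(fg, fr, voi = vois[[nm]], id = paste0("f_QTF:", nm)))
    names(ems) <- names(vois)
    res <- regional_stats(rec, gt, ems)
    for (nm in names(res))
      add(c(list(metric = paste0("regional:", nm), class = "QTF"),
            list(value = if (isTRUE(res[[nm]]$evaluable)) res[[nm]]$mean_error else NA,
                 detail = res[[nm]], uncertainty = NULL,
                 mask_id = paste0("f_QTF:", nm), normalization = list(type = "native"),
                 hyperparameters = list(snr_definition = "mean(rec)/sd(rec-gt)"),
                 eval_cs = eval_cs)))
  })
  if ("cnr" %in% plan$metrics && length(plan$cnr_pair %||% c()) == 2) {
    fail_safe("cnr", "QTM", function() {
      res <- cnr(rec, vois[[plan$cnr_pair[1]]], vois[[plan$cnr_pair[2]]])
      add(list(metric = "cnr", class = "QTM", value = res$cnr,
               uncertainty = NULL,
               mask_id = paste(plan$cnr_pair, collapse = "|"),
               normalization = list(type = "native"),
               hyperparameters = list(formula = res$formula), eval_cs = eval_cs))
    })
  }
  rep <- structure(list(entries = entries, eval_cs = eval_cs,
                        masks = list(f_QFR = fqfr$construction),
                        res_record = plan$res_record %||% NULL),
                   class = "quality_report")
  validate_quality_report(rep)
  rep
}

#' Validate a quality report against the shipped schema contract
#'
#' Structural validation: every non-failed entry must carry a metric id, a
#' class in {QFR, QTF, QTM}, a numeric (or "Inf") value, a mask id, a
#' normalization record, a hyperparameter record and an evaluation-CS id.
#' The JSON schema describing this contract ships at
#' `system.file("schema", "quality_report.schema.json", package = "vctbench")`.
#'
#' @param rep a `quality_report` (or a list parsed from its JSON form).
#' @return `TRUE` invisibly; errors describe the first violation.
#' @export
validate_quality_report <- function(rep) {
  if (is.null(rep$entries)) stop_contract("report lacks 'entries'")
  for (i in seq_along(rep$entries)) {
    e <- rep$entries[[i]]
    if (isTRUE(e$failed)) {
      if (is.null(e$reason)) stop_contract("failed entry %d lacks a reason", i)
      next
    }
    for (f in c("metric", "class", "value", "mask_id", "normalization",
                "hyperparameters", "eval_cs"))
      if (is.null(e[[f]]))
        stop_contract("entry %d ('%s') lacks required field '%s'",
                      i, e$metric %||% "?", f)
    if (!e$class %in% c("QFR", "QTF", "QTM"))
      stop_contract("entry %d has unknown class '%s'", i, e$class)
  }
  invisible(TRUE)
}

#' Serialize / load a quality report as JSON
#' @param rep a `quality_report`.
#' @param path file path.
#' @export
write_quality_report <- function(rep, path) write_json_file(unclass(rep), path)

#' @rdname write_quality_report
#' @export
read_quality_report <- function(path) {
  structure(jsonlite::read_json(path, simplifyVector = FALSE), class = "quality_report")
}
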