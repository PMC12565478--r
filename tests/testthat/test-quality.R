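mk_pair <- function(n = 48, noise = 0, seed = 1) {
  set.seed(seed)
  gt <- voxel_volume(matrix(runif(n * n, 0.3, 0.7), n), pitch = 0.1)
  rec <- gt
  if (noise > 0) rec$values <- rec$values + rnorm(n * n, 0, noise)
  attr(gt, "fov_radius") <- Inf
  attr(rec, "fov_radius") <- Inf
  list(rec = rec, gt = gt,
       mask = eval_mask(fov_mask(gt), fov_mask(rec)))
}

test_that("masked RMSE/PSNR: closed form, identity, and mask invariance", {
  p <- mk_pair()
  res <- masked_rmse_psnr(p$rec, p$gt, p$mask, normalization = c(0, 1))
  expect_equal(res$rmse, 0)
  expect_identical(res$psnr, Inf)
  ## constant offset 0.1 after normalization, no clipping -> RMSE 0.1, PSNR 20
  rec2 <- p$gt; rec2$values <- rec2$values + 0.1
  res2 <- masked_rmse_psnr(rec2, p$gt, p$mask, normalization = c(0, 1))
  expect_equal(res2$rmse, 0.1, tolerance = 1e-12)
  expect_equal(res2$psnr, 20, tolerance = 1e-9)
  ## corrupting voxels outside the mask leaves both values unchanged
  m <- binary_mask(matrix(0, 48, 48), pitch = 0.1)
  m$values[10:30, 10:30, 1] <- 1
  base <- masked_rmse_psnr(rec2, p$gt, m, c(0, 1))
  rec3 <- rec2; rec3$values[1, , 1] <- 99; rec3$values[48, , 1] <- -99
  after <- masked_rmse_psnr(rec3, p$gt, m, c(0, 1))
  expect_identical(base$rmse, after$rmse)
  expect_error(masked_rmse_psnr(rec2, p$gt, binary_mask(matrix(0, 48, 48), pitch = 0.1),
                                c(0, 1)), "empty")
})

test_that("masked SSIM matches the direct-window oracle and honors erosion", {
  p <- mk_pair(noise = 0.05, seed = 3)
  m <- binary_mask(matrix(0, 48, 48), pitch = 0.1)
  m$values[8:40, 8:40, 1] <- 1
  res <- masked_ssim(p$rec, p$gt, m, normalization = c(0, 1))
  expect_lt(res$ssim, 1)
  ## identity -> 1
  resid <- masked_ssim(p$gt, p$gt, m, normalization = c(0, 1))
  expect_equal(resid$ssim, 1, tolerance = 1e-9)
  ## oracle: straightforward double-loop SSIM on the crop, fully-inside pixels.
  ## The eroded-mask aggregation over [8,40]^2 equals plain SSIM over the same
  ## window centers computed from scratch.
  x <- pmin(pmax(p$rec$values[, , 1], 0), 1)
  y <- p$gt$values[, , 1]
  ## crop = the mask rectangle: its fully-inside window centers are exactly
  ## the eroded-mask centers the implementation aggregates over
  oracle <- ssim_oracle(x[8:40, 8:40], y[8:40, 8:40])
  expect_equal(res$ssim, oracle, tolerance = 1e-6)
  ## randomizing voxels outside the mask cannot change the value
  rec2 <- p$rec
  rec2$values[m$values == 0] <- runif(sum(m$values == 0), -5, 5)
  res2 <- masked_ssim(rec2, p$gt, m, normalization = c(0, 1))
  expect_identical(res$ssim, res2$ssim)
  tiny <- binary_mask(matrix(0, 48, 48), pitch = 0.1)
  tiny$values[10:12, 10:12, 1] <- 1
  expect_error(masked_ssim(p$rec, p$gt, tiny, c(0, 1)), "too small")
  expect_error(masked_ssim(p$rec, p$gt, m, c(0, 1), window_size = 8), "odd")
})

test_that("regional statistics report per-VOI bias and sampling-accurate SNR", {
  p <- mk_pair(seed = 5)
  voi_a <- binary_mask(matrix(0, 48, 48), pitch = 0.1); voi_a$values[5:20, 5:20, 1] <- 1
  voi_b <- binary_mask(matrix(0, 48, 48), pitch = 0.1); voi_b$values[30:45, 30:45, 1] <- 1
  res0 <- regional_stats(p$rec, p$gt, list(a = voi_a, b = voi_b))
  expect_equal(res0$a$mean_error, 0)
  expect_equal(res0$b$mean_error, 0)
  ## constant bias inside one VOI only
  rec <- p$gt; rec$values[5:20, 5:20, 1] <- rec$values[5:20, 5:20, 1] + 0.25
  res <- regional_stats(rec, p$gt, list(a = voi_a, b = voi_b))
  expect_equal(res$a$mean_error, 0.25, tolerance = 1e-12)
  expect_equal(res$b$mean_error, 0)
  ## SNR within 10% of the analytic mean/sigma at 10^4 voxels
  set.seed(6)
  n <- 100
  gt2 <- voxel_volume(matrix(2, n, n), pitch = 0.1)
  rec2 <- voxel_volume(matrix(2 + rnorm(n * n, 0, 0.1), n), pitch = 0.1)
  all_m <- binary_mask(matrix(1, n, n), pitch = 0.1)
  snr <- regional_stats(rec2, gt2, list(v = all_m))$v$snr
  expect_lt(abs(snr / (2 / 0.1) - 1), 0.1)
  ## disjoint VOI reported as not evaluable, never dropped
  off <- binary_mask(matrix(0, 48, 48), pitch = 0.1)
  off$values[1, 1, 1] <- 1
  recNA <- p$rec; recNA$values[1, 1, 1] <- NA
  resNA <- regional_stats(recNA, p$gt, list(off = off))
  expect_false(resNA$off$evaluable)
})

test_that("CNR: closed form, affine invariance, disjointness contract", {
  n <- 80
  set.seed(8)
  img <- voxel_volume(matrix(rnorm(n * n, 0, 0.1), n), pitch = 0.1)
  img$values[1:30, , 1] <- img$values[1:30, , 1] + 1     # region A mean 1
  va <- binary_mask(matrix(0, n, n), pitch = 0.1); va$values[1:30, , 1] <- 1
  vb <- binary_mask(matrix(0, n, n), pitch = 0.1); vb$values[41:70, , 1] <- 1
  res <- cnr(img, va, vb)
  expect_lt(abs(res$cnr - 10), 1)                         # 1/0.1 within sampling error
  ## identical homogeneous regions -> 0
  flat <- voxel_volume(matrix(5, n, n), pitch = 0.1)
  flat$values <- flat$values + array(rnorm(n * n, 0, 1e-6), dim(flat$values))
  expect_lt(cnr(flat, va, vb)$cnr, 1)
  ## affine invariance with positive gain
  img2 <- img; img2$values <- 3.7 * img$values - 11
  expect_equal(cnr(img2, va, vb)$cnr, res$cnr, tolerance = 1e-9)
  expect_error(cnr(img, va, va), "disjoint")
})

test_that("noise power spectrum: null case, Parseval, and low-pass mass shift", {
  n <- 64
  voi <- binary_mask(matrix(1, n, n), pitch = 0.1)
  same <- voxel_volume(matrix(7, n, n), pitch = 0.1)
  sp0 <- nps(list(same, same), voi)
  expect_true(all(sp0$nps == 0))
  ## white noise: spectrum integral approximates the variance within 10%
  set.seed(11)
  reals <- lapply(1:6, function(i) voxel_volume(matrix(rnorm(n * n, 0, 0.3), n), pitch = 0.1))
  spw <- nps(reals, voi)
  expect_lt(abs(attr(spw, "integral") / 0.3^2 - 1), 0.1)
  ## low-pass filtered noise shifts mass to low frequencies
  smooth <- lapply(reals, function(r) {
    v <- r$values[, , 1]
    sm <- (v + v[c(1, 1:(n - 1)), ] + v[c(2:n, n), ] +
           v[, c(1, 1:(n - 1))] + v[, c(2:n, n)]) / 5
    voxel_volume(matrix(sm, n), pitch = 0.1)
  })
  sps <- nps(smooth, voi)
  nb <- nrow(spw)
  lo <- 1:floor(nb / 3); hi <- (nb - floor(nb / 3)):nb
  frac_white <- sum(spw$nps[lo]) / sum(spw$nps)
  frac_smooth <- sum(sps$nps[lo], na.rm = TRUE) / sum(sps$nps, na.rm = TRUE)
  expect_gt(frac_smooth, frac_white)
  ## non-rectangular VOI refused
  bad <- binary_mask(matrix(1, n, n), pitch = 0.1)
  bad$values[1, 1, 1] <- 0
  expect_error(nps(reals, bad), "rectangular")
  expect_error(nps(reals[1], voi), ">= 2")
})

test_that("evaluate produces a complete, deterministic, schema-valid report", {
  p <- mk_pair(noise = 0.02, seed = 13)
  voi <- binary_mask(matrix(0, 48, 48), pitch = 0.1)
  voi$values[10:40, 10:40, 1] <- 1
  plan <- list(metrics = c("rmse", "psnr", "ssim", "regional"),
               normalization = c(0, 1), n_boot = 50, seed = 21)
  rep1 <- evaluate(p$rec, p$gt, vois = list(core = voi), plan = plan)
  rep2 <- evaluate(p$rec, p$gt, vois = list(core = voi), plan = plan)
  expect_identical(rep1$entries, rep2$entries)   # seeded bootstrap included
  expect_true(validate_quality_report(rep1))
  ## every entry carries mask id + normalization + hyperparameters
  for (e in rep1$entries) if (!isTRUE(e$failed)) {
    expect_false(is.null(e$mask_id))
    expect_false(is.null(e$normalization))
    expect_false(is.null(e$hyperparameters))
  }
  ## identity pair: rmse 0 and ssim 1 entries, masks logged
  repid <- evaluate(p$gt, p$gt, vois = list(core = voi),
                    plan = modifyList(plan, list(n_boot = 0)))
  vals <- setNames(lapply(repid$entries, `[[`, "value"),
                   vapply(repid$entries, `[[`, "", "metric"))
  expect_equal(vals$rmse, 0)
  expect_equal(vals$ssim, 1, tolerance = 1e-9)
  expect_equal(repid$masks$f_QFR, c("FOV(gt)", "FOV(rec)"))
  ## JSON round trip validates
  f <- tempfile(fileext = ".json")
  write_quality_report(rep1, f)
  expect_true(validate_quality_report(read_quality_report(f)))
  ## incomplete entry rejected
  broken <- rep1
  broken$entries[[1]]$normalization <- NULL
  expect_error(validate_quality_report(broken), "normalization")
})

test_that("all masked metrics are invariant to out-of-mask fuzz", {
  p <- mk_pair(noise = 0.03, seed = 17)
  m <- binary_mask(matrix(0, 48, 48), pitch = 0.1)
  m$values[12:36, 12:36, 1] <- 1
  base_r <- masked_rmse_psnr(p$rec, p$gt, m, c(0, 1))
  base_s <- masked_ssim(p$rec, p$gt, m, c(0, 1))
  base_g <- regional_stats(p$rec, p$gt, list(v = m))
  set.seed(19)
  for (i in 1:100) {
    rec <- p$rec
    out <- m$values == 0
    rec$values[out] <- runif(sum(out), -10, 10)
    expect_identical(masked_rmse_psnr(rec, p$gt, m, c(0, 1))$rmse, base_r$rmse)
    expect_identical(masked_ssim(rec, p$gt, m, c(0, 1))$ssim, base_s$ssim)
    expect_identical(regional_stats(rec, p$gt, list(v = m))$v$mean_error,
                     base_g$v$mean_error)
  }
})

test_that("PSNR depends on the declared normalization window predictably", {
  gt <- voxel_volume(matrix(100, 32, 32), pitch = 1)
  rec <- gt; rec$values <- rec$values + 10
  m <- binary_mask(matrix(1, 32, 32), pitch = 1)
  ## window width 1000: normalized error 0.01 -> PSNR 40; width 100: 0.1 -> 20
  res_wide <- masked_rmse_psnr(rec, gt, m, hu_window(100, 1000))
  res_narrow <- masked_rmse_psnr(rec, gt, m, hu_window(100, 100))
  expect_equal(res_wide$psnr, 40, tolerance = 1e-9)
  expect_equal(res_narrow$psnr, 20, tolerance = 1e-9)
})
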