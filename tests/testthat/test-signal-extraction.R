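test_that("identical label/control pairs give zero perfusion-weighted signal", {
  ctrl <- ir_model(bcsfb_tis, 4.24, 400)
  series <- make_uniform_series(rep(0, 7), ctrl)
  rois <- make_small_rois()
  out <- extract_roi_curves(series, rois, "ventricles")
  expect_equal(out$delta_m$delta_m, rep(0, 7))
  expect_equal(out$delta_m$sem, rep(0, 7))
  expect_equal(out$control$mean_signal, ctrl)
})

test_that("a known noiseless profile is recovered exactly for both roles", {
  dm <- bcsfb_csf_signal(bcsfb_tis, kinetic_params(2.8e-3, 4.24, 400))
  ctrl <- ir_model(bcsfb_tis, 4.24, 400)
  series <- make_uniform_series(dm, ctrl)
  rois <- make_small_rois()
  for (role in c("ventricles", "cortex")) {
    out <- extract_roi_curves(series, rois, role)
    expect_equal(out$delta_m$delta_m, dm, tolerance = 1e-12)
    expect_equal(out$control$mean_signal, ctrl, tolerance = 1e-12)
    expect_equal(out$delta_m$n, rep(10L, 7))
  }
})

test_that("per-TI SEM equals the recomputed SD/sqrt(n) of the pairwise differences", {
  dm <- bcsfb_csf_signal(bcsfb_tis, kinetic_params(2.8e-3, 4.24, 400))
  ctrl <- ir_model(bcsfb_tis, 4.24, 400)
  series <- make_uniform_series(dm, ctrl, noise_sd = 2, seed = 99)
  rois <- make_small_rois()
  out <- extract_roi_curves(series, rois, "ventricles")
  mask <- rois$ventricle_mask
  # direct recomputation from the raw arrays
  for (k in seq_along(bcsfb_tis)) {
    diffs <- vapply(1:10, function(r) {
      mean(series$selective[, , k, r][mask]) -
        mean(series$nonselective[, , k, r][mask])
    }, numeric(1))
    expect_equal(out$delta_m$delta_m[k], mean(diffs), tolerance = 1e-12)
    expect_equal(out$delta_m$sem[k], sd(diffs) / sqrt(10),
                 tolerance = 1e-12)
  }
})

test_that("extraction is invariant to the order of the two ventricular ROIs", {
  dm <- bcsfb_csf_signal(bcsfb_tis, kinetic_params(2.8e-3, 4.24, 400))
  ctrl <- ir_model(bcsfb_tis, 4.24, 400)
  series <- make_uniform_series(dm, ctrl, noise_sd = 2, seed = 5)
  r1 <- make_small_rois()
  r2 <- roi_set(r1$cortex_mask, rev(r1$ventricle_masks),
                r1$voxel_volume_mm3)
  expect_equal(extract_roi_curves(series, r1, "ventricles"),
               extract_roi_curves(series, r2, "ventricles"))
})

test_that("ROI containers validate masks and shapes", {
  rois <- make_small_rois()
  expect_equal(rois$ventricle_roi_volume, 8 * 4.8)
  # overlapping ventricle ROIs rejected
  m <- matrix(FALSE, 8, 8); m[4:5, 4:5] <- TRUE
  expect_error(roi_set(rois$cortex_mask, list(m, m), 4.8), "disjoint")
  # cortex/ventricle overlap rejected
  expect_error(roi_set(m, list(m), 4.8), "disjoint")
  # empty mask and grid mismatch at extraction time
  ctrl <- ir_model(bcsfb_tis, 4.24, 400)
  series <- make_uniform_series(rep(0, 7), ctrl)
  empty <- roi_set(matrix(FALSE, 8, 8),
                   list(rois$ventricle_masks[[1]]), 4.8)
  expect_error(extract_roi_curves(series, empty, "cortex"), "empty")
  big <- roi_set(matrix(FALSE, 9, 9),
                 list(matrix(c(TRUE, rep(FALSE, 80)), 9, 9)), 4.8)
  expect_error(extract_roi_curves(series, big, "ventricles"), "grid")
})

test_that("asl_series enforces shape and protocol consistency", {
  ok <- array(0, c(4, 4, 7, 10))
  expect_s3_class(asl_series(ok, ok, bcsfb_protocol()), "asl_series")
  expect_error(asl_series(ok, array(0, c(4, 4, 7, 9)), bcsfb_protocol()),
               "identical shape")
  expect_error(asl_series(array(0, c(4, 4, 6, 10)),
                          array(0, c(4, 4, 6, 10)), bcsfb_protocol()),
               "TI count")
})

test_that("M0 volume correction follows the volume-ratio law", {
  expect_equal(m0_volume_correct(1000, 86.4, 86.4), 1000)
  expect_equal(m0_volume_correct(1000, 83, 86.4), 1000 * 83 / 86.4)
  expect_equal(m0_volume_correct(1000, 83, 86.4), 960.648,
               tolerance = 1e-6)
  # linear in total ventricular volume
  expect_equal(m0_volume_correct(1000, 2 * 56, 86.4),
               2 * m0_volume_correct(1000, 56, 86.4))
  expect_error(m0_volume_correct(-1, 56, 86.4))
  expect_error(m0_volume_correct(1000, 0, 86.4))
  expect_error(m0_volume_correct(1000, 56, -5))
})
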