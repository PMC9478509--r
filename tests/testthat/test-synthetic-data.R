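test_that("phantom realises the target ventricular volume within one voxel", {
  vox <- (30 / 256)^2 * 0.4
  wky <- build_phantom(phantom_spec("WKY"))
  expect_lt(abs(wky$realized_volume - 56), vox + 1e-9)
  shr <- build_phantom(phantom_spec("SHR"))
  expect_lt(abs(shr$realized_volume - 83), vox + 1e-9)
  expect_equal(sum(wky$t2w$mask), wky$t2w$n_voxels)
  # infeasible geometry is rejected
  expect_error(build_phantom(phantom_spec("SHR",
                                          ventricular_volume = 2000)),
               "not representable")
})

test_that("phantom labels partition the grid and ventricles underlie the ROIs", {
  ph <- build_phantom(phantom_spec("WKY"))
  labels <- ph$asl$labels
  expect_setequal(unique(as.vector(labels)),
                  c("background", "tissue", "cortex", "ventricle"))
  expect_true(all((labels == "background") == !ph$asl$brain))
  # fractions are a partition of unity inside the brain
  tot <- ph$asl$csf_frac + ph$asl$tissue_frac
  expect_equal(tot[ph$asl$brain], rep(1, sum(ph$asl$brain)))
  expect_true(all(tot[!ph$asl$brain] == 0))
  # each 3x3 ventricular ROI covers ventricle signal
  for (m in ph$asl$ventricle_masks) {
    expect_equal(sum(m), 9)
    expect_gt(sum(ph$asl$csf_frac[m]), 0)
  }
  # ASL-grid CSF volume tracks the T2w-grid realisation (partial volume)
  expect_equal(sum(ph$asl$csf_frac) * 4.8, ph$realized_volume,
               tolerance = 0.05)
})

test_that("simulation is reproducible from its seed", {
  ph <- build_phantom(phantom_spec("WKY"))
  a <- simulate_asl_series(ph, "bcsfb", seed = 123)
  b <- simulate_asl_series(ph, "bcsfb", seed = 123)
  expect_identical(a, b)
  c <- simulate_asl_series(ph, "bcsfb", seed = 124)
  expect_false(identical(a$selective, c$selective))
  s1 <- simulate_subject(phantom_spec("SHR"), seed = 9)
  s2 <- simulate_subject(phantom_spec("SHR"), seed = 9)
  expect_identical(s1$bcsfb, s2$bcsfb)
  expect_identical(s1$t2w, s2$t2w)
})

test_that("long-TE variant is CSF-specific: cortical DeltaM is crushed", {
  ph <- build_phantom(phantom_spec("WKY", noise_sd = 0))
  series <- simulate_asl_series(ph, "bcsfb")
  rois <- phantom_rois(ph, 4.8)
  ctx <- extract_roi_curves(series, rois, "cortex")
  expect_true(all(abs(ctx$delta_m$delta_m) < 1e-10))
  # control signal in the cortex is also suppressed at TE = 220 ms
  expect_true(all(abs(ctx$control$mean_signal) < 1e-10))
  # while the short-TE variant carries tissue signal
  std <- extract_roi_curves(simulate_asl_series(ph, "standard"),
                            phantom_rois(ph, 2.4), "cortex")
  expect_gt(max(std$delta_m$delta_m), 1)
  expect_gt(max(abs(std$control$mean_signal)), 100)
})

test_that("noiseless simulated curves equal the generating kinetic model", {
  spec <- phantom_spec("WKY", noise_sd = 0)
  ph <- build_phantom(spec)
  series <- simulate_asl_series(ph, "bcsfb")
  rois <- phantom_rois(ph, 4.8)
  vent <- extract_roi_curves(series, rois, "ventricles")
  # the extracted DeltaM / M0_corr curve must equal the model evaluated
  # with the analysis-convention rate at the protocol TIs
  ir <- fit_inversion_recovery(vent$control)
  m0_corr <- m0_volume_correct(ir$m0, ph$realized_volume,
                               rois$ventricle_roi_volume)
  rate_roi <- spec$total_delivery / (86.4 * 60)
  expected <- bcsfb_csf_signal(
    bcsfb_protocol()$ti_s,
    kinetic_params(rate_roi, t1_dest = spec$t1_csf, m0 = m0_corr)
  )
  expect_equal(vent$delta_m$delta_m, expected, tolerance = 1e-8)
})

test_that("cohort generation: spread modes, truncation logging, metadata", {
  coh0 <- simulate_cohort(n_per_group = 2, seed = 4, spread = "none")
  expect_equal(nrow(coh0$truth), 4)
  expect_setequal(unique(coh0$truth$group), c("WKY", "SHR"))
  wky <- coh0$truth[coh0$truth$group == "WKY", ]
  expect_equal(wky$total_delivery, rep(14.4, 2))
  expect_equal(wky$t1_csf, rep(4.24, 2))
  # group assignment round-trips through subject ids
  expect_true(all(startsWith(coh0$truth$subject_id,
                             tolower(coh0$truth$group))))
  # calibrated spread draws differ between subjects but stay positive
  coh1 <- simulate_cohort(n_per_group = 3, seed = 5)
  expect_gt(sd(coh1$truth$total_delivery[coh1$truth$group == "WKY"]), 0)
  expect_true(all(coh1$truth$total_delivery > 0))
  expect_gte(attr(coh1, "truncations"), 0)
  expect_error(simulate_cohort(n_per_group = 3, spread = "cv"), "cv")
})

test_that("calibrated cohorts reproduce the published delivery SEM in expectation", {
  sems <- vapply(1:50, function(s) {
    coh <- simulate_cohort(n_per_group = 6, seed = 4000 + s,
                           presets = "WKY")
    res <- purrr::map_dfr(coh$subjects, run_subject)
    sd(res$total_delivery) / sqrt(6)
  }, numeric(1))
  expect_lt(abs(mean(sems) / 1.92 - 1), 0.5)
})
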