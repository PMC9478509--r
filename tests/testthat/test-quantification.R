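test_that("fixed-mode BCSFB fit recovers a noiseless generating rate exactly", {
  for (rate in c(5e-4, 2.7778e-3, 1e-2)) {
    curve <- make_bcsfb_curve(rate, t1_csf = 4.24, m0 = 960)
    fit <- fit_bcsfb_rate(curve, t1_csf = 4.24, m0_corr = 960)
    expect_true(fit$converged)
    expect_lt(abs(fit$rate / rate - 1), 1e-6)
    expect_identical(fit$arrival_time, 1.04)
    expect_identical(fit$bolus_duration, 3.66)
    expect_identical(fit$fixed, c("arrival_time", "bolus_duration"))
  }
  # an all-zero curve fits a zero rate, flagged at the lower bound
  zero <- tibble::tibble(ti_s = bcsfb_tis, delta_m = rep(0, 7))
  f0 <- fit_bcsfb_rate(zero, 4.24, 1000)
  expect_equal(f0$rate, 0)
  expect_true(f0$rate_at_bound)
})

test_that("pilot mode frees and recovers arrival time and bolus duration", {
  truth <- list(rate = 3.2e-3, dt = 1.3, tau = 3.1)
  curve <- make_bcsfb_curve(truth$rate, arrival_time = truth$dt,
                            bolus_duration = truth$tau)
  fit <- fit_bcsfb_rate(curve, 4.24, 1000, mode = "pilot")
  expect_true(fit$converged)
  expect_equal(fit$rate, truth$rate, tolerance = 1e-5)
  expect_equal(fit$arrival_time, truth$dt, tolerance = 1e-4)
  expect_equal(fit$bolus_duration, truth$tau, tolerance = 1e-4)
  expect_identical(fit$fixed, character(0))
})

test_that("cortical CBF fit recovers the generating perfusion", {
  rate <- 123 / (0.9 * 6000)
  curve <- make_tissue_curve(rate, t1_cortex = 1.88, m0 = 610)
  fit <- fit_cbf(curve, t1_cortex = 1.88, m0 = 610)
  expect_true(fit$converged)
  expect_lt(abs(fit$rate / rate - 1), 1e-6)
  expect_equal(cbf_in_reporting_units(fit$rate), 123, tolerance = 1e-5)
  # zero perfusion maps to zero CBF
  zero <- tibble::tibble(ti_s = standard_tis, delta_m = rep(0, 8))
  expect_equal(fit_cbf(zero, 1.88, 610)$rate, 0)
})

test_that("fixing the bolus timing shrinks the rate standard error", {
  set.seed(31)
  curve <- make_bcsfb_curve(2.8e-3, m0 = 960)
  curve$delta_m <- curve$delta_m + rnorm(7, 0, 0.03 * max(curve$delta_m))
  fixed <- fit_bcsfb_rate(curve, 4.24, 960, mode = "fixed")
  pilot <- fit_bcsfb_rate(curve, 4.24, 960, mode = "pilot")
  expect_lt(fixed$std_errors[["rate"]], pilot$std_errors[["rate"]])
})

test_that("fit preconditions are enforced", {
  few <- make_bcsfb_curve(2.8e-3)[c(1, 2, 4), ]
  expect_error(fit_bcsfb_rate(few, 4.24, 1000), "beyond the arrival time")
  short <- make_bcsfb_curve(2.8e-3)[1:4, ]
  expect_error(fit_bcsfb_rate(short, 4.24, 1000, mode = "pilot"),
               "at least 5")
  expect_error(fit_bcsfb_rate(make_bcsfb_curve(1e-3), -1, 1000))
  expect_error(fit_cbf(make_tissue_curve(0.02), 1.88, 0))
})

test_that("reporting-unit conversions are the declared linear maps", {
  expect_equal(total_delivery(0), 0)
  expect_equal(total_delivery(2.7778e-3, 86.4), 14.4, tolerance = 1e-4)
  expect_equal(total_delivery(2e-3, 100), 2e-3 * 100 * 60)
  expect_equal(total_delivery(2 * 3e-3), 2 * total_delivery(3e-3))
  expect_equal(cbf_in_reporting_units(0), 0)
  expect_equal(cbf_in_reporting_units(0.02278, 0.9), 123.0,
               tolerance = 1e-3)
  expect_equal(cbf_in_reporting_units(0.01, 1.8),
               2 * cbf_in_reporting_units(0.01, 0.9))
  expect_error(total_delivery(-1))
  expect_error(total_delivery(1e-3, 0))
  expect_error(cbf_in_reporting_units(1e-3, -0.9))
})

test_that("asl_fit tidiers report estimates, fixedness and reporting units", {
  curve <- make_bcsfb_curve(2.8e-3, m0 = 960)
  fit <- fit_bcsfb_rate(curve, 4.24, 960)
  td <- tidy(fit)
  expect_equal(td$term, c("rate", "arrival_time", "bolus_duration"))
  expect_equal(td$fixed, c(FALSE, TRUE, TRUE))
  expect_true(is.na(td$std.error[2]))
  gl <- glance(fit)
  expect_equal(gl$total_delivery, total_delivery(fit$rate))
  gl2 <- glance(fit_cbf(make_tissue_curve(0.02), 1.88, 1000))
  expect_true("cbf" %in% names(gl2))
})
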