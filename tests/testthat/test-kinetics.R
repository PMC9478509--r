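test_that("closed-form inflow integral matches adaptive quadrature on random draws", {
  set.seed(42)
  for (i in 1:300) {
    t1b <- runif(1, 0.5, 3)
    t1d <- runif(1, 0.5, 5.5)
    ti <- runif(1, 0.5, 8)
    a <- runif(1, 0, ti)
    b <- runif(1, a, ti)
    closed <- inflow_integral(a, b, ti, t1b, t1d)
    quad <- inflow_integral_quadrature(a, b, ti, t1b, t1d)
    if (quad > 1e-12) {
      expect_lt(abs(closed - quad) / quad, 1e-8)
    } else {
      expect_lt(abs(closed - quad), 1e-12)
    }
  }
})

test_that("inflow integral: degenerate branch, exact values and error contracts", {
  # empty interval
  expect_identical(inflow_integral(1.5, 1.5, 2, 2.4, 4.24), 0)
  # equal T1s: the degenerate closed form exp(-ti/T1) * (b - a)
  expect_equal(inflow_integral(1, 2, 2, 2, 2), exp(-1), tolerance = 1e-12)
  # continuity across the k -> 0 branch switch
  t1d_plus <- 1 / (1 / 2.4 + 5e-10)
  t1d_minus <- 1 / (1 / 2.4 - 5e-10)
  v0 <- inflow_integral(0.5, 2, 3, 2.4, 2.4)
  expect_equal(inflow_integral(0.5, 2, 3, 2.4, t1d_plus), v0,
               tolerance = 1e-6)
  expect_equal(inflow_integral(0.5, 2, 3, 2.4, t1d_minus), v0,
               tolerance = 1e-6)
  # the long-TI BCSFB configuration against the quadrature oracle
  closed <- inflow_integral(1.04, 4, 4, 2.4, 4.24)
  quad <- inflow_integral_quadrature(1.04, 4, 4, 2.4, 4.24)
  expect_lt(abs(closed - quad) / quad, 1e-8)
  expect_error(inflow_integral(2, 1, 3, 2.4, 4.24))
  expect_error(inflow_integral(0, 1, 2, -1, 4.24))
})

test_that("CSF signal model: piecewise bolus structure, linearity, positivity", {
  p <- kinetic_params(2.778e-3, t1_dest = 4.24, m0 = 1000)
  # zero before bolus arrival (arrival_time = 1.04 s)
  expect_identical(bcsfb_csf_signal(0.2, p), 0)
  # zero delivery, zero signal everywhere
  p0 <- kinetic_params(0, t1_dest = 4.24, m0 = 1000)
  expect_identical(bcsfb_csf_signal(bcsfb_tis, p0), rep(0, 7))
  # hand-derived degenerate value: 2 * 0.001 * exp(-1)
  pd <- kinetic_params(0.001, t1_dest = 2, m0 = 1, arrival_time = 1,
                       bolus_duration = 3, t1_blood = 2)
  expect_equal(bcsfb_csf_signal(2, pd), 2 * 0.001 * exp(-1),
               tolerance = 1e-12)
  # exact linearity in rate, m0, alpha
  ti <- seq(0, 8, by = 0.5)
  base <- bcsfb_csf_signal(ti, kinetic_params(1e-3, 4.24, 500, alpha = 0.5))
  expect_equal(bcsfb_csf_signal(ti, kinetic_params(3e-3, 4.24, 500,
                                                   alpha = 0.5)),
               3 * base, tolerance = 1e-12)
  expect_equal(bcsfb_csf_signal(ti, kinetic_params(1e-3, 4.24, 1500,
                                                   alpha = 0.5)),
               3 * base, tolerance = 1e-12)
  expect_equal(bcsfb_csf_signal(ti, kinetic_params(1e-3, 4.24, 500,
                                                   alpha = 1)),
               2 * base, tolerance = 1e-12)
  # non-negative everywhere, decaying to zero at long TI
  curve <- bcsfb_csf_signal(seq(0, 60, by = 0.25), p)
  expect_true(all(curve >= 0))
  expect_lt(curve[length(curve)], 1e-4 * max(curve))
})

test_that("signal is continuous at bolus arrival and bolus end", {
  for (pars in list(
    kinetic_params(2.8e-3, 4.24, 1000),
    kinetic_params(0.0228, 1.88, 800, arrival_time = 0.3,
                   bolus_duration = 2.5)
  )) {
    eps <- 1e-9
    for (knot in c(pars$arrival_time,
                   pars$arrival_time + pars$bolus_duration)) {
      lo <- bcsfb_csf_signal(max(knot - eps, 0), pars)
      hi <- bcsfb_csf_signal(knot + eps, pars)
      expect_lt(abs(hi - lo), 1e-6 * max(pars$m0 * pars$delivery_rate, 1))
    }
  }
})

test_that("tissue model reduces to the CSF model without clearance and matches quadrature", {
  rate <- 123 / (0.9 * 6000)
  p <- kinetic_params(rate, t1_dest = 1.88, m0 = 1000, arrival_time = 0.3,
                      bolus_duration = 3.66)
  ti <- seq(0, 8, by = 0.25)
  # lambda -> Inf removes the clearance term exactly
  expect_equal(pasl_tissue_signal(ti, p, lambda = 1e12),
               bcsfb_csf_signal(ti, p), tolerance = 1e-9)
  # closed form against quadrature at the apparent T1
  t1_app <- 1 / (1 / 1.88 + rate / 0.9)
  ti0 <- 2
  expected <- 2 * 1000 * rate *
    inflow_integral_quadrature(0.3, ti0, ti0, 2.4, t1_app)
  expect_equal(pasl_tissue_signal(ti0, p, 0.9), expected,
               tolerance = 1e-8)
})

test_that("long CSF T1 delays time-to-peak and slows post-peak decay versus cortex", {
  ti <- seq(0, 10, by = 0.01)
  shared <- list(delivery_rate = 2.8e-3, m0 = 1000, arrival_time = 1.04,
                 bolus_duration = 3.66)
  csf <- bcsfb_csf_signal(ti, do.call(kinetic_params,
                                      c(shared, t1_dest = 4.24)))
  ctx <- bcsfb_csf_signal(ti, do.call(kinetic_params,
                                      c(shared, t1_dest = 1.88)))
  i_csf <- which.max(csf)
  i_ctx <- which.max(ctx)
  expect_gt(ti[i_csf], ti[i_ctx])
  # post-peak log-decay rate is strictly slower for CSF
  tail_idx <- ti >= 6
  slope <- function(y) coef(lm(log(y[tail_idx]) ~ ti[tail_idx]))[2]
  expect_gt(slope(csf), slope(ctx))
})

test_that("kinetic_params enforces its invariants", {
  expect_error(kinetic_params(-1, 4.24, 1000))
  expect_error(kinetic_params(1e-3, -4.24, 1000))
  expect_error(kinetic_params(1e-3, 4.24, 0))
  expect_error(kinetic_params(1e-3, 4.24, 1000, alpha = 1.2))
  expect_error(kinetic_params(1e-3, 4.24, 1000, bolus_duration = 0))
  expect_s3_class(kinetic_params(0, 4.24, 1), "kinetic_params")
})
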