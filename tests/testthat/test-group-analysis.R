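test_that("summary-statistic t-test matches stats::t.test on reconstructed samples", {
  set.seed(12)
  for (i in 1:25) {
    n1 <- sample(3:9, 1); n2 <- sample(3:9, 1)
    m1 <- runif(1, -5, 20); m2 <- runif(1, -5, 20)
    s1 <- runif(1, 0.5, 4); s2 <- runif(1, 0.5, 4)
    x1 <- make_sample(n1, m1, s1)
    x2 <- make_sample(n2, m2, s2)
    ref <- stats::t.test(x1, x2, var.equal = TRUE)
    got <- students_t(mean(x1), sd(x1) / sqrt(n1), n1,
                      mean(x2), sd(x2) / sqrt(n2), n2)
    expect_equal(got$t, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(got$df, unname(ref$parameter))
    expect_equal(got$p, ref$p.value, tolerance = 1e-10)
  }
})

test_that("t-test edge cases: identical groups, degenerate variance, bad input", {
  same <- students_t(5, 1, 6, 5, 1, 6)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  ident <- students_t(5, 0, 6, 5, 0, 6)
  expect_equal(ident$p, 1)
  expect_warning(deg <- students_t(5, 0, 6, 7, 0, 6), "zero pooled")
  expect_equal(deg$p, 0)
  expect_true(deg$degenerate)
  expect_error(students_t(5, 1, 1, 7, 1, 6))
  expect_error(students_t(5, -1, 6, 7, 1, 6))
})

test_that("percent and fold change follow their definitions", {
  expect_equal(percent_change(10, 10), 0)
  expect_equal(percent_change(14.4, 9.22), 35.97, tolerance = 1e-3)
  expect_equal(percent_change(10, 14), -percent_change(10, 6))
  expect_error(percent_change(0, 5))
  expect_equal(fold_change(7, 7), 1)
  expect_equal(fold_change(83, 56), 1.482, tolerance = 1e-3)
  expect_equal(fold_change(3, 7) * fold_change(7, 3), 1)
  expect_error(fold_change(5, 0))
})

test_that("published summaries reproduce the study's significance pattern", {
  comp <- compare_groups_summary(reported_group_summaries(),
                                 reference = "WKY")
  p <- setNames(comp$p, comp$metric)
  expect_lt(p[["total_delivery"]], 0.05)
  expect_lt(p[["t1_csf"]], 0.01)
  expect_lt(p[["ventricular_volume"]], 0.001)
  expect_gt(p[["cbf"]], 0.05)
  expect_gt(p[["t1_cortex"]], 0.05)
  # delivery reduction and ventriculomegaly from the same table
  del <- comp[comp$metric == "total_delivery", ]
  expect_equal(del$percent_change, 35.97, tolerance = 1e-3)
  vol <- comp[comp$metric == "ventricular_volume", ]
  expect_equal(vol$fold_change, 83 / 56, tolerance = 1e-10)
})

test_that("subject-level and summary-level comparisons agree", {
  df <- dplyr::bind_rows(
    tibble::tibble(group = "WKY", delivery = make_sample(6, 14.4, 4.7)),
    tibble::tibble(group = "SHR", delivery = make_sample(6, 9.22, 2.94))
  )
  c1 <- compare_groups(df, reference = "WKY")
  summ <- df |>
    dplyr::group_by(group) |>
    dplyr::summarise(mean = mean(delivery),
                     sem = sd(delivery) / sqrt(dplyr::n()),
                     n = dplyr::n()) |>
    dplyr::mutate(metric = "delivery")
  c2 <- compare_groups_summary(summ, reference = "WKY")
  expect_equal(c1$t, c2$t, tolerance = 1e-10)
  expect_equal(c1$p, c2$p, tolerance = 1e-10)
  expect_error(compare_groups(df[df$group == "WKY", ]), "two levels")
})

test_that("blood-pressure summaries carry the expected structure", {
  bp <- blood_pressure_summaries()
  expect_setequal(unique(bp$group), c("WKY", "SHR"))
  wky_pulse <- bp[bp$metric == "pulse_pressure" & bp$group == "WKY", ]
  # pulse pressure equals the printed systolic - diastolic difference
  sysd <- bp[bp$group == "WKY" & bp$metric %in% c("systolic", "diastolic"), ]
  expect_equal(wky_pulse$mean, max(sysd$mean) - min(sysd$mean))
})
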