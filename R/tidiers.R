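#' Tidy an inversion-recovery fit
#'
#' @param x An `ir_fit`.
#' @param ... Unused.
#' @return A tibble with one row per parameter: `term`, `estimate`,
#'   `std.error`, `fixed`.
#' @export
tidy.ir_fit <- function(x, ...) {
  terms <- c("t1", "m0", if (!x$beta_fixed) "beta")
  tibble::tibble(
    term = c("t1", "m0", "beta"),
    estimate = c(x$t1, x$m0, x$beta),
    std.error = unname(x$std_errors[match(c("t1", "m0", "beta"), terms)]),
    fixed = c(FALSE, FALSE, x$beta_fixed)
  )
}

#' @rdname tidy.ir_fit
#' @return `glance()` returns a one-row fit summary.
#' @export
glance.ir_fit <- function(x, ...) {
  tibble::tibble(
    t1 = x$t1, m0 = x$m0, beta = x$beta,
    residual_norm = x$residual_norm,
    converged = x$converged, n_ti = x$n_ti
  )
}

#' Tidy a fitted ASL kinetic model
#'
#' @param x An `asl_fit`.
#' @param ... Unused.
#' @return A tibble with one row per kinetic parameter: `term`, `estimate`,
#'   `std.error` (NA for parameters held fixed), `fixed`.
#' @export
tidy.asl_fit <- function(x, ...) {
  terms <- c("rate", "arrival_time", "bolus_duration")
  est <- c(x$rate, x$arrival_time, x$bolus_duration)
  se <- unname(x$std_errors[match(terms, names(x$std_errors))])
  tibble::tibble(
    term = terms, estimate = est, std.error = se,
    fixed = terms %in% x$fixed
  )
}

#' @rdname tidy.asl_fit
#' @return `glance()` returns a one-row summary including the rate in
#'   reporting units (`total_delivery` in ul/min for the BCSFB model, `cbf`
#'   in ml/min/100 g for the tissue model).
#' @export
glance.asl_fit <- function(x, ...) {
  out <- tibble::tibble(
    model = x$model, mode = x$inputs$mode, rate = x$rate,
    arrival_time = x$arrival_time, bolus_duration = x$bolus_duration,
    residual_norm = x$residual_norm, converged = x$converged,
    rate_at_bound = x$rate_at_bound, n_ti = x$n_ti
  )
  if (x$model == "bcsfb") {
    out$total_delivery <- total_delivery(x$rate)
  } else {
    out$cbf <- cbf_in_reporting_units(x$rate, x$inputs$lambda)
  }
  out
}

#' Tidy a cohort result
#'
#' @param x A `cohort_result`.
#' @param ... Unused.
#' @return The group-comparison tibble (one row per metric).
#' @export
tidy.cohort_result <- function(x, ...) {
  tibble::as_tibble(x$comparison)
}

#' @rdname tidy.cohort_result
#' @return `glance()` returns a one-row cohort summary.
#' @export
glance.cohort_result <- function(x, ...) {
  tibble::tibble(
    n_subjects = nrow(x$subjects),
    n_failed = sum(!x$status$ok),
    reference = x$reference,
    n_significant = sum(x$comparison$p < 0.05)
  )
}
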