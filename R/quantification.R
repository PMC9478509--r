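new_asl_fit <- function(model, fit, rate_bounded, arrival_time, bolus_duration,
                        fixed, inputs, curve) {
  structure(
    list(
      model = model,
      rate = unname(fit$par[["rate"]]),
      arrival_time = arrival_time,
      bolus_duration = bolus_duration,
      fixed = fixed,
      std_errors = fit$std_errors,
      residual_norm = fit$residual_norm,
      converged = fit$converged,
      rate_at_bound = rate_bounded,
      inputs = inputs,
      n_ti = fit$n,
      data = tibble::as_tibble(curve)
    ),
    class = "asl_fit"
  )
}

rate_init_from_peak <- function(curve, alpha, m0) {
  peak <- which.max(curve$delta_m)
  init <- curve$delta_m[peak] / (2 * alpha * m0 * curve$ti_s[peak])
  min(max(init, 1e-6), 1)
}

# Starting points for the 3-parameter (rate, arrival, duration) fit. The
# arrival time is weakly identified from sparse TI schedules and the
# least-squares surface has local minima in (arrival, duration), so the fit
# is restarted from a grid of arrival-time starts (including every pre-peak
# TI); the lowest-residual solution wins.
free_fit_starts <- function(ti, y, rate0) {
  peak <- which.max(y)
  dts <- sort(unique(pmin(pmax(
    c(0.1, 0.5, 1, 1.5, 2, ti[ti < ti[peak]]), 0), 2.9)))
  lapply(dts, function(dt) {
    c(rate = rate0, arrival_time = dt, bolus_duration = 3)
  })
}

best_free_fit <- function(ti, y, rate0, model, weights) {
  fits <- lapply(free_fit_starts(ti, y, rate0), function(st) {
    # the signal is exactly linear in the rate, so the optimal rate for
    # this (arrival, duration) start is the least-squares projection
    m1 <- model(c(rate = 1, st[c("arrival_time", "bolus_duration")]))
    denom <- sum(m1^2)
    if (denom > 0) {
      st[["rate"]] <- min(max(sum(y * m1) / denom, 1e-8), 1)
    }
    lm_fit(st,
           lower = c(rate = 0, arrival_time = 0, bolus_duration = 0.5),
           upper = c(rate = 1, arrival_time = 3, bolus_duration = 8),
           model = model, observed = y, weights = weights)
  })
  fits[[which.min(vapply(fits, function(f) f$residual_norm, numeric(1)))]]
}

#' Fit the BCSFB water-delivery rate to a ventricular DeltaM curve
#'
#' Nonlinear least squares of [bcsfb_csf_signal()] against a
#' repetition-averaged `[TI, DeltaM]` curve. The subject's `T1_CSF` and
#' volume-corrected `M0_corr` (from the inversion-recovery fit and
#' [m0_volume_correct()]) enter as fixed inputs; the fit is not a joint fit.
#'
#' Two modes mirror the two phases of the measurement protocol:
#' * `"fixed"` (default): bolus arrival time and duration are held at the
#'   pilot-optimised values (defaults 1.04 s and 3.66 s) and only the
#'   delivery rate is free, for maximum precision;
#' * `"pilot"`: `rate`, `arrival_time` and `bolus_duration` are all free
#'   (the parameter-optimisation configuration).
#'
#' Bounds: rate in `[0, 1]` s^-1, arrival time in `[0, 3]` s, bolus duration
#' in `[0.5, 8]` s. The rate is initialised from the peak signal as
#' `peak DeltaM / (2 * alpha * m0 * peak TI)`. Solutions pinned at the zero
#' lower bound are flagged via `rate_at_bound`.
#'
#' @param curve Data frame with columns `ti_s` and `delta_m` (the `delta_m`
#'   element of [extract_roi_curves()]).
#' @param t1_csf Subject `T1_CSF` (s), from the ventricular IR fit.
#' @param m0_corr Volume-corrected equilibrium magnetization (signal units).
#' @param mode `"fixed"` or `"pilot"` (see Details).
#' @param arrival_time,bolus_duration Values held fixed in `"fixed"` mode
#'   (defaults 1.04 s / 3.66 s); starting values are 0.5 s / 3 s in
#'   `"pilot"` mode.
#' @param t1_blood Arterial blood T1 (s), default 2.4.
#' @param alpha Inversion efficiency, default 1.
#' @param weights Optional per-TI weights.
#' @return An object of class `asl_fit`; see [tidy.asl_fit()],
#'   [glance.asl_fit()], [total_delivery()].
#' @export
fit_bcsfb_rate <- function(curve, t1_csf, m0_corr,
                           mode = c("fixed", "pilot"),
                           arrival_time = 1.04, bolus_duration = 3.66,
                           t1_blood = 2.4, alpha = 1, weights = NULL) {
  mode <- match.arg(mode)
  stopifnot(is.data.frame(curve),
            all(c("ti_s", "delta_m") %in% names(curve)),
            t1_csf > 0, m0_corr > 0)
  ti <- curve$ti_s
  y <- curve$delta_m
  if (mode == "fixed" && sum(ti > arrival_time) < 3L) {
    abort("need at least 3 TIs beyond the arrival time in fixed mode.")
  }
  if (mode == "pilot" && length(ti) < 5L) {
    abort("need at least 5 TIs for the 3-parameter pilot fit.")
  }
  rate0 <- rate_init_from_peak(curve, alpha, m0_corr)
  mkpar <- function(rate, dt, tau) {
    kinetic_params(rate, t1_dest = t1_csf, m0 = m0_corr,
                   arrival_time = dt, bolus_duration = tau,
                   t1_blood = t1_blood, alpha = alpha)
  }
  if (mode == "fixed") {
    fit <- lm_fit(
      c(rate = rate0), lower = c(rate = 0), upper = c(rate = 1),
      model = function(par) {
        bcsfb_csf_signal(ti, mkpar(par[["rate"]], arrival_time,
                                   bolus_duration))
      },
      observed = y, weights = weights
    )
    dt_hat <- arrival_time; tau_hat <- bolus_duration
    fixed <- c("arrival_time", "bolus_duration")
  } else {
    fit <- best_free_fit(
      ti, y, rate0,
      model = function(par) {
        bcsfb_csf_signal(ti, mkpar(par[["rate"]], par[["arrival_time"]],
                                   par[["bolus_duration"]]))
      },
      weights = weights
    )
    dt_hat <- unname(fit$par[["arrival_time"]])
    tau_hat <- unname(fit$par[["bolus_duration"]])
    fixed <- character(0)
  }
  if (!fit$converged) warn("BCSFB rate fit did not converge.")
  new_asl_fit(
    "bcsfb", fit, rate_bounded = fit$par[["rate"]] <= 0,
    arrival_time = dt_hat, bolus_duration = tau_hat, fixed = fixed,
    inputs = list(t1_dest = t1_csf, m0 = m0_corr, t1_blood = t1_blood,
                  alpha = alpha, lambda = NA_real_, mode = mode),
    curve = curve
  )
}

#' Fit cortical perfusion to a standard-ASL DeltaM curve
#'
#' Nonlinear least squares of the single-compartment Buxton model
#' ([pasl_tissue_signal()]) against the cortical `[TI, DeltaM]` curve, with
#' the subject's cortical `T1` and fitted `M0` as fixed inputs. By default
#' all three kinetic parameters (rate, arrival time, bolus duration) are
#' free (`mode = "pilot"`); `mode = "fixed"` holds arrival time and bolus
#' duration at the supplied values. Bounds and initialisation as in
#' [fit_bcsfb_rate()]. Convert the fitted rate with
#' [cbf_in_reporting_units()].
#'
#' @inheritParams fit_bcsfb_rate
#' @param t1_cortex Cortical tissue T1 (s), from the short-TE IR fit.
#' @param m0 Fitted cortical equilibrium magnetization (signal units).
#' @param lambda Blood-tissue water partition coefficient (ml/g), default 0.9.
#' @param arrival_time,bolus_duration Values held fixed in `"fixed"` mode
#'   (tissue defaults 0.3 s / 3.66 s).
#' @return An object of class `asl_fit`.
#' @export
fit_cbf <- function(curve, t1_cortex, m0,
                    mode = c("pilot", "fixed"), lambda = 0.9,
                    arrival_time = 0.3, bolus_duration = 3.66,
                    t1_blood = 2.4, alpha = 1, weights = NULL) {
  mode <- match.arg(mode)
  stopifnot(is.data.frame(curve),
            all(c("ti_s", "delta_m") %in% names(curve)),
            t1_cortex > 0, m0 > 0, lambda > 0)
  ti <- curve$ti_s
  y <- curve$delta_m
  if (mode == "fixed" && sum(ti > arrival_time) < 3L) {
    abort("need at least 3 TIs beyond the arrival time in fixed mode.")
  }
  if (mode == "pilot" && length(ti) < 5L) {
    abort("need at least 5 TIs for the 3-parameter fit.")
  }
  rate0 <- rate_init_from_peak(curve, alpha, m0)
  mkpar <- function(rate, dt, tau) {
    kinetic_params(rate, t1_dest = t1_cortex, m0 = m0,
                   arrival_time = dt, bolus_duration = tau,
                   t1_blood = t1_blood, alpha = alpha)
  }
  if (mode == "fixed") {
    fit <- lm_fit(
      c(rate = rate0), lower = c(rate = 0), upper = c(rate = 1),
      model = function(par) {
        pasl_tissue_signal(ti, mkpar(par[["rate"]], arrival_time,
                                     bolus_duration), lambda)
      },
      observed = y, weights = weights
    )
    dt_hat <- arrival_time; tau_hat <- bolus_duration
    fixed <- c("arrival_time", "bolus_duration")
  } else {
    fit <- best_free_fit(
      ti, y, rate0,
      model = function(par) {
        pasl_tissue_signal(ti, mkpar(par[["rate"]], par[["arrival_time"]],
                                     par[["bolus_duration"]]), lambda)
      },
      weights = weights
    )
    dt_hat <- unname(fit$par[["arrival_time"]])
    tau_hat <- unname(fit$par[["bolus_duration"]])
    fixed <- character(0)
  }
  if (!fit$converged) warn("CBF fit did not converge.")
  new_asl_fit(
    "tissue", fit, rate_bounded = fit$par[["rate"]] <= 0,
    arrival_time = dt_hat, bolus_duration = tau_hat, fixed = fixed,
    inputs = list(t1_dest = t1_cortex, m0 = m0, t1_blood = t1_blood,
                  alpha = alpha, lambda = lambda, mode = mode),
    curve = curve
  )
}

#' Total BCSFB-mediated water delivery
#'
#' Scales the fitted per-second delivery rate by the functional ROI volume
#' to the total delivery of labelled water to the lateral ventricles:
#' `total = rate * volume * 60`, in microlitres per minute (1 mm^3 of CSF is
#' taken as 1 ul of water-equivalent volume; no density correction).
#'
#' @param fitted_rate Delivery rate (s^-1), `>= 0`.
#' @param functional_roi_volume Functional ROI volume (mm^3), `> 0`;
#'   default 86.4 (two 3x3 voxel ROIs at 1 x 1 x 4.8 mm).
#' @return Total delivery in ul/min.
#' @export
#' @examples
#' total_delivery(2.7778e-3) # ~14.4 ul/min
total_delivery <- function(fitted_rate, functional_roi_volume = 86.4) {
  if (any(fitted_rate < 0)) abort("`fitted_rate` must be non-negative.")
  if (any(functional_roi_volume <= 0)) abort("ROI volume must be positive.")
  fitted_rate * functional_roi_volume * 60
}

#' Convert a fitted tissue delivery rate to CBF reporting units
#'
#' `CBF = rate * lambda * 6000` converts the fitted per-second rate
#' (fraction of tissue M0 delivered per second, i.e. f/lambda) to
#' ml/min/100 g via the blood-tissue water partition coefficient.
#'
#' @param fitted_rate Delivery rate (s^-1), `>= 0`.
#' @param partition_coefficient_lambda Partition coefficient (ml/g), `> 0`;
#'   default 0.9.
#' @return CBF in ml/min/100 g.
#' @export
#' @examples
#' cbf_in_reporting_units(0.02278) # ~123 ml/min/100 g
cbf_in_reporting_units <- function(fitted_rate,
                                   partition_coefficient_lambda = 0.9) {
  if (any(fitted_rate < 0)) abort("`fitted_rate` must be non-negative.")
  if (any(partition_coefficient_lambda <= 0)) {
    abort("`partition_coefficient_lambda` must be positive.")
  }
  fitted_rate * partition_coefficient_lambda * 6000
}

#' Predict from a fitted ASL kinetic model
#'
#' @param object An `asl_fit`.
#' @param ti Inflow times (s); defaults to the fitted TIs.
#' @param ... Unused.
#' @return Predicted DeltaM values.
#' @export
predict.asl_fit <- function(object, ti = object$data$ti_s, ...) {
  p <- kinetic_params(
    object$rate, t1_dest = object$inputs$t1_dest, m0 = object$inputs$m0,
    arrival_time = object$arrival_time,
    bolus_duration = object$bolus_duration,
    t1_blood = object$inputs$t1_blood, alpha = object$inputs$alpha
  )
  if (object$model == "tissue") {
    pasl_tissue_signal(ti, p, object$inputs$lambda)
  } else {
    bcsfb_csf_signal(ti, p)
  }
}

#' @export
print.asl_fit <- function(x, ...) {
  cat(sprintf("<asl_fit: %s, %s mode>%s\n", x$model, x$inputs$mode,
              if (!x$converged) " (NOT converged)" else ""))
  cat(sprintf("  rate = %.5g s^-1 (SE %.3g)%s\n", x$rate,
              x$std_errors[["rate"]],
              if (isTRUE(x$rate_at_bound)) " [at zero bound]" else ""))
  cat(sprintf("  arrival %.3g s%s, bolus %.3g s%s\n",
              x$arrival_time,
              if ("arrival_time" %in% x$fixed) " (fixed)" else "",
              x$bolus_duration,
              if ("bolus_duration" %in% x$fixed) " (fixed)" else ""))
  if (x$model == "bcsfb") {
    cat(sprintf("  total delivery (86.4 mm^3): %.4g ul/min\n",
                total_delivery(x$rate)))
  } else {
    cat(sprintf("  CBF: %.4g ml/min/100 g\n",
                cbf_in_reporting_units(x$rate, x$inputs$lambda)))
  }
  invisible(x)
}
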