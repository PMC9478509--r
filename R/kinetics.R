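#' Kinetic model parameters for ASL signal models
#'
#' Bundles the parameters shared by the single-compartment (cortical tissue)
#' and two-compartment (ventricular CSF) pulsed-ASL kinetic models.
#'
#' @param delivery_rate Delivery rate in s^-1: the fraction of the destination
#'   compartment's equilibrium magnetization delivered per second. For the
#'   tissue model this is f/lambda (perfusion over the blood-tissue water
#'   partition coefficient); see [cbf_in_reporting_units()].
#' @param t1_dest Longitudinal relaxation time (s) of the destination
#'   compartment: `T1_CSF` for the BCSFB model, cortical `T1` for the tissue
#'   model (the apparent `T1'` including venous clearance is derived
#'   internally by [pasl_tissue_signal()]).
#' @param m0 Equilibrium magnetization of the destination compartment, in
#'   arbitrary signal units (`M0` for tissue, volume-corrected `M0_corr` for
#'   ventricular CSF; see [m0_volume_correct()]).
#' @param arrival_time Bolus arrival time Delta-t (s). Default 1.04 s, the
#'   value fixed for BCSFB fits after pilot optimization.
#' @param bolus_duration Temporal length tau (s) of the labelled bolus.
#'   Default 3.66 s, fixed after pilot optimization.
#' @param t1_blood Longitudinal relaxation time of arterial blood (s).
#'   Default 2.4 s (literature value at 9.4 T).
#' @param alpha Inversion efficiency in (0, 1]. Default 1 (adiabatic FAIR
#'   inversion assumed perfect).
#'
#' @return An object of class `kinetic_params` (a validated list).
#' @seealso [bcsfb_csf_signal()], [pasl_tissue_signal()]
#' @export
#' @examples
#' kinetic_params(delivery_rate = 2.78e-3, t1_dest = 4.24, m0 = 1000)
kinetic_params <- function(delivery_rate, t1_dest, m0,
                           arrival_time = 1.04, bolus_duration = 3.66,
                           t1_blood = 2.4, alpha = 1) {
  stopifnot(
    is.numeric(delivery_rate), length(delivery_rate) == 1L, delivery_rate >= 0,
    is.numeric(t1_dest), t1_dest > 0,
    is.numeric(m0), m0 > 0,
    is.numeric(arrival_time), arrival_time >= 0,
    is.numeric(bolus_duration), bolus_duration > 0,
    is.numeric(t1_blood), t1_blood > 0,
    is.numeric(alpha), alpha > 0, alpha <= 1
  )
  structure(
    list(
      delivery_rate = delivery_rate, t1_dest = t1_dest, m0 = m0,
      arrival_time = arrival_time, bolus_duration = bolus_duration,
      t1_blood = t1_blood, alpha = alpha
    ),
    class = "kinetic_params"
  )
}

#' Labelled-inflow relaxation integral (closed form)
#'
#' The kernel shared by both pulsed-ASL models:
#' `I = int_a^b exp(-s/T1b) * exp(-(ti - s)/T1d) ds`,
#' i.e. labelled spins relax at the blood `T1b` until delivery at time `s`,
#' then at the destination-compartment `T1d` until readout at `ti`.
#'
#' The closed form `exp(-ti/T1d) * (exp(k*b) - exp(k*a)) / k` with
#' `k = 1/T1d - 1/T1b` suffers catastrophic cancellation as `k -> 0`, so for
#' `|k| < k_tol` the degenerate limit `exp(-ti/T1d) * (b - a)` is used; the
#' two branches agree continuously at the switch.
#'
#' @param a,b Integration limits (s), `0 <= a <= b <= ti`.
#' @param ti Inflow time (s) at readout.
#' @param t1_blood,t1_dest Relaxation times (s) of arterial blood and of the
#'   destination compartment.
#' @param k_tol Switch point to the degenerate form (s^-1). Default 1e-9.
#'
#' @return The dimensionless integral value (vectorised over `a`, `b`, `ti`).
#' @seealso [inflow_integral_quadrature()] for the independent numerical check.
#' @export
#' @examples
#' inflow_integral(1, 2, ti = 2, t1_blood = 2, t1_dest = 2) # exp(-1)
inflow_integral <- function(a, b, ti, t1_blood, t1_dest, k_tol = 1e-9) {
  if (any(t1_blood <= 0) || any(t1_dest <= 0)) {
    abort("`t1_blood` and `t1_dest` must be positive.")
  }
  n <- max(length(a), length(b), length(ti))
  a <- rep_len(a, n); b <- rep_len(b, n); ti <- rep_len(ti, n)
  if (any(a > b + 1e-12)) abort("`a` must not exceed `b`.")
  if (any(a < -1e-12) || any(b > ti + 1e-9)) {
    abort("limits must satisfy 0 <= a <= b <= ti.")
  }
  k <- 1 / t1_dest - 1 / t1_blood
  pre <- exp(-ti / t1_dest)
  if (abs(k) < k_tol) {
    pre * (b - a)
  } else {
    pre * (exp(k * b) - exp(k * a)) / k
  }
}

#' Labelled-inflow relaxation integral by adaptive quadrature
#'
#' Independent numerical evaluation of the same integrand as
#' [inflow_integral()], via [stats::integrate()]. Used as the arbiter for the
#' closed form; not vectorised and not intended for fitting.
#'
#' @inheritParams inflow_integral
#' @param rel_tol Relative tolerance passed to [stats::integrate()].
#' @return The integral value (scalar).
#' @export
inflow_integral_quadrature <- function(a, b, ti, t1_blood, t1_dest,
                                       rel_tol = 1e-12) {
  stopifnot(length(a) == 1L, length(b) == 1L, length(ti) == 1L,
            a <= b, t1_blood > 0, t1_dest > 0)
  if (a == b) return(0)
  f <- function(s) exp(-s / t1_blood) * exp(-(ti - s) / t1_dest)
  integrate(f, lower = a, upper = b, rel.tol = rel_tol,
            abs.tol = 0, subdivisions = 500L)$value
}

# Shared piecewise bolus structure: zero before arrival, inflow window capped
# at arrival_time + bolus_duration, no outflow from the destination pool.
signal_kernel <- function(ti, rate, m0, alpha, dt, tau, t1_blood, t1_dest) {
  stopifnot(is.numeric(ti), all(ti >= 0))
  dm <- numeric(length(ti))
  active <- ti > dt
  if (any(active)) {
    tia <- ti[active]
    upper <- pmin(tia, dt + tau)
    dm[active] <- 2 * alpha * m0 * rate *
      inflow_integral(dt, upper, tia, t1_blood, t1_dest)
  }
  dm
}

#' Two-compartment BCSFB-ASL signal model (ventricular CSF)
#'
#' Perfusion-weighted signal `DeltaM(ti)` for labelled arterial water
#' delivered across the blood-CSF barrier into ventricular CSF. Labelled
#' spins relax at `t1_blood` until delivery, then at `T1_CSF`
#' (`p$t1_dest`); the CSF pool has no outflow term, so
#' `DeltaM(ti) = 2 * alpha * m0 * rate * I(dt, min(ti, dt + tau), ti)` for
#' `ti > dt` and 0 before bolus arrival.
#'
#' @param ti Inflow time(s) in seconds, `>= 0`.
#' @param p A [kinetic_params()] object with `t1_dest = T1_CSF` and
#'   `m0 = M0_corr`.
#' @return `DeltaM` in the units of `p$m0` (vectorised over `ti`).
#' @export
#' @examples
#' p <- kinetic_params(2.78e-3, t1_dest = 4.24, m0 = 1000)
#' bcsfb_csf_signal(c(0.2, 2, 4, 6), p)
bcsfb_csf_signal <- function(ti, p) {
  stopifnot(inherits(p, "kinetic_params"))
  signal_kernel(ti, p$delivery_rate, p$m0, p$alpha,
                p$arrival_time, p$bolus_duration, p$t1_blood, p$t1_dest)
}

#' Single-compartment Buxton pulsed-ASL signal model (cortical tissue)
#'
#' Perfusion-weighted signal for labelled blood water exchanging into
#' cortical tissue. Identical inflow structure to [bcsfb_csf_signal()], but
#' the destination compartment relaxes at the apparent tissue time
#' `1/T1' = 1/T1_cortex + delivery_rate/lambda`, which folds venous clearance
#' of labelled water into an effective relaxation rate (the Buxton
#' pulsed-ASL q-factor solution is this same integral in closed form). As
#' `lambda -> Inf` (no clearance) the model reduces exactly to
#' [bcsfb_csf_signal()] with `t1_dest = T1_cortex`.
#'
#' @inheritParams bcsfb_csf_signal
#' @param p A [kinetic_params()] object with `t1_dest = T1_cortex` and `m0`
#'   the (blood-scaled) tissue equilibrium magnetization.
#' @param lambda Blood-tissue water partition coefficient (ml/g), default 0.9.
#' @return `DeltaM` in the units of `p$m0` (vectorised over `ti`).
#' @export
pasl_tissue_signal <- function(ti, p, lambda = 0.9) {
  stopifnot(inherits(p, "kinetic_params"), is.numeric(lambda), lambda > 0)
  t1_app <- 1 / (1 / p$t1_dest + p$delivery_rate / lambda)
  signal_kernel(ti, p$delivery_rate, p$m0, p$alpha,
                p$arrival_time, p$bolus_duration, p$t1_blood, t1_app)
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat("<kinetic_params>\n")
  cat(sprintf("  delivery_rate : %.6g s^-1\n", x$delivery_rate))
  cat(sprintf("  arrival_time  : %.3g s   bolus_duration: %.3g s\n",
              x$arrival_time, x$bolus_duration))
  cat(sprintf("  t1_blood      : %.3g s   t1_dest: %.3g s\n",
              x$t1_blood, x$t1_dest))
  cat(sprintf("  m0            : %.6g     alpha: %.3g\n", x$m0, x$alpha))
  invisible(x)
}
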