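#' Inversion-recovery signal model
#'
#' Signed (not magnitude) inversion-recovery curve
#' `M(ti) = m0 * (1 - 2 * beta * exp(-ti / t1))`. The signed convention is
#' used because repetition-averaged control signals retain their sign.
#'
#' @param ti Inversion time(s), seconds.
#' @param t1 Longitudinal relaxation time (s), `> 0`.
#' @param m0 Equilibrium magnetization (signal units), `> 0`.
#' @param beta Inversion efficiency in `[0.5, 1]`; 1 is a perfect inversion,
#'   for which the null crossing sits at `ti = t1 * log(2)`.
#' @return Signal values, vectorised over `ti`.
#' @export
#' @examples
#' ir_model(4.24 * log(2), t1 = 4.24, m0 = 1000) # ~0 at the null point
ir_model <- function(ti, t1, m0, beta = 1) {
  if (any(t1 <= 0) || any(m0 <= 0)) abort("`t1` and `m0` must be positive.")
  m0 * (1 - 2 * beta * exp(-ti / t1))
}

# Bounded Levenberg-Marquardt least squares with a uniform result shape.
# `model` maps a named parameter vector to predicted values.
lm_fit <- function(par_init, lower, upper, model, observed, weights = NULL) {
  w <- if (is.null(weights)) rep(1, length(observed)) else weights
  stopifnot(length(w) == length(observed), all(w >= 0))
  resid_fn <- function(par) sqrt(w) * (model(par) - observed)
  fit <- minpack.lm::nls.lm(
    par = par_init, lower = lower, upper = upper, fn = resid_fn,
    control = minpack.lm::nls.lm.control(
      ftol = 1e-13, ptol = 1e-13, gtol = 0, maxiter = 500
    )
  )
  est <- fit$par
  # Parameter standard errors from the local Jacobian (Gauss-Newton
  # approximation); NA when the residual degrees of freedom are exhausted.
  p <- length(est)
  n <- length(observed)
  se <- rep(NA_real_, p)
  if (n > p) {
    sigma2 <- fit$deviance / (n - p)
    covm <- tryCatch(sigma2 * solve(fit$hessian), error = function(e) NULL)
    if (!is.null(covm)) {
      dg <- diag(covm)
      se <- ifelse(dg >= 0, sqrt(dg), NA_real_)
    }
  }
  names(se) <- names(est)
  list(
    par = est,
    std_errors = se,
    residual_norm = sqrt(fit$deviance),
    converged = fit$info %in% 1:4,
    info = fit$info,
    message = fit$message,
    n = n
  )
}

#' Fit an inversion-recovery curve
#'
#' Nonlinear least-squares fit of [ir_model()] to repetition-averaged control
#' data, yielding the compartment `T1` and `M0` (and optionally the inversion
#' efficiency `beta`). This is the relaxometry stage applied to the
#' non-selective (control) ROI signals of each ASL variant: `T1_CSF` from the
#' long-TE ventricular data and cortical `T1` from the short-TE data.
#'
#' Initialisation: `m0` from the largest absolute signal; `t1` from the TI of
#' smallest absolute signal divided by `log(2)` (the null-point heuristic);
#' `beta = 1`. Bounds: `t1` in `[0.1, 10]` s, `beta` in `[0.5, 1]`. The loss
#' is unweighted by default; pass `weights` (e.g. inverse variances) to
#' change that.
#'
#' @param curve A data frame with columns `ti_s` and `mean_signal` (and
#'   optionally `sd`, `n`), e.g. the `control` element of
#'   [extract_roi_curves()]. TIs must be distinct; at least 3 are required
#'   (4 when `beta` is free).
#' @param fix_beta If `TRUE`, hold `beta = 1` (2-parameter fit). Default
#'   `FALSE` (3-parameter fit absorbing imperfect inversion).
#' @param weights Optional per-TI weights for the least-squares loss.
#' @return An object of class `ir_fit` with elements `t1`, `m0`, `beta`,
#'   `std_errors`, `residual_norm`, `converged`, `n_ti`, `data`.
#'   [tidy()] and [glance()] methods are provided.
#' @export
#' @examples
#' ti <- c(0.2, 0.75, 1.5, 2.75, 4, 5, 6)
#' curve <- tibble::tibble(ti_s = ti, mean_signal = ir_model(ti, 4.24, 1000))
#' fit <- fit_inversion_recovery(curve)
#' fit$t1
fit_inversion_recovery <- function(curve, fix_beta = FALSE, weights = NULL) {
  stopifnot(is.data.frame(curve),
            all(c("ti_s", "mean_signal") %in% names(curve)))
  ti <- curve$ti_s
  y <- curve$mean_signal
  if (anyDuplicated(ti)) abort("`ti_s` values must be distinct.")
  if (is.unsorted(ti)) abort("`ti_s` must be increasing.")
  min_ti <- if (fix_beta) 3L else 4L
  if (length(ti) < min_ti) {
    abort(sprintf("need at least %d distinct TIs for this fit.", min_ti))
  }
  m0_init <- max(abs(y))
  if (m0_init <= 0) abort("signal is identically zero; nothing to fit.")
  t1_init <- ti[which.min(abs(y))] / log(2)
  t1_init <- min(max(t1_init, 0.1), 10)

  if (fix_beta) {
    par_init <- c(t1 = t1_init, m0 = m0_init)
    lower <- c(t1 = 0.1, m0 = 1e-12)
    upper <- c(t1 = 10, m0 = Inf)
    model <- function(par) ir_model(ti, par[["t1"]], par[["m0"]], beta = 1)
  } else {
    # start beta strictly inside its bounds so the optimizer can move it
    par_init <- c(t1 = t1_init, m0 = m0_init, beta = 0.9)
    lower <- c(t1 = 0.1, m0 = 1e-12, beta = 0.5)
    upper <- c(t1 = 10, m0 = Inf, beta = 1)
    model <- function(par) ir_model(ti, par[["t1"]], par[["m0"]], par[["beta"]])
  }
  fit <- lm_fit(par_init, lower, upper, model, y, weights)
  if (!fit$converged) {
    warn("inversion-recovery fit did not converge; inspect `residual_norm`.")
  }
  structure(
    list(
      t1 = unname(fit$par[["t1"]]),
      m0 = unname(fit$par[["m0"]]),
      beta = if (fix_beta) 1 else unname(fit$par[["beta"]]),
      beta_fixed = fix_beta,
      std_errors = fit$std_errors,
      residual_norm = fit$residual_norm,
      converged = fit$converged,
      n_ti = length(ti),
      data = tibble::as_tibble(curve)
    ),
    class = "ir_fit"
  )
}

#' @export
print.ir_fit <- function(x, ...) {
  cat("<ir_fit>", if (!x$converged) "(NOT converged)", "\n")
  cat(sprintf("  t1 = %.4g s, m0 = %.6g, beta = %.4g%s\n",
              x$t1, x$m0, x$beta, if (x$beta_fixed) " (fixed)" else ""))
  cat(sprintf("  %d TIs, residual norm %.4g\n", x$n_ti, x$residual_norm))
  invisible(x)
}

#' Predict from an inversion-recovery fit
#'
#' @param object An `ir_fit`.
#' @param ti Inversion times (s); defaults to the fitted TIs.
#' @param ... Unused.
#' @return Predicted signal values.
#' @export
predict.ir_fit <- function(object, ti = object$data$ti_s, ...) {
  ir_model(ti, object$t1, object$m0, object$beta)
}
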