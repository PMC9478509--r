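#' Plot an inversion-recovery fit
#'
#' Repetition-averaged control data (error bars: per-TI SD when available)
#' with the fitted inversion-recovery curve.
#'
#' @param object An `ir_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ir_fit <- function(object, ...) {
  dat <- object$data
  grid <- tibble::tibble(ti_s = seq(0, max(dat$ti_s), length.out = 200))
  grid$fit <- predict(object, grid$ti_s)
  p <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$ti_s)) +
    ggplot2::geom_line(data = grid, ggplot2::aes(y = .data$fit),
                       colour = "steelblue") +
    ggplot2::geom_point(ggplot2::aes(y = .data$mean_signal)) +
    ggplot2::labs(
      x = "inversion time (s)", y = "control signal (a.u.)",
      title = sprintf("Inversion recovery: T1 = %.3g s", object$t1)
    ) +
    ggplot2::theme_minimal()
  if ("sd" %in% names(dat)) {
    p <- p + ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean_signal - .data$sd,
                   ymax = .data$mean_signal + .data$sd),
      width = 0.08
    )
  }
  p
}

#' Plot a fitted ASL kinetic curve
#'
#' Repetition-averaged perfusion-weighted data (error bars: SEM) with the
#' fitted kinetic model.
#'
#' @param object An `asl_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.asl_fit <- function(object, ...) {
  dat <- object$data
  grid <- tibble::tibble(ti_s = seq(0, max(dat$ti_s), length.out = 300))
  grid$fit <- predict(object, grid$ti_s)
  lab <- if (object$model == "bcsfb") {
    sprintf("BCSFB delivery: %.3g ul/min", total_delivery(object$rate))
  } else {
    sprintf("Cortical CBF: %.4g ml/min/100 g",
            cbf_in_reporting_units(object$rate, object$inputs$lambda))
  }
  p <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$ti_s)) +
    ggplot2::geom_line(data = grid, ggplot2::aes(y = .data$fit),
                       colour = "firebrick") +
    ggplot2::geom_point(ggplot2::aes(y = .data$delta_m)) +
    ggplot2::labs(x = "inflow time (s)", y = expression(Delta * M ~ "(a.u.)"),
                  title = lab) +
    ggplot2::theme_minimal()
  if ("sem" %in% names(dat)) {
    p <- p + ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$delta_m - .data$sem,
                   ymax = .data$delta_m + .data$sem),
      width = 0.08
    )
  }
  p
}

#' Plot a cohort result
#'
#' `which = "comparison"`: group means with SEM error bars per metric.
#' `which = "curves"`: group-averaged normalised kinetic curves
#' (`DeltaM / M0_corr` for BCSFB-ASL, `DeltaM / M0` for standard-ASL).
#'
#' @param object A `cohort_result`.
#' @param which `"comparison"` or `"curves"`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cohort_result <- function(object,
                                   which = c("comparison", "curves"), ...) {
  which <- match.arg(which)
  if (which == "curves") {
    return(
      ggplot2::ggplot(object$curves,
                      ggplot2::aes(x = .data$ti_s, y = .data$mean_norm,
                                   colour = .data$group)) +
        ggplot2::geom_point() +
        ggplot2::geom_line(alpha = 0.6) +
        ggplot2::geom_errorbar(
          ggplot2::aes(ymin = .data$mean_norm - .data$sem_norm,
                       ymax = .data$mean_norm + .data$sem_norm),
          width = 0.1
        ) +
        ggplot2::facet_wrap(ggplot2::vars(.data$variant),
                            scales = "free_y") +
        ggplot2::labs(x = "inflow time (s)",
                      y = "normalised perfusion-weighted signal") +
        ggplot2::theme_minimal()
    )
  }
  long <- object$subjects |>
    tidyr::pivot_longer(
      cols = c("total_delivery", "cbf", "t1_csf", "t1_cortex",
               "ventricular_volume"),
      names_to = "metric", values_to = "value"
    ) |>
    dplyr::group_by(.data$metric, .data$group) |>
    dplyr::summarise(mean = mean(.data$value),
                     sem = sd(.data$value) / sqrt(dplyr::n()),
                     .groups = "drop")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$group, y = .data$mean,
                                     fill = .data$group)) +
    ggplot2::geom_col(width = 0.6, show.legend = FALSE) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$sem,
                                        ymax = .data$mean + .data$sem),
                           width = 0.2) +
    ggplot2::facet_wrap(ggplot2::vars(.data$metric), scales = "free_y") +
    ggplot2::labs(x = NULL, y = "group mean +/- SEM") +
    ggplot2::theme_minimal()
}

#' Quick plot of a perfusion-weighted curve
#'
#' @param curve Tibble with `ti_s`, `delta_m` and optionally `sem`.
#' @return A ggplot.
#' @export
plot_delta_m_curve <- function(curve) {
  p <- ggplot2::ggplot(curve, ggplot2::aes(x = .data$ti_s,
                                           y = .data$delta_m)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(alpha = 0.5) +
    ggplot2::labs(x = "inflow time (s)",
                  y = expression(Delta * M ~ "(a.u.)")) +
    ggplot2::theme_minimal()
  if ("sem" %in% names(curve)) {
    p <- p + ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$delta_m - .data$sem,
                   ymax = .data$delta_m + .data$sem),
      width = 0.08
    )
  }
  p
}
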