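# TE attenuation with the long-TE suppression idealisation: factors below
# the floor are treated as fully crushed (the sub-percent residual tissue
# signal at TE = 220 ms sits below the noise floor and is modelled as zero).
te_attenuation <- function(te_ms, t2_s, floor = 0.01) {
  a <- exp(-te_ms / 1000 / t2_s)
  ifelse(a < floor, 0, a)
}

# Ground-truth CSF-compartment delivery rate (s^-1, fraction of CSF M0 per
# second) that makes the analysis chain -- IR fit, Eq.-1 volume correction
# with the measured ventricular volume, rate fit, total = rate * 86.4 * 60 --
# recover the preset total delivery. The ROI dilution factor cancels between
# the DeltaM curve and the fitted M0, leaving rate_roi = r_csf * 86.4 / Vv.
csf_rate_from_delivery <- function(total_delivery_ul_min, vent_volume_mm3,
                                   roi_volume_mm3 = 86.4) {
  (total_delivery_ul_min / (roi_volume_mm3 * 60)) *
    (vent_volume_mm3 / roi_volume_mm3)
}

#' Simulate a paired FAIR-ASL series from a phantom
#'
#' Forward model, voxel by voxel on the 32 x 32 ASL grid:
#'
#' * non-selective (control) signal: per-compartment inversion recovery
#'   [ir_model()] with the compartment `T1` and TE-attenuated `M0`,
#'   partial-volume weighted by the ventricular area fraction;
#' * selective (label) signal: control plus the compartment kinetic signal
#'   ([bcsfb_csf_signal()] for CSF, [pasl_tissue_signal()] for tissue),
#'   weighted the same way;
#' * additive Gaussian noise, SD `noise_sd * m0_tissue`, drawn fresh for
#'   every image (each TI, repetition, and label/control member).
#'
#' At TE = 220 ms the tissue attenuation `exp(-TE/T2_tissue)` falls below
#' the suppression floor and tissue contributes no signal, so ventricular
#' ROIs are purely CSF-weighted; at TE = 20 ms both compartments contribute.
#'
#' @param phantom A [build_phantom()] result.
#' @param variant `"bcsfb"` or `"standard"`; selects the matching preset
#'   protocol unless `protocol` is given.
#' @param protocol Optional [acquisition_protocol()] override.
#' @param seed Integer seed for reproducibility; same seed, same series.
#' @param noise_sd Override of the phantom's `noise_sd`.
#' @return An [asl_series()].
#' @export
simulate_asl_series <- function(phantom, variant = c("bcsfb", "standard"),
                                protocol = NULL, seed = NULL,
                                noise_sd = NULL) {
  stopifnot(inherits(phantom, "bcsfb_phantom"))
  variant <- match.arg(variant)
  protocol <- protocol %||%
    switch(variant, bcsfb = bcsfb_protocol(), standard = standard_protocol())
  stopifnot(inherits(protocol, "acquisition_protocol"))
  if (protocol$matrix_size != phantom$asl$n) {
    abort("protocol matrix size does not match the phantom grid.")
  }
  spec <- phantom$spec
  noise_sd <- noise_sd %||% spec$noise_sd
  ti <- protocol$ti_s
  att_csf <- te_attenuation(protocol$te_ms, spec$t2_csf,
                            spec$suppression_floor)
  att_tis <- te_attenuation(protocol$te_ms, spec$t2_tissue,
                            spec$suppression_floor)
  a_csf <- spec$m0_csf * att_csf
  a_tis <- spec$m0_tissue * att_tis

  r_csf <- csf_rate_from_delivery(spec$total_delivery,
                                  phantom$realized_volume)
  r_tis <- spec$cbf / (spec$lambda * 6000)

  comp_curves <- function(a, t1, rate, dt, tau, model) {
    if (a <= 0) return(list(ctrl = numeric(length(ti)),
                            dm = numeric(length(ti))))
    ctrl <- ir_model(ti, t1 = t1, m0 = a, beta = 1)
    dm <- if (rate > 0) {
      p <- kinetic_params(rate, t1_dest = t1, m0 = a, arrival_time = dt,
                          bolus_duration = tau, t1_blood = spec$t1_blood,
                          alpha = spec$alpha)
      if (identical(model, "tissue")) {
        pasl_tissue_signal(ti, p, spec$lambda)
      } else {
        bcsfb_csf_signal(ti, p)
      }
    } else {
      numeric(length(ti))
    }
    list(ctrl = ctrl, dm = dm)
  }
  csf <- comp_curves(a_csf, spec$t1_csf, r_csf, spec$arrival_csf,
                     spec$bolus_csf, "csf")
  tis <- comp_curves(a_tis, spec$t1_cortex, r_tis, spec$arrival_tissue,
                     spec$bolus_tissue, "tissue")

  n <- phantom$asl$n
  n_ti <- length(ti)
  n_rep <- protocol$repetitions
  fc <- as.vector(phantom$asl$csf_frac)
  ft <- as.vector(phantom$asl$tissue_frac)
  base_ctrl <- outer(fc, csf$ctrl) + outer(ft, tis$ctrl)   # (vox, ti)
  base_dm <- outer(fc, csf$dm) + outer(ft, tis$dm)

  make_stack <- function(base, sd) {
    arr <- array(rep(base, times = n_rep), c(n, n, n_ti, n_rep))
    if (sd > 0) arr <- arr + array(rnorm(length(arr), 0, sd), dim(arr))
    arr
  }
  gen <- function() {
    sd <- noise_sd * spec$m0_tissue
    nonsel <- make_stack(base_ctrl, sd)
    sel <- make_stack(base_ctrl + base_dm, sd)
    list(sel = sel, nonsel = nonsel)
  }
  imgs <- if (is.null(seed)) gen() else withr::with_seed(seed, gen())
  asl_series(imgs$sel, imgs$nonsel, protocol)
}

#' Simulate the coronal T2-weighted anatomical stack
#'
#' Bright-CSF fast-spin-echo contrast at an effective TE of 33 ms: each
#' compartment contributes `m0 * exp(-TE/T2)` (CSF hyperintense thanks to
#' its long T2), background is zero, and Gaussian noise with SD
#' `noise_sd * m0_tissue` is added.
#'
#' @inheritParams simulate_asl_series
#' @param te_ms Effective echo time of the anatomical sequence (ms).
#' @return A [t2w_stack()].
#' @export
simulate_t2w_stack <- function(phantom, seed = NULL, noise_sd = NULL,
                               te_ms = 33) {
  stopifnot(inherits(phantom, "bcsfb_phantom"))
  spec <- phantom$spec
  noise_sd <- noise_sd %||% spec$noise_sd
  csf_level <- spec$m0_csf * exp(-te_ms / 1000 / spec$t2_csf)
  tis_level <- spec$m0_tissue * exp(-te_ms / 1000 / spec$t2_tissue)
  t2 <- phantom$t2w
  data <- array(0, dim(t2$mask))
  data[t2$brain] <- tis_level
  data[t2$mask] <- csf_level
  gen <- function() {
    if (noise_sd > 0) {
      data + array(rnorm(length(data), 0, noise_sd * spec$m0_tissue),
                   dim(data))
    } else {
      data
    }
  }
  data <- if (is.null(seed)) gen() else withr::with_seed(seed, gen())
  t2w_stack(data, in_plane_mm = t2$in_plane_mm,
            slice_thickness_mm = t2$slice_thickness_mm)
}

#' Simulate one complete subject
#'
#' Builds the phantom and simulates the three acquisitions of the study
#' protocol: the long-TE BCSFB-ASL series, the short-TE standard-ASL series
#' and the T2-weighted anatomical stack. Sub-seeds are derived from `seed`
#' so the whole subject is reproducible from one integer.
#'
#' @param spec A [phantom_spec()].
#' @param seed Integer seed.
#' @param subject_id,group Optional identifiers carried into results.
#' @return An object of class `asl_subject`: list with `phantom`, `bcsfb`,
#'   `standard`, `t2w`, `truth` (one-row tibble of ground-truth values in
#'   reporting units) and identifiers.
#' @export
#' @examples
#' \donttest{
#' subj <- simulate_subject(phantom_spec("WKY", noise_sd = 0), seed = 1)
#' subj$truth
#' }
simulate_subject <- function(spec = phantom_spec("WKY"), seed = 1,
                             subject_id = "s1", group = spec$preset) {
  stopifnot(inherits(spec, "phantom_spec"))
  phantom <- build_phantom(spec)
  structure(
    list(
      phantom = phantom,
      bcsfb = simulate_asl_series(phantom, "bcsfb", seed = seed + 1L),
      standard = simulate_asl_series(phantom, "standard", seed = seed + 2L),
      t2w = simulate_t2w_stack(phantom, seed = seed + 3L),
      truth = tibble::tibble(
        subject_id = subject_id, group = group,
        total_delivery = spec$total_delivery, cbf = spec$cbf,
        t1_csf = spec$t1_csf, t1_cortex = spec$t1_cortex,
        ventricular_volume = phantom$realized_volume
      ),
      subject_id = subject_id, group = group, seed = seed
    ),
    class = "asl_subject"
  )
}

#' @export
print.asl_subject <- function(x, ...) {
  cat(sprintf("<asl_subject %s (%s)> seed %s\n", x$subject_id, x$group,
              format(x$seed)))
  print(x$truth)
  invisible(x)
}

# Between-subject SDs calibrated to the published group SEMs (SD = SEM *
# sqrt(6)); the residual measurement noise at the default noise_sd inflates
# the total spread by < 4%, so simulated group SEMs match the published
# ones in expectation.
calibrated_spread <- function(preset) {
  summ <- reported_group_summaries()
  summ <- summ[summ$group == preset, ]
  setNames(summ$sem * sqrt(summ$n), summ$metric)
}

#' Simulate a two-group cohort
#'
#' Draws subject-level ground-truth parameters around the preset means and
#' simulates every subject's full acquisition set. With
#' `spread = "calibrated"` (default) the between-subject SD of each metric
#' is set to the published between-subject SD (SEM x sqrt(n)) of the
#' matching strain; `spread = "cv"` applies one coefficient of variation to
#' all metrics; `spread = "none"` gives every subject the preset truth.
#' Draws that would be non-positive (or ventricular volumes below 10 mm^3)
#' are redrawn; the redraw count is recorded in the `truncations` attribute.
#'
#' @param n_per_group Subjects per group, `>= 2`.
#' @param seed Integer seed; subject seeds are derived deterministically.
#' @param spread `"calibrated"`, `"cv"` or `"none"`.
#' @param cv Coefficient of variation for `spread = "cv"`.
#' @param presets Group presets (default WKY and SHR).
#' @param noise_sd Optional override of the image-noise level for all
#'   subjects.
#' @return An object of class `asl_cohort`: list with `subjects` (list of
#'   [simulate_subject()] results) and `truth` (tibble of ground-truth
#'   values, one row per subject).
#' @export
simulate_cohort <- function(n_per_group = 6, seed = 1,
                            spread = c("calibrated", "cv", "none"),
                            cv = NULL, presets = c("WKY", "SHR"),
                            noise_sd = NULL) {
  spread <- match.arg(spread)
  stopifnot(n_per_group >= 2)
  if (spread == "cv" && is.null(cv)) abort("supply `cv` for spread = 'cv'.")
  metrics <- c("total_delivery", "cbf", "t1_csf", "t1_cortex",
               "ventricular_volume")
  n_trunc <- 0L
  draw_spec <- function(preset) {
    base <- phantom_spec(preset)
    sds <- switch(spread,
      none = setNames(rep(0, length(metrics)), metrics),
      cv = setNames(cv * vapply(metrics, function(m) base[[m]], 1), metrics),
      calibrated = calibrated_spread(preset)[metrics]
    )
    vals <- vapply(metrics, function(m) {
      mu <- base[[m]]
      lo <- if (m == "ventricular_volume") 10 else 1e-6
      x <- rnorm(1, mu, sds[[m]])
      while (x <= lo) {
        n_trunc <<- n_trunc + 1L
        x <- rnorm(1, mu, sds[[m]])
      }
      x
    }, numeric(1))
    args <- c(list(preset = preset), as.list(vals))
    if (!is.null(noise_sd)) args$noise_sd <- noise_sd
    do.call(phantom_spec, args)
  }
  specs <- withr::with_seed(seed, {
    unlist(lapply(presets, function(p) {
      lapply(seq_len(n_per_group), function(i) draw_spec(p))
    }), recursive = FALSE)
  })
  groups <- rep(presets, each = n_per_group)
  ids <- sprintf("%s_%02d", tolower(groups),
                 rep(seq_len(n_per_group), times = length(presets)))
  subjects <- purrr::pmap(
    list(specs, ids, groups, seq_along(specs)),
    function(sp, id, gr, i) {
      simulate_subject(sp, seed = seed + 7919L * i, subject_id = id,
                       group = gr)
    }
  )
  truth <- purrr::map_dfr(subjects, "truth")
  structure(
    list(subjects = subjects, truth = truth, seed = seed,
         spread = spread),
    class = "asl_cohort", truncations = n_trunc
  )
}

#' @export
print.asl_cohort <- function(x, ...) {
  cat(sprintf("<asl_cohort> %d subjects (%s), spread '%s', seed %s\n",
              length(x$subjects),
              paste(unique(x$truth$group), collapse = " vs "),
              x$spread, format(x$seed)))
  invisible(x)
}
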