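#' Paired selective/non-selective ASL image series
#'
#' Container for one multi-TI FAIR acquisition: two 4-D arrays indexed
#' `[x, y, ti, repetition]` holding the slice-selective (label) and
#' non-selective (control) images, plus the protocol that produced them.
#'
#' @param selective,nonselective Numeric 4-D arrays of identical dimension
#'   `c(nx, ny, n_ti, n_rep)`.
#' @param protocol An [acquisition_protocol()]; its TI count and repetitions
#'   must match the array dimensions.
#' @return An object of class `asl_series`.
#' @export
asl_series <- function(selective, nonselective, protocol) {
  stopifnot(inherits(protocol, "acquisition_protocol"),
            is.array(selective), is.array(nonselective),
            length(dim(selective)) == 4L)
  if (!identical(dim(selective), dim(nonselective))) {
    abort("selective and non-selective stacks must have identical shape.")
  }
  d <- dim(selective)
  if (d[3] != length(protocol$ti_s)) {
    abort("third array dimension must match the protocol's TI count.")
  }
  if (d[4] != protocol$repetitions) {
    abort("fourth array dimension must match the protocol's repetitions.")
  }
  structure(list(selective = selective, nonselective = nonselective,
                 protocol = protocol),
            class = "asl_series")
}

#' @export
print.asl_series <- function(x, ...) {
  d <- dim(x$selective)
  cat(sprintf("<asl_series: %s> %dx%d voxels, %d TIs, %d repetitions\n",
              x$protocol$variant, d[1], d[2], d[3], d[4]))
  invisible(x)
}

#' ROI definitions for ASL signal extraction
#'
#' Holds the cortical ROI mask and the two ventricular ROI masks on the ASL
#' in-plane grid, together with the voxel volume. For the BCSFB protocol the
#' two 3x3 ventricular ROIs (18 voxels at 1 x 1 x 4.8 mm) give the canonical
#' ROI volume of 86.4 mm^3. (The originating description of the volume
#' correction mentions "12 voxels" in prose while defining an 18-voxel ROI;
#' this implementation always uses the actual mask voxel count.)
#'
#' @param cortex_mask Logical matrix (`nx x ny`) selecting cortical voxels.
#' @param ventricle_masks List of two logical matrices, one per ventricular
#'   ROI; they must be disjoint from each other and from the cortex mask.
#' @param voxel_volume_mm3 Volume of one ASL voxel (in-plane area x slice
#'   thickness), mm^3.
#' @return An object of class `roi_set` with derived `ventricle_roi_volume`
#'   (mm^3).
#' @export
roi_set <- function(cortex_mask, ventricle_masks, voxel_volume_mm3) {
  stopifnot(is.matrix(cortex_mask), is.logical(cortex_mask),
            is.list(ventricle_masks), length(ventricle_masks) >= 1L,
            voxel_volume_mm3 > 0)
  for (m in ventricle_masks) {
    stopifnot(is.matrix(m), is.logical(m),
              identical(dim(m), dim(cortex_mask)))
    if (any(m & cortex_mask)) abort("ROI masks must be disjoint per role.")
  }
  if (length(ventricle_masks) >= 2L) {
    overlap <- Reduce(`+`, lapply(ventricle_masks, as.numeric))
    if (any(overlap > 1)) abort("ventricular ROI masks must be disjoint.")
  }
  vent_union <- Reduce(`|`, ventricle_masks)
  structure(
    list(
      cortex_mask = cortex_mask,
      ventricle_masks = ventricle_masks,
      ventricle_mask = vent_union,
      voxel_volume_mm3 = voxel_volume_mm3,
      ventricle_roi_volume = sum(vent_union) * voxel_volume_mm3
    ),
    class = "roi_set"
  )
}

# ROI-mean time series: returns an n_ti x n_rep matrix of ROI means.
roi_means <- function(stack, mask) {
  d <- dim(stack)
  flat <- matrix(stack, nrow = d[1] * d[2])
  sub <- flat[as.vector(mask), , drop = FALSE]
  matrix(colMeans(sub), nrow = d[3], ncol = d[4])
}

#' Extract repetition-averaged ASL curves from an ROI
#'
#' Turns a paired image series into the two fitting inputs: the
#' perfusion-weighted `[TI, DeltaM]` curve and the control `[TI, M_c]`
#' inversion-recovery curve. Per repetition, the ROI mean of the selective
#' image minus the ROI mean of the paired non-selective image gives one
#' `DeltaM` sample (repetition r of the label is paired with repetition r of
#' the control at the same TI); repeated measures are then averaged per TI.
#' The control curve is built from the non-selective ROI means. For the
#' ventricular role the two 3x3 ROIs are combined into one sample before
#' subtraction, so their order is irrelevant; volume is handled entirely by
#' [m0_volume_correct()].
#'
#' @param series An [asl_series()].
#' @param rois An [roi_set()] on the same in-plane grid.
#' @param role `"cortex"` or `"ventricles"`: which mask to average over.
#' @return A list with two tibbles:
#'   * `delta_m`: `ti_s`, `delta_m` (mean over repetitions), `sem`
#'     (SD of the per-repetition differences / sqrt(n)), `n`;
#'   * `control`: `ti_s`, `mean_signal`, `sd`, `n`.
#' @export
extract_roi_curves <- function(series, rois,
                               role = c("cortex", "ventricles")) {
  stopifnot(inherits(series, "asl_series"), inherits(rois, "roi_set"))
  role <- match.arg(role)
  mask <- switch(role, cortex = rois$cortex_mask,
                 ventricles = rois$ventricle_mask)
  d <- dim(series$selective)
  if (!identical(dim(mask), d[1:2])) {
    abort("ROI mask grid does not match the image grid.")
  }
  if (!any(mask)) abort("ROI mask is empty.")
  sel <- roi_means(series$selective, mask)
  ctl <- roi_means(series$nonselective, mask)
  diffs <- sel - ctl
  n_rep <- ncol(diffs)
  ti <- series$protocol$ti_s
  list(
    delta_m = tibble::tibble(
      ti_s = ti,
      delta_m = rowMeans(diffs),
      sem = apply(diffs, 1, sd) / sqrt(n_rep),
      n = n_rep
    ),
    control = tibble::tibble(
      ti_s = ti,
      mean_signal = rowMeans(ctl),
      sd = apply(ctl, 1, sd),
      n = n_rep
    )
  )
}

#' Ventricular-volume correction of the fitted M0
#'
#' Rescales the ROI-fitted equilibrium magnetization by the ratio of total
#' ventricular volume (from T2-weighted morphometry) to the ventricular ROI
#' volume: `M0_corr = M0 * total_ventricular_volume / roi_volume`. The
#' fitted M0 of the low-resolution ventricular ROI depends strongly on
#' ventricle size through partial-volume effects; this correction makes the
#' downstream delivery estimate comparable across subjects with different
#' ventricular volumes.
#'
#' @param m0 Fitted equilibrium magnetization (signal units), `> 0`.
#' @param total_ventricular_volume Lateral-ventricular volume (mm^3), `> 0`.
#' @param roi_volume Ventricular ROI volume (mm^3), `> 0`; 86.4 for the
#'   standard two-3x3-voxel BCSFB ROI.
#' @return `M0_corr` in signal units.
#' @export
#' @examples
#' m0_volume_correct(1000, total_ventricular_volume = 83, roi_volume = 86.4)
m0_volume_correct <- function(m0, total_ventricular_volume, roi_volume) {
  if (any(m0 <= 0) || any(total_ventricular_volume <= 0) ||
      any(roi_volume <= 0)) {
    abort("`m0` and both volumes must be positive.")
  }
  m0 * total_ventricular_volume / roi_volume
}
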