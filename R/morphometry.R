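#' Coronal T2-weighted stack
#'
#' Container for the anatomical reference stack used for ventricular
#' morphometry: 12 coronal slices of 0.4 mm over a 30 mm field of view at a
#' 256 x 256 matrix by default (in-plane resolution 30/256 mm).
#'
#' @param data Numeric 3-D array `[x, y, slice]`.
#' @param in_plane_mm In-plane voxel size (mm), default `30/256`.
#' @param slice_thickness_mm Slice thickness (mm), default 0.4.
#' @return An object of class `t2w_stack` with derived `voxel_volume_mm3`.
#' @export
t2w_stack <- function(data, in_plane_mm = 30 / 256,
                      slice_thickness_mm = 0.4) {
  stopifnot(is.array(data), length(dim(data)) == 3L,
            in_plane_mm > 0, slice_thickness_mm > 0)
  structure(
    list(
      data = data,
      in_plane_mm = in_plane_mm,
      slice_thickness_mm = slice_thickness_mm,
      n_slices = dim(data)[3],
      voxel_volume_mm3 = in_plane_mm^2 * slice_thickness_mm
    ),
    class = "t2w_stack"
  )
}

#' @export
print.t2w_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<t2w_stack> %dx%d x %d slices, %.4g mm in-plane, %.2g mm slices\n",
    d[1], d[2], d[3], x$in_plane_mm, x$slice_thickness_mm))
  invisible(x)
}

#' Lateral-ventricular volume from a segmentation mask
#'
#' `volume = voxel count x (in_plane^2 x slice_thickness)`, the morphometry
#' readout from manually or automatically segmented coronal T2-weighted
#' images. Additive over disjoint masks by construction.
#'
#' @param mask Logical 3-D array on the stack grid (or any logical array).
#' @param geometry A [t2w_stack()] supplying the voxel volume, or a single
#'   numeric voxel volume in mm^3.
#' @return Volume in mm^3; an empty mask returns 0 with a warning.
#' @export
#' @examples
#' ventricular_volume(array(TRUE, c(2, 2, 1)), geometry = 0.0055)
ventricular_volume <- function(mask, geometry) {
  stopifnot(is.logical(mask))
  vox <- if (inherits(geometry, "t2w_stack")) {
    geometry$voxel_volume_mm3
  } else {
    stopifnot(is.numeric(geometry), geometry > 0)
    geometry
  }
  n <- sum(mask)
  if (n == 0L) warn("segmentation mask is empty; volume is 0.")
  n * vox
}

#' Intensity-threshold segmentation of a T2-weighted stack
#'
#' Stand-in for manual segmentation on synthetic data, where CSF is the
#' hyperintense class at the long effective echo time: selects voxels at or
#' above a threshold, restricted to a search region. The threshold can be
#' given in signal units or as a quantile of the search-region intensities
#' (in which case the resulting mask, and hence the volume estimate, is
#' invariant under global intensity rescaling).
#'
#' @param stack A [t2w_stack()].
#' @param threshold Absolute intensity threshold; mutually exclusive with
#'   `prob`.
#' @param prob Quantile (in `[0, 1]`) of the search-region intensities used
#'   as the threshold.
#' @param search_region Optional logical array restricting the search;
#'   default is the whole stack.
#' @return Logical 3-D mask.
#' @export
threshold_segment <- function(stack, threshold = NULL, prob = NULL,
                              search_region = NULL) {
  stopifnot(inherits(stack, "t2w_stack"))
  v <- stack$data
  region <- search_region %||% array(TRUE, dim(v))
  stopifnot(is.logical(region), identical(dim(region), dim(v)))
  if (is.null(threshold) == is.null(prob)) {
    abort("supply exactly one of `threshold` or `prob`.")
  }
  if (!is.null(prob)) {
    stopifnot(prob >= 0, prob <= 1)
    threshold <- quantile(v[region], prob, names = FALSE)
  }
  (v >= threshold) & region
}

#' Default CSF threshold for synthetic T2-weighted stacks
#'
#' Midpoint between the brain-parenchyma level (median of in-brain
#' intensities) and the brightest tissue class (maximum), with "in brain"
#' taken as intensities above `brain_frac` of the maximum. Both anchors are
#' quantile-based, so the threshold scales with the image and the resulting
#' segmentation is invariant under global intensity rescaling. Adequate for
#' the bimodal synthetic stacks produced by [simulate_t2w_stack()]; real
#' data would be segmented manually.
#'
#' @param stack A [t2w_stack()].
#' @param brain_frac Fraction of the maximum intensity used to exclude
#'   background, default 0.3.
#' @return A threshold in signal units.
#' @export
default_csf_threshold <- function(stack, brain_frac = 0.3) {
  v <- stack$data
  mx <- max(v)
  brain <- v > brain_frac * mx
  (median(v[brain]) + mx) / 2
}
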