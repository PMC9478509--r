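# Fixed phantom geometry (mm, in the ASL physical frame whose in-plane
# origin is the image corner; the grid centre sits at (16, 16)):
# a circular brain, two elliptical lateral ventricles centred inside the two
# 3x3-voxel functional ROIs, and a dorsal cortical band.
phantom_geometry <- function() {
  list(
    asl_n = 32L, asl_voxel_mm = 1,
    brain_centre = c(16, 16), brain_radius = 13,
    vent_centres = list(c(12.5, 14.5), c(18.5, 14.5)),
    vent_rx = 1.3,
    vent_roi_x = list(12:14, 18:20), vent_roi_y = 14:16,
    cortex_x = 10:23, cortex_y = 23:26,
    t2w_n = 256L, t2w_fov_mm = 30, t2w_slices = 12L,
    t2w_slice_mm = 0.4,
    # offset aligning the 30 mm T2w FOV centre with the 32 mm ASL FOV centre
    t2w_offset_mm = 1
  )
}

#' Digital-phantom specification
#'
#' Ground-truth tissue and acquisition parameters for one simulated subject.
#' The two presets reproduce the group-mean values of the normotensive
#' (WKY-like) and hypertensive (SHR-like) rat strains: total BCSFB-mediated
#' water delivery 14.4 vs 9.22 ul/min, cortical CBF 123 vs 118
#' ml/min/100 g, `T1_CSF` 4.24 vs 4.58 s, cortical `T1` 1.88 vs 1.91 s, and
#' lateral ventricular volume 56 vs 83 mm^3.
#'
#' @param preset `"WKY"` or `"SHR"`.
#' @param ... Named overrides of any field below.
#'
#' @section Fields:
#' * `total_delivery` (ul/min), `cbf` (ml/min/100 g), `t1_csf`, `t1_cortex`
#'   (s), `ventricular_volume` (mm^3): ground truth in reporting units;
#' * `m0_csf`, `m0_tissue`: equilibrium magnetizations (arbitrary units);
#' * `t2_csf`, `t2_tissue` (s): transverse relaxation used for the TE
#'   attenuation `exp(-TE/T2)` (defaults 0.25 / 0.04 s -- assumptions, not
#'   measured values);
#' * `suppression_floor`: attenuation factors below this are treated as
#'   fully crushed (default 0.01), an idealisation of the long-TE T2 filter
#'   that isolates CSF at TE = 220 ms;
#' * `arrival_csf`, `bolus_csf`, `arrival_tissue`, `bolus_tissue` (s):
#'   kinetic timing (defaults 1.04 / 3.66 for CSF, 0.3 / 3.66 for tissue);
#' * `t1_blood` (s), `alpha`, `lambda`: model constants;
#' * `noise_sd`: image-noise SD as a fraction of `m0_tissue` per image
#'   (default 0.001; see the methods vignette for the calibration argument).
#'
#' @return An object of class `phantom_spec`.
#' @export
#' @examples
#' phantom_spec("SHR", noise_sd = 0)
phantom_spec <- function(preset = c("WKY", "SHR"), ...) {
  preset <- match.arg(preset)
  base <- switch(preset,
    WKY = list(total_delivery = 14.4, cbf = 123, t1_csf = 4.24,
               t1_cortex = 1.88, ventricular_volume = 56),
    SHR = list(total_delivery = 9.22, cbf = 118, t1_csf = 4.58,
               t1_cortex = 1.91, ventricular_volume = 83)
  )
  spec <- c(base, list(
    m0_csf = 1000, m0_tissue = 1000,
    t2_csf = 0.25, t2_tissue = 0.04, suppression_floor = 0.01,
    arrival_csf = 1.04, bolus_csf = 3.66,
    arrival_tissue = 0.3, bolus_tissue = 3.66,
    t1_blood = 2.4, alpha = 1, lambda = 0.9,
    noise_sd = 0.001, preset = preset
  ))
  dots <- list(...)
  bad <- setdiff(names(dots), names(spec))
  if (length(bad)) abort(paste0("unknown phantom field(s): ",
                                paste(bad, collapse = ", ")))
  spec[names(dots)] <- dots
  num <- spec[setdiff(names(spec), "preset")]
  if (!all(vapply(num, function(x) is.numeric(x) && length(x) == 1L,
                  logical(1)))) {
    abort("phantom fields must be scalar numerics.")
  }
  positive <- c("total_delivery", "cbf", "t1_csf", "t1_cortex",
                "ventricular_volume", "m0_csf", "m0_tissue", "t2_csf",
                "t2_tissue", "bolus_csf", "bolus_tissue", "t1_blood",
                "alpha", "lambda")
  for (f in positive) if (spec[[f]] <= 0) {
    abort(paste0("`", f, "` must be positive."))
  }
  if (spec$noise_sd < 0) abort("`noise_sd` must be non-negative.")
  if (spec$alpha > 1) abort("`alpha` must be in (0, 1].")
  structure(spec, class = "phantom_spec")
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf("<phantom_spec: %s-like>\n", x$preset))
  cat(sprintf("  delivery %.3g ul/min, CBF %.4g ml/min/100g\n",
              x$total_delivery, x$cbf))
  cat(sprintf("  T1_CSF %.3g s, T1_cortex %.3g s, ventricles %.3g mm^3\n",
              x$t1_csf, x$t1_cortex, x$ventricular_volume))
  cat(sprintf("  noise_sd %.4g x M0\n", x$noise_sd))
  invisible(x)
}

# In-plane ventricle ellipse semi-axes for a target volume over the 4.8 mm
# ASL slice: two ellipses of equal area Vv / (2 * 4.8), fixed rx.
vent_ellipses <- function(volume_mm3, geom = phantom_geometry()) {
  area_each <- volume_mm3 / (2 * 4.8)
  rx <- geom$vent_rx
  ry <- area_each / (pi * rx)
  lapply(geom$vent_centres, function(cc) {
    list(cx = cc[1], cy = cc[2], rx = rx, ry = ry)
  })
}

# Smallest normalised elliptical radius across the two ventricles.
vent_rho <- function(x, y, ellipses) {
  rho <- Inf
  for (e in ellipses) {
    rho <- pmin(rho, sqrt(((x - e$cx) / e$rx)^2 + ((y - e$cy) / e$ry)^2))
  }
  rho
}

# Area fraction of each ASL voxel covered by ventricle, by k x k subsampling.
asl_csf_fractions <- function(ellipses, geom = phantom_geometry(), k = 11L) {
  n <- geom$asl_n
  frac <- matrix(0, n, n)
  off <- (seq_len(k) - 0.5) / k
  pad <- 1
  xs <- range(vapply(ellipses, function(e) c(e$cx - e$rx, e$cx + e$rx),
                     numeric(2)))
  ys <- range(vapply(ellipses, function(e) c(e$cy - e$ry, e$cy + e$ry),
                     numeric(2)))
  ix <- max(1, floor(xs[1] - pad)):min(n, ceiling(xs[2] + pad))
  iy <- max(1, floor(ys[1] - pad)):min(n, ceiling(ys[2] + pad))
  for (i in ix) for (j in iy) {
    px <- (i - 1) + off
    py <- (j - 1) + off
    g <- expand.grid(x = px, y = py)
    frac[i, j] <- mean(vent_rho(g$x, g$y, ellipses) <= 1)
  }
  frac
}

#' Build the digital phantom for one subject
#'
#' Realises the subject's anatomy deterministically on both imaging grids:
#'
#' * ASL grid (32 x 32 at 1 mm): a circular brain, per-voxel ventricular
#'   area fractions for two elliptical lateral ventricles centred inside the
#'   two 3x3-voxel functional ROIs (partial volume is handled by
#'   area-fraction weighting of compartment signals), a dorsal cortical ROI
#'   band, and a label map partitioning the grid;
#' * T2-weighted grid (256 x 256 x 12 at 30/256 mm in-plane, 0.4 mm
#'   slices): a ventricle voxel mask whose realised volume matches the
#'   target to within one voxel (exact voxel-count construction by ranking
#'   voxels on normalised elliptical radius).
#'
#' The imaging slice geometry mimics positioning at the caudal end of the
#' lateral ventricles, where the choroid plexus resides; the 4.8 mm ASL
#' slice and the 12 x 0.4 mm T2w stack cover the same 4.8 mm slab, so the
#' morphometric volume is the volume seen by the functional slice.
#'
#' @param spec A [phantom_spec()].
#' @return An object of class `bcsfb_phantom`: a list with elements `asl`
#'   (fractions, masks, labels), `t2w` (mask and geometry),
#'   `realized_volume` (mm^3) and `spec`.
#' @export
build_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  geom <- phantom_geometry()
  ellipses <- vent_ellipses(spec$ventricular_volume, geom)
  # feasibility: ventricles must stay inside the brain disk
  if (any(vapply(ellipses, function(e) {
    sqrt((e$cx - 16)^2) + e$rx > geom$brain_radius ||
      abs(e$cy - 16) + e$ry > geom$brain_radius
  }, logical(1)))) {
    abort("target ventricular volume is not representable on this geometry.")
  }

  n <- geom$asl_n
  centres <- seq_len(n) - 0.5
  gx <- matrix(centres, n, n)
  gy <- matrix(centres, n, n, byrow = TRUE)
  brain <- (gx - geom$brain_centre[1])^2 + (gy - geom$brain_centre[2])^2 <=
    geom$brain_radius^2
  frac <- asl_csf_fractions(ellipses, geom)
  frac[!brain] <- 0
  tissue_frac <- ifelse(brain, 1 - frac, 0)

  cortex <- matrix(FALSE, n, n)
  cortex[geom$cortex_x, geom$cortex_y] <- TRUE
  vent_masks <- lapply(geom$vent_roi_x, function(xs) {
    m <- matrix(FALSE, n, n)
    m[xs, geom$vent_roi_y] <- TRUE
    m
  })

  labels <- matrix("background", n, n)
  labels[brain] <- "tissue"
  labels[frac > 0.5] <- "ventricle"
  labels[cortex] <- "cortex"

  # T2w grid: exact-count realisation of the same ellipses
  ip <- geom$t2w_fov_mm / geom$t2w_n
  voxvol <- ip^2 * geom$t2w_slice_mm
  n_target <- round(spec$ventricular_volume / voxvol)
  tx <- (seq_len(geom$t2w_n) - 0.5) * ip + geom$t2w_offset_mm
  xs <- range(vapply(ellipses, function(e) c(e$cx - e$rx, e$cx + e$rx),
                     numeric(2)))
  ys <- range(vapply(ellipses, function(e) c(e$cy - e$ry, e$cy + e$ry),
                     numeric(2)))
  ci <- which(tx >= xs[1] - 0.5 & tx <= xs[2] + 0.5)
  cj <- which(tx >= ys[1] - 0.5 & tx <= ys[2] + 0.5)
  sub_x <- matrix(tx[ci], length(ci), length(cj))
  sub_y <- matrix(tx[cj], length(ci), length(cj), byrow = TRUE)
  rho2d <- vent_rho(as.vector(sub_x), as.vector(sub_y), ellipses)
  # uniform through-slice shape: replicate the in-plane field over slices
  rho <- rep(rho2d, times = geom$t2w_slices)
  if (n_target > length(rho)) {
    abort("target ventricular volume is not representable on this geometry.")
  }
  sel <- order(rho)[seq_len(n_target)]
  mask <- array(FALSE, c(geom$t2w_n, geom$t2w_n, geom$t2w_slices))
  n_sub <- length(ci) * length(cj)
  slice_of <- (sel - 1L) %/% n_sub
  within <- (sel - 1L) %% n_sub
  mask[cbind(ci[(within %% length(ci)) + 1L],
             cj[(within %/% length(ci)) + 1L],
             slice_of + 1L)] <- TRUE

  bx <- matrix(tx, geom$t2w_n, geom$t2w_n)
  by <- matrix(tx, geom$t2w_n, geom$t2w_n, byrow = TRUE)
  brain2d <- (bx - 16)^2 + (by - 16)^2 <= geom$brain_radius^2
  brain3d <- array(rep(brain2d, geom$t2w_slices),
                   c(geom$t2w_n, geom$t2w_n, geom$t2w_slices))

  structure(
    list(
      asl = list(
        n = n, voxel_mm = geom$asl_voxel_mm,
        csf_frac = frac, tissue_frac = tissue_frac, brain = brain,
        cortex_mask = cortex, ventricle_masks = vent_masks,
        labels = labels
      ),
      t2w = list(
        mask = mask, brain = brain3d,
        in_plane_mm = ip, slice_thickness_mm = geom$t2w_slice_mm,
        n_slices = geom$t2w_slices, voxel_volume_mm3 = voxvol,
        n_voxels = n_target
      ),
      realized_volume = n_target * voxvol,
      spec = spec
    ),
    class = "bcsfb_phantom"
  )
}

#' @export
print.bcsfb_phantom <- function(x, ...) {
  cat(sprintf("<bcsfb_phantom: %s-like>\n", x$spec$preset))
  cat(sprintf("  realized ventricular volume %.4f mm^3 (target %.4g)\n",
              x$realized_volume, x$spec$ventricular_volume))
  cat(sprintf("  ASL CSF volume (fractions x 4.8 mm): %.2f mm^3\n",
              sum(x$asl$csf_frac) * 4.8))
  invisible(x)
}

#' ROI set for a phantom at a given slice thickness
#'
#' Convenience wrapper building the [roi_set()] (cortex band plus the two
#' 3x3 ventricular ROIs) for one ASL variant of a phantom.
#'
#' @param phantom A [build_phantom()] result.
#' @param slice_thickness_mm Slice thickness of the ASL variant (mm).
#' @return An [roi_set()].
#' @export
phantom_rois <- function(phantom, slice_thickness_mm) {
  stopifnot(inherits(phantom, "bcsfb_phantom"))
  roi_set(
    cortex_mask = phantom$asl$cortex_mask,
    ventricle_masks = phantom$asl$ventricle_masks,
    voxel_volume_mm3 = phantom$asl$voxel_mm^2 * slice_thickness_mm
  )
}
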