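#' Write / read a paired ASL series as NIfTI plus a JSON sidecar
#'
#' The selective and non-selective stacks are written as two 4-D NIfTI
#' volumes `<prefix>_selective.nii.gz` / `<prefix>_nonselective.nii.gz`
#' (dimensions x, y, TI, repetition; in-plane pixdim from the protocol) and
#' the acquisition protocol as `<prefix>_protocol.json`.
#'
#' @param series An [asl_series()].
#' @param prefix Path prefix for the three files.
#' @return `write_asl_series()` returns `prefix` invisibly;
#'   `read_asl_series()` returns an [asl_series()].
#' @export
write_asl_series <- function(series, prefix) {
  stopifnot(inherits(series, "asl_series"))
  p <- series$protocol
  vox <- p$fov_mm / p$matrix_size
  wr <- function(arr, path) {
    img <- RNifti::asNifti(arr)
    RNifti::pixdim(img) <- c(vox, vox, p$slice_thickness_mm, 1)
    RNifti::writeNifti(img, path)
  }
  wr(series$selective, paste0(prefix, "_selective.nii.gz"))
  wr(series$nonselective, paste0(prefix, "_nonselective.nii.gz"))
  jsonlite::write_json(
    list(ti_s = p$ti_s, te_ms = p$te_ms, repetitions = p$repetitions,
         matrix_size = p$matrix_size, fov_mm = p$fov_mm,
         slice_thickness_mm = p$slice_thickness_mm, variant = p$variant),
    paste0(prefix, "_protocol.json"), auto_unbox = TRUE, digits = NA
  )
  invisible(prefix)
}

#' @rdname write_asl_series
#' @export
read_asl_series <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, "_protocol.json"),
                              simplifyVector = TRUE)
  protocol <- acquisition_protocol(
    ti_s = meta$ti_s, te_ms = meta$te_ms, repetitions = meta$repetitions,
    matrix_size = meta$matrix_size, fov_mm = meta$fov_mm,
    slice_thickness_mm = meta$slice_thickness_mm, variant = meta$variant
  )
  rd <- function(path) {
    img <- RNifti::readNifti(path)
    array(as.double(img), dim = dim(img))
  }
  asl_series(rd(paste0(prefix, "_selective.nii.gz")),
             rd(paste0(prefix, "_nonselective.nii.gz")),
             protocol)
}

#' Write / read a T2-weighted stack as NIfTI
#'
#' @param stack A [t2w_stack()].
#' @param path NIfTI file path (`.nii` or `.nii.gz`).
#' @return `write_t2w_stack()` returns `path` invisibly;
#'   `read_t2w_stack()` returns a [t2w_stack()] with geometry taken from
#'   the NIfTI pixdim.
#' @export
write_t2w_stack <- function(stack, path) {
  stopifnot(inherits(stack, "t2w_stack"))
  img <- RNifti::asNifti(stack$data)
  RNifti::pixdim(img) <- c(stack$in_plane_mm, stack$in_plane_mm,
                           stack$slice_thickness_mm)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_t2w_stack
#' @export
read_t2w_stack <- function(path) {
  img <- RNifti::readNifti(path)
  pd <- RNifti::pixdim(img)
  t2w_stack(array(as.double(img), dim = dim(img)),
            in_plane_mm = pd[1], slice_thickness_mm = pd[3])
}

#' Write / read a voxel mask as NIfTI
#'
#' Masks are stored as 0/1 integer volumes; on reading, values above 0.5
#' become `TRUE`.
#'
#' @param mask Logical array.
#' @param path NIfTI file path.
#' @param pixdim_mm Optional voxel dimensions written to the header.
#' @return `read_mask()` returns a logical array.
#' @export
write_mask <- function(mask, path, pixdim_mm = NULL) {
  stopifnot(is.logical(mask))
  arr <- array(as.integer(mask), dim(mask))
  img <- RNifti::asNifti(arr)
  if (!is.null(pixdim_mm)) RNifti::pixdim(img) <- pixdim_mm
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  img <- RNifti::readNifti(path)
  array(as.double(img), dim = dim(img)) > 0.5
}
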