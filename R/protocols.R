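#' Acquisition protocol for one FAIR-ASL variant
#'
#' Describes the inflow-time schedule and geometry of a single-slice,
#' multi-TI FAIR acquisition.
#'
#' @param ti_s Inflow times (s), strictly increasing.
#' @param te_ms Echo time (ms). The ultra-long 220 ms readout suppresses
#'   short-T2 tissue/blood signal, isolating ventricular CSF.
#' @param repetitions Label/control pairs acquired per TI (`>= 1`).
#' @param matrix_size In-plane matrix (square), default 32.
#' @param fov_mm In-plane field of view (mm, square), default 32.
#' @param slice_thickness_mm Imaging slice thickness (mm).
#' @param variant Label, `"bcsfb"` or `"standard"`.
#' @return An object of class `acquisition_protocol`.
#' @export
acquisition_protocol <- function(ti_s, te_ms, repetitions,
                                 matrix_size = 32L, fov_mm = 32,
                                 slice_thickness_mm, variant = "custom") {
  stopifnot(
    is.numeric(ti_s), length(ti_s) >= 2L, all(diff(ti_s) > 0), all(ti_s > 0),
    is.numeric(te_ms), te_ms > 0,
    repetitions >= 1, matrix_size >= 1, fov_mm > 0, slice_thickness_mm > 0
  )
  structure(
    list(
      ti_s = ti_s, te_ms = te_ms, repetitions = as.integer(repetitions),
      matrix_size = as.integer(matrix_size), fov_mm = fov_mm,
      slice_thickness_mm = slice_thickness_mm, variant = variant
    ),
    class = "acquisition_protocol"
  )
}

#' Preset protocols for the two ASL variants
#'
#' `bcsfb_protocol()`: TE = 220 ms, 4.8 mm slice, TIs
#' \{0.2, 0.75, 1.5, 2.75, 4, 5, 6\} s, 10 repetitions per TI.
#' `standard_protocol()`: TE = 20 ms, 2.4 mm slice, TIs
#' \{0.2, 0.5, 1, 1.5, 2, 3, 4, 6\} s, 5 repetitions per TI.
#' Both use a 32x32 matrix over a 32x32 mm field of view.
#'
#' @return An `acquisition_protocol`.
#' @export
bcsfb_protocol <- function() {
  acquisition_protocol(
    ti_s = c(0.2, 0.75, 1.5, 2.75, 4, 5, 6),
    te_ms = 220, repetitions = 10L, slice_thickness_mm = 4.8,
    variant = "bcsfb"
  )
}

#' @rdname bcsfb_protocol
#' @export
standard_protocol <- function() {
  acquisition_protocol(
    ti_s = c(0.2, 0.5, 1, 1.5, 2, 3, 4, 6),
    te_ms = 20, repetitions = 5L, slice_thickness_mm = 2.4,
    variant = "standard"
  )
}

#' @export
print.acquisition_protocol <- function(x, ...) {
  cat(sprintf("<acquisition_protocol: %s>\n", x$variant))
  cat(sprintf("  TE %g ms, slice %g mm, %dx%d over %gx%g mm\n",
              x$te_ms, x$slice_thickness_mm, x$matrix_size, x$matrix_size,
              x$fov_mm, x$fov_mm))
  cat(sprintf("  TIs (s): %s; %d repetitions\n",
              paste(x$ti_s, collapse = ", "), x$repetitions))
  invisible(x)
}
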