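# Shared fixture builders; everything is generated in code at test time.

bcsfb_tis <- c(0.2, 0.75, 1.5, 2.75, 4, 5, 6)
standard_tis <- c(0.2, 0.5, 1, 1.5, 2, 3, 4, 6)

make_ir_curve <- function(t1, m0, beta = 1, ti = bcsfb_tis, sd = 0,
                          seed = NULL) {
  y <- ir_model(ti, t1, m0, beta)
  if (sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    y <- y + rnorm(length(ti), 0, sd)
  }
  tibble::tibble(ti_s = ti, mean_signal = y)
}

make_bcsfb_curve <- function(rate, t1_csf = 4.24, m0 = 1000,
                             ti = bcsfb_tis, ...) {
  p <- kinetic_params(rate, t1_dest = t1_csf, m0 = m0, ...)
  tibble::tibble(ti_s = ti, delta_m = bcsfb_csf_signal(ti, p))
}

make_tissue_curve <- function(rate, t1_cortex = 1.88, m0 = 1000,
                              lambda = 0.9, ti = standard_tis,
                              arrival_time = 0.3, ...) {
  p <- kinetic_params(rate, t1_dest = t1_cortex, m0 = m0,
                      arrival_time = arrival_time, ...)
  tibble::tibble(ti_s = ti, delta_m = pasl_tissue_signal(ti, p, lambda))
}

# A sample with exactly the requested mean and SD, for cross-checking the
# summary-statistic t-test against stats::t.test on raw data.
make_sample <- function(n, mean, sd) {
  base <- as.vector(scale(seq_len(n)))
  mean + sd * base
}

# Minimal paired series on a small grid with a uniform ROI profile.
make_uniform_series <- function(dm_profile, ctrl_profile,
                                protocol = bcsfb_protocol(), nx = 8,
                                noise_sd = 0, seed = 1) {
  n_ti <- length(protocol$ti_s)
  stopifnot(length(dm_profile) == n_ti, length(ctrl_profile) == n_ti)
  n_rep <- protocol$repetitions
  base_ctrl <- array(rep(ctrl_profile, each = nx * nx),
                     c(nx, nx, n_ti, n_rep))
  base_sel <- array(rep(ctrl_profile + dm_profile, each = nx * nx),
                    c(nx, nx, n_ti, n_rep))
  if (noise_sd > 0) {
    set.seed(seed)
    base_sel <- base_sel + array(rnorm(length(base_sel), 0, noise_sd),
                                 dim(base_sel))
    base_ctrl <- base_ctrl + array(rnorm(length(base_ctrl), 0, noise_sd),
                                   dim(base_ctrl))
  }
  asl_series(base_sel, base_ctrl, protocol)
}

make_small_rois <- function(nx = 8, voxel_volume = 4.8) {
  cortex <- matrix(FALSE, nx, nx); cortex[1:2, 1:2] <- TRUE
  v1 <- matrix(FALSE, nx, nx); v1[4:5, 4:5] <- TRUE
  v2 <- matrix(FALSE, nx, nx); v2[7:8, 7:8] <- TRUE
  roi_set(cortex, list(v1, v2), voxel_volume)
}
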