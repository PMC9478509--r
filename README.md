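# bcsfbasl

Quantification of blood–CSF-barrier (BCSFB) water delivery and cortical
perfusion from multi-inflow-time FAIR arterial spin labelling (ASL) MRI.

## What it is for

The choroid plexus secretes cerebrospinal fluid across the blood–CSF
barrier inside the brain's lateral ventricles. BCSFB-ASL measures the rate
at which magnetically labelled arterial blood water is delivered across
that barrier into ventricular CSF — a non-invasive surrogate of choroid
plexus function — by combining a FAIR labelling scheme with an ultra-long
echo time (TE = 220 ms) that suppresses everything except CSF. A
conventional short-TE variant of the same acquisition yields cortical
cerebral blood flow (CBF). The package is aimed at preclinical perfusion
researchers who want a tested, reproducible implementation of this
quantification chain, including the two-group (hypertensive SHR vs
normotensive WKY rat) statistics it was designed around, plus a digital
phantom so the whole pipeline runs without scanner data.

The chain, per subject:

1. **Signal extraction** — ROI averages of paired slice-selective /
   non-selective images; pairwise subtraction gives the perfusion-weighted
   ΔM(TI) curve, the control signal gives an inversion-recovery M_c(TI)
   curve.
2. **Relaxometry** — nonlinear least squares of
   `M_c(t) = M0 (1 − 2 β e^(−t/T1))` yields each compartment's T1 and M0
   (T1_CSF from the long-TE data, cortical T1 from the short-TE data).
3. **Ventricular-volume M0 correction** —
   `M0_corr = M0 × V_ventricles / V_ROI` (V_ROI = 86.4 mm³ for the two
   3×3-voxel functional ROIs), with V_ventricles from segmented
   T2-weighted morphometry.
4. **Kinetic-model fitting** — both variants fit the closed-form inflow
   integral `I = ∫ e^(−s/T1b) e^(−(t−s)/T1d) ds` over the bolus window
   `[Δt, min(t, Δt+τ)]`:
   `ΔM(t) = 2 α M0 r I` with `T1d = T1_CSF` (two-compartment CSF model,
   no outflow) or with the apparent tissue T1 including venous clearance
   (single-compartment Buxton model). The BCSFB fit holds the
   pilot-optimised bolus timing (Δt = 1.04 s, τ = 3.66 s) fixed and frees
   only the rate.
5. **Reporting units** — total delivery = rate × 86.4 mm³ × 60 (µl/min);
   CBF = rate × λ × 6000 (ml/min/100 g, λ = 0.9 ml/g).
6. **Group statistics** — pooled-variance Student's t-tests, percent and
   fold changes, from subject tables or directly from published summary
   statistics.

## Worked example

Simulate one normotensive-preset subject (noisy acquisition) and quantify
it:

```r
library(bcsfbasl)

subj <- simulate_subject(phantom_spec("WKY"), seed = 42,
                         subject_id = "wky_01")
res <- run_subject(subj)
dplyr::select(res, total_delivery, cbf, t1_csf, t1_cortex,
              ventricular_volume)
#> # A tibble: 1 × 5
#>   total_delivery   cbf t1_csf t1_cortex ventricular_volume
#>            <dbl> <dbl>  <dbl>     <dbl>              <dbl>
#> 1           14.9  123.   4.24      1.88               56.0
```

The subject was generated with a ground-truth delivery of 14.4 µl/min,
CBF 123 ml/min/100 g, T1_CSF 4.24 s, cortical T1 1.88 s and 56 mm³
ventricles; the recovered values match up to measurement noise (with
`phantom_spec("WKY", noise_sd = 0)` they match to ~1e-6). `autoplot()` on
the audit objects (`attr(res, "audit")`) draws the fitted IR and kinetic
curves; `run_cohort()` does the same over a two-group cohort and returns
the comparison table.

Analysing the published WKY/SHR group summaries shipped with the package:

```r
comp <- compare_groups_summary(reported_group_summaries(),
                               reference = "WKY")
dplyr::select(comp, metric, mean_ref, mean_other, t, p,
              percent_change, fold_change)
#> # A tibble: 5 × 7
#>   metric             mean_ref mean_other      t          p percent_change fold_change
#> 1 total_delivery        14.4        9.22  2.29  0.0452              36.0        0.640
#> 2 cbf                  123        118     0.438 0.671                4.07       0.959
#> 3 t1_csf                 4.24       4.58 -4.71  0.000823            -8.02       1.08
#> 4 t1_cortex              1.88       1.91 -2.12  0.0599              -1.60       1.02
#> 5 ventricular_volume    56         83    -8.54  0.00000663         -48.2        1.48
```

Read: hypertensive animals show a 36% reduction in BCSFB-mediated water
delivery (p < 0.05), a lengthened T1_CSF (p < 0.01) and a 1.48-fold
ventriculomegaly (p ≈ 6×10⁻⁶), while cortical CBF and cortical T1 do not
differ significantly — altered CSF homeostasis without a detectable
cerebrovascular deficit.

See `vignette("bcsfb-asl-methods")` for the models, the phantom's
assumptions, and the numerical design choices.

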