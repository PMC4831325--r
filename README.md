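# gfr2c — GFR from renal DCE-MRI two-compartment models

`gfr2c` estimates single-kidney glomerular filtration rate (GFR) from
ROI-averaged dynamic contrast-enhanced MRI signal curves of the aorta
and the kidney parenchyma. It is written for renal-physiology and
MR-methods researchers who have extracted signal–time curves (1.7 s
temporal resolution, 135 frames, 10 precontrast in the emulated
protocol) and want a subject-specific, reproducible GFR analysis
together with the standard comparator models and agreement statistics.

## The model

The aortic plasma input is a two-gamma-variate AIF,
`Ao_p(t) = Σᵢ aᵢ (t−tᵢ)₊^bᵢ exp(−(t−tᵢ)/cᵢ)` (first pass +
recirculation), obtained from the aortic enhancement divided by
`1 − Hct`. The renal plasma compartment sees this input delayed by δ and
dispersed with time constant `T_disp`:

    dP/dt = (Ao_p(t − δ) − P) / T_disp ,  P(0) = 0.

The subject-specific two-compartment (SS-2C) **uptake model** describes
the parenchymal concentration up to the end of the uptake phase,

    C_k(t) = v_p · P(t) + (GFR_V / 60) · ∫₀ᵗ P(s) ds ,

with `v_p` the fractional plasma volume and `GFR_V` (min⁻¹) the
filtration rate per unit parenchymal volume; whole-kidney GFR is
`GFR_V × volume` (mL/min). The end-of-uptake point — the maximum
parenchymal enhancement before significant tracer outflow — is detected
automatically per subject from the smoothed curve derivative. Comparator
fits use fixed 90 s / 110 s windows after the postaortic rise, and a
two-compartment **inflow–outflow model** with tubular mean transit time
`T_tub` (`dT/dt = (GFR_V/60) P − T/T_tub`) over the full acquisition.
Cohort agreement with a reference GFR is quantified by linear
regression and Bland–Altman bias with ±2 SD limits of agreement.

A seeded synthetic cohort generator reproduces the acquisition geometry
and the population heterogeneity (Hct 30–49%, volumes 158–333 mL,
uptake intervals 64–141 s) so every stage is testable without patient
data.

## Worked example

```r
library(gfr2c)

cohort <- simulate_cohort(cohort_config(n_subjects = 8, seed = 42))
sub <- cohort[[1]]
sub
#> <subject_record> sub01: Hct 0.35, volume 236 mL, reference GFR 141.5 mL/min (simulated)

fit <- estimate_subject_gfr(sub, method = "ss", hct_mode = "subject")
fit
#> <fit_result> method=ss R^2=0.99321 residual=6.709 GFR=109.4 mL/min
#> <kidney_params> v_p=0.318 gfr_v=0.4636 /min delay=0.633 s t_disp=11.2 s t_tub=NA s
sprintf("detected uptake interval: %.1f s (%s)",
        fit$provenance$uptake_interval, fit$provenance$detection_mode)
#> "detected uptake interval: 117.3 s (outflow_defined)"
```

The fit report reads: the SS-2C model matched this subject's renal
curve with R² = 0.993 over the subject's own 117 s uptake window,
estimating `GFR_V` = 0.46 min⁻¹, i.e. 109 mL/min for a 236 mL
parenchyma — an underestimate of the simulated truth, as expected when
an uptake model is fitted to curves whose tubules already drain (see the
methods vignette).

Cohort-level comparison against the reference GFR:

```r
res <- fit_cohort(cohort, methods = c("ss", "fixed90"),
                  hct_modes = c("subject", "fixed41"))
writeLines(format_cohort_summary(summarize_cohort(res)))
#> model            Hct        n  range (mL/min)  mean +/- SD     regression vs reference      Bland-Altman bias [LoA]
#> -------------------------------------------------------------------------------------------------------------------
#> reference        -          8    64.6-141.5     109.2 +/- 22.7   -                            -
#> ss               subject    8    60.5-109.4      92.7 +/- 17.7   slope 0.67, R^2 0.731, p 0.0068 -16.5 [-40.3, 7.3]
#> fixed90          subject    8    60.6-114.5      95.7 +/- 17.9   slope 0.74, R^2 0.883, p 0.00053 -13.5 [-30.4, 3.5]
#> ss               fixed41    8    65.2-104.8      88.7 +/- 14.9   slope 0.50, R^2 0.593, p 0.025 -20.5 [-49.9, 8.9]
#> fixed90          fixed41    8    65.4-113.0      91.7 +/- 15.4   slope 0.57, R^2 0.715, p 0.0082 -17.5 [-42.9, 7.9]
```

Within each model, using the measured subject hematocrit instead of the
fixed 41% literature value improves the correlation with the reference —
the `(1 − Hct)` scaling of the estimate is exact, so a wrong hematocrit
translates directly into a GFR error (0.72% per 1% relative Hct
deviation at Hct = 0.42).

A command-line wrapper over the same functions ships in
`inst/cli/gfr2c.R` with `simulate`, `detect`, `fit` and `compare`
subcommands.

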