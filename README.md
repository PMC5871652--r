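# ivimsim

Simulation and analysis tools for estimating intravoxel incoherent motion
(IVIM) parameters from **rapid three-b-value** diffusion-weighted MRI
protocols.

## The problem

The IVIM model describes the normalized DWI signal as a bi-exponential
decay,

    S(b)/S(0) = f · exp(−b·D*) + (1 − f) · exp(−b·D),

where *D* (mm²/s) is the tissue diffusion coefficient, *D\** the
perfusion-driven pseudo-diffusion coefficient, and *f* the perfusion
fraction. Because joint estimation of *D\** is unstable, clinical practice
favours the **segmented (constrained) fit**: assume the perfusion
compartment has fully decayed at high b, fit log S linearly over the high
b-values (S(b)/S(0) = exp(−b·D)), take D̂ = −slope, extrapolate to the
intercept S(int), and read the perfusion fraction from its offset,

    f̂ = 1 − S(int)/S(0).

With only three acquired b-values {0, b_low, b_high} the scan takes about
two minutes — but the choice of b_low trades an *intrinsic negative bias*
in f̂ (the perfusion residue left at low b_low steepens the high-b slope)
against *noise amplification* (extrapolating from high b_low inflates
variance). `ivimsim` quantifies that trade-off by Monte-Carlo simulation
across tissue scenarios (brain D*/D = 10, kidney 20, liver 70; D fixed at
0.7×10⁻³ mm²/s), schemes [200,1000]…[900,1000] s/mm², and SNR levels
40/55/80, and recommends schemes by minimal overall relative error
σ_D+f = σ_D + σ_f. A synthetic grey-matter cohort generator and a voxelwise
pipeline (parameter maps, mask resampling, histograms, Bland–Altman,
within-subject CV) support in-vivo-style analyses end to end.

Audience: MR physicists and image-analysis researchers choosing b-value
protocols for perfusion-fraction mapping, or validating segmented-fit
pipelines against known ground truth.

## Worked example

```r
library(ivimsim)

cfg <- study_config(models = tissue_models(), b_low = c(300, 500),
                    snr = c(40, 55), n_iter = 1000, seed = 42)
study <- run_simulation_study(cfg)
study
#> <ivim_study> 3 models x 2 schemes x 2 SNR levels, 13 f values, N = 1000 (rms_db)
#> Recommended schemes (lowest overall relative error):
#>   model snr       best overall_mean
#>   brain  40 [500,1000]   0.25016927
#>   brain  55 [500,1000]   0.11927565
#>  kidney  40 [300,1000]   0.13783273
#>  kidney  55 [500,1000]   0.03807661
#>  liver   40 [300,1000]   0.12989109
#>  liver   55 [300,1000]   0.02325082
```

For the low-perfusion brain model the grid-level table shows why
[500,1000] wins at SNR 40:

```r
study$grid |>
  dplyr::filter(model == "brain") |>
  dplyr::select(scheme, snr, bias_f_mean, cov_f_mean, relerr_f_mean, overall_mean)
#>       scheme snr bias_f_mean cov_f_mean relerr_f_mean overall_mean
#> 1 [300,1000]  40     -0.2173      12.63        0.2443        0.324
#> 2 [300,1000]  55     -0.2165       2.24        0.2175        0.286
#> 3 [500,1000]  40     -0.0858      17.82        0.1890        0.250
#> 4 [500,1000]  55     -0.0840       3.17        0.0904        0.119
```

Reading: fitting from b = 300 carries a −22% intrinsic bias in f̂
(perfusion residue), while fitting from b = 500 trades that for more noise
(CoV 17.8% vs 12.6% at SNR 40) but lower total error. `autoplot(study)`
draws the relative-error surface; `overall_error_table(study)` renders the
wide mean ± SD table.

The synthetic volunteer cohort reproduces the same orderings in an
image-domain pipeline:

```r
cohort <- generate_cohort(cohort_spec(seed = 42))   # 16 subjects, 4 rescanned
cohort_stats(cohort)
#> <ivim_cohort_stats> schemes [300,1000] vs [500,1000] (differences: first minus second)
#>   [300,1000]: cohort mean D = 0.862 x10^-3 mm^2/s, f = 0.124
#>   [500,1000]: cohort mean D = 0.844 x10^-3 mm^2/s, f = 0.139
#>   Bland-Altman bias: D 0.0178 x10^-3, f -0.0147
#>   wCV (%): [300,1000] D 0.8, [300,1000] f 4.3, [500,1000] D 1.4, [500,1000] f 6.0
```

Higher f̂ and lower D̂ with [500,1000], a negative Bland–Altman f bias for
[300,1000] vs [500,1000], and worse repeatability for f than for D — the
signature of the segmented fit in low-perfusion grey matter.

Fitted objects follow broom conventions: `tidy()` gives per-f (or
per-subject) tables, `glance()` one-row summaries, `autoplot()` standard
figures. `write_cohort()` / `read_bval()` / `fit_voxelwise()` exchange
standard NIfTI + FSL-bval files.

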