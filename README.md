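# perfquant

Fully quantitative first-pass myocardial perfusion CMR analysis in R, with
the companion measurements a microvascular-disease study needs: MOLLI-based
T1 and extracellular volume fraction (ECV), Agatston coronary calcium
scoring, and covariate-adjusted two-group cohort statistics. The package is
aimed at imaging scientists who want a tested, reproducible reference
implementation of the dual-sequence quantification chain, exercised
end-to-end on synthetic data with known ground truth.

## What it computes

**Myocardial blood flow (MBF).** A saturation-recovery spoiled-GRE pulse
train is simulated by the longitudinal recurrence
`Mz <- (Mz cos a) E1 + M0 (1 - E1)`, `E1 = exp(-TR/T1)`; proton-density
frames normalize away receiver scale, and the normalized ratio is inverted
on a dense lookup to T1, then to gadolinium concentration via
`1/T1 = 1/T10 + r1 C`. Tissue curves are deconvolved against the arterial
input function (AIF, measured with a short-SR low-resolution acquisition
that stays invertible at blood-pool concentrations) by bounded nonlinear
least squares with a Fermi impulse response

    R(t) = F / (1 + exp(k (t - td - w))),  t >= td,

and flow is the response amplitude at contrast arrival,
`MBF = R(td+) = F / (1 + exp(-k w))` in ml/min/g. Pixel-wise fits give an
MBF map; the mean over valid pixels is global perfusion, and
`MPR = stress MBF / rest MBF`.

**T1/ECV.** MOLLI 5(4)3 magnitude samples are fitted with
`|A - B exp(-TI/T1*)|` plus polarity restoration and Look-Locker correction
`T1 = T1*(B/A - 1)`; the partition coefficient λ is the OLS slope of
1/T1-myocardium on 1/T1-blood across serial timepoints, and
`ECV = λ (1 - hematocrit)`.

**Calcium.** Classic Agatston scoring: per-slice 4-connected components at
≥ 130 HU, area × peak-HU weight, summed over slices.

**Statistics.** Shapiro-Wilk-gated two-group comparisons (pooled t-test or
exact Wilcoxon-Mann-Whitney), Fisher exact tests for flags, and
covariate-adjusted group means (OLS with age, LV mass, BMI, gender;
adjusted means at covariate grand means, Tukey adjustment beyond two
groups).

**Synthetic data.** Seeded generators for every input: gamma-variate AIFs,
Fermi-convolved tissue curves encoded through the same signal model the
analysis inverts, MOLLI samples, CT phantoms with exact-area lesions, and
two-group cohorts shaped like a 46-vs-20 study design.

## Worked example

```r
library(perfquant)

# one synthetic subject: true rest 1.1, stress 3.0 ml/min/g, SNR 30
rest   <- gen_dynamic_series(matrix(1.1, 4, 4), snr = 30, seed = 101)
stress <- gen_dynamic_series(matrix(3.0, 4, 4), snr = 30, seed = 102)
mask <- array(TRUE, c(4, 4, 1))
q_rest   <- quantify_perfusion(rest$imaging,   rest$aif,   myo_mask = mask)
q_stress <- quantify_perfusion(stress$imaging, stress$aif, myo_mask = mask)
compute_mpr(q_stress$global_mbf, q_rest$global_mbf)
```

```
rest MBF   1.16 ml/min/g
stress MBF 2.92 ml/min/g
MPR        2.51
```

The estimates sit a few percent from the injected truth (1.1 / 3.0 / 2.73):
at SNR 30 the per-pixel Fermi fits scatter, but the 16-pixel global means
recover the flows closely.

```r
ch <- gen_cohort(cohort_spec_default(), seed = 7)
compare_continuous(ch$table, "stress_mbf")
```

```
stress_mbf: Two-sample t-test (pooled), p = 0.005658
    group  n     mean        sd   median       q1       q3
  control 20 3.199545 0.3842061 3.183033 3.021463 3.452940
 mvd_risk 46 2.766309 0.6256619 2.657818 2.290299 3.278315
```

The generated cohort reproduces the study shape: the risk group's stress
perfusion is significantly lower than the controls'. T1, ECV and calcium
follow the same pattern:

```r
fit_molli(gen_molli_samples(1000))$t1_ms   # 1000.0 ms
compute_ecv(0.45, 0.40)                    # 0.27
vol <- gen_ct_phantom(dims = c(16, 16, 1),
  lesions = data.frame(slice = 1, x = 4, y = 4, n_pixels = 4, hu = 450))
agatston_score(vol)$total                  # 16  (4 mm^2 x weight 4)
```

The whole study shape — simulate, quantify, tabulate — runs as one call:

```r
run_demo_study(seed = 42, out_dir = "demo")   # cohort.csv, table1/2.csv,
                                              # adjusted_models.csv, recovery.csv
```

A command-line front end for each stage lives at
`inst/cli/perfquant.R` (`simulate`, `quantify`-style stages, `ecv`, `cac`,
`stats`, `demo-study`).

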