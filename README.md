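# melflick

Silent-substitution stimulus design and flicker-detection threshold
analysis for melanopsin psychophysics — an end-to-end, fully simulated
re-implementation of the computations behind a "does melanopsin stimulation
change cone-mediated flicker sensitivity?" experiment.

The package is for visual psychophysicists and colorimetry methodologists
who want the complete computational chain of such a study as tested,
reusable code: photoreceptor-directed stimulus design on a multiprimary
light source, an adaptive-staircase two-interval forced-choice (2IFC)
trial engine, psychometric threshold estimation, and the stimulus-artifact
("splatter") analyses that decide whether small device imprecisions could
mimic or mask a real effect.

## What it computes

**Colorimetry.** Receptor excitations are rectangle-rule integrals of
spectrum × sensitivity, `e_r = Σ S_r(λ) Φ(λ) Δλ`, for L, M, S cones and
melanopsin (curves normalized to unit peak). Weber contrast per class is
`c_r = (e_mod − e_bg)/e_bg`; LMS content/contrast is the equally weighted
mean over the three cones; chromatic splatter is `(c_L − c_M)/c_LMS`.

**Silent substitution.** The device is linear in its settings, so designing
a background pair with melanopic Weber contrast `T = 3.5` (350%, i.e. a
4.5× excitation step) while silencing the cones is a linear
equality-constrained problem, solved in closed form with a gamut-box
fallback; infeasible targets bisect to the maximum achievable. Flicker arms
deliver equal contrast on L, M, S with melanopsin silent; scatter light is
compensated by re-solving against the total light.

**Psychophysics.** Three interleaved staircases (down on each correct
response; up after 3, 2, or 1 consecutive errors) schedule 120 trials per
condition on a 0–5% contrast grid. Simulated observers follow the
cumulative Weibull `p(c) = γ + (1−γ−λ)(1−exp(−(c/α)^β))` with γ = 0.5.

**Thresholds and JNDs.** Each block is fit by maximum likelihood (γ fixed
at 0.5, λ ∈ [0, 0.05], slope free, multistart + quasi-Newton); threshold
is the closed-form inversion at 70.71% correct; JND = threshold ×
background LMS content, normalized so the low-condition median is 1;
summaries use median ± 1.58·IQR/√n.

**Splatter predictors.** Three null-mediation models convert measured
stimulus deviations into predicted normalized JNDs (background Weber's
law, measured/nominal flicker ratio, L–M chromatic mediation). Fed the
melanopsin excitations of the 350% pair, the first predictor returns the
Weber's-law positive-control bound of 4.5×.

## Worked example

```r
library(melflick)

sens   <- default_sensitivities()
device <- make_synthetic_device(seed = 1)
pair   <- solve_background_pair(device, sens, target_contrast = 3.5)
round(pair$achieved_contrasts, 6)
#>   L   M   S Mel
#>   0   0   0 3.5

e_lo <- excitation(device_spectrum(device, pair$low_settings),  sens)
e_hi <- excitation(device_spectrum(device, pair$high_settings), sens)
e_hi[["Mel"]] / e_lo[["Mel"]]
#> [1] 4.5
```

The exchange raises melanopsin excitation 4.5× (a 350% Weber contrast)
with residual cone contrasts at numerical zero. Running the simulated
adaptation experiment and its analysis:

```r
res <- run_experiment1(run_config(list(seed = 1)))
writeLines(res$report[4:7])
#> Within-session high - low normalized JND differences:
#>   participant 1: median -0.052, 95% CI [-0.200, +0.096] -> covers zero
#>   participant 2: median +0.208, 95% CI [+0.026, +0.391] -> excludes zero
#>   participant 3: median -0.091, 95% CI [-0.451, +0.270] -> covers zero
```

Observers here are null (no melanopsin effect): two of three confidence
intervals cover zero, and the methods vignette explains why occasional
exclusions are exactly what this interval produces at four sessions. The
cone-directed positive control in the same run lands near the Weber's-law
4.5× JND step (4.63, 4.36, 4.53 for the three simulated participants).

## The analysis workflow

Numbered drivers under `analysis/` run the study stage by stage, writing
tables under `results/`:

| script | what it does |
|---|---|
| `01_design_stimuli.R` | designs backgrounds/flicker, writes spectra + design report |
| `02_simulate_study.R` | simulates the adaptation experiment (null observers) |
| `03_fit_thresholds.R` | refits thresholds from the archived trial-log CSV |
| `04_pedestal_experiments.R` | pulsed-pedestal runs: substitution vs projector flicker |
| `05_splatter_analysis.R` | the three artifact predictors + Weber's-law bound |

Each is a thin narrative over exported package functions and takes seconds.

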