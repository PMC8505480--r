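---
title: "Methods: silent-substitution design and flicker-threshold analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: silent-substitution design and flicker-threshold analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The scientific problem

Intrinsically photosensitive retinal ganglion cells (ipRGCs) express the
photopigment melanopsin and are best known for reflexive functions (pupil
control, circadian entrainment). Whether tonic or transient melanopsin
stimulation also modulates cone-mediated *perception* — specifically, the
threshold for detecting luminance (LMS) flicker — can be tested by holding
cone excitation constant while stepping melanopsin excitation by a large
factor, and measuring flicker-detection thresholds on each background.

`melflick` implements that test end-to-end *in silico*: silent-substitution
stimulus design on a model multiprimary light source, a staircase-driven
two-interval forced-choice (2IFC) experiment against simulated Weibull
observers, maximum-likelihood threshold estimation, and the artifact
("splatter") analyses that ask whether small stimulus imprecisions could
masquerade as — or mask — a melanopsin effect.

# Colorimetry

A spectrum on a uniform wavelength grid (default 380–780 nm in 2 nm steps)
excites receptor class $r$ by the rectangle-rule integral

$$ e_r = \sum_\lambda S_r(\lambda)\,\Phi(\lambda)\,\Delta\lambda , $$

with every sensitivity $S_r$ normalized to a peak of 1. Whether
$\Delta\lambda$ is included is a pure convention — it cancels from every
Weber contrast $c_r = (e_{\mathrm{mod},r}-e_{\mathrm{bg},r})/e_{\mathrm{bg},r}$
and from all normalized JND statistics — but we state it so excitations are
reproducible in absolute units.

Two combination conventions exist in the field for "LMS content": the sum
and the mean of the three cone excitations. They differ by a constant
factor of 3 that cancels in every contrast and every normalized quantity;
the package adopts the **mean** everywhere (so that a modulation with 5%
contrast on each cone class has `lms_contrast` exactly 0.05, matching the
nominal contrast scale of the experiment) and exposes the `"sum"`
convention so the invariance can be demonstrated. The chromatic-splatter
statistic is the ratio $(c_L - c_M)/c_{LMS}$, which is invariant both to
this convention and to uniform scaling of the modulation.

The packaged sensitivity set is a **synthetic, physiologically shaped
fixture**: four smooth Gaussian curves peaking near 440 (S), 480 (Mel),
530 (M) and 560 (L) nm with SDs of 20–32 nm. These are deliberately
somewhat narrower than tabulated human cone fundamentals; with realistic
overlap, a four-receptor silent substitution on a small synthetic primary
set cannot reach the large melanopic contrast the design targets (real
systems manage it with ~50 narrowband primaries and the fine spectral
structure of measured fundamentals). The narrower fixture preserves every
qualitative property of the problem — heavy L/M overlap, melanopsin between
S and M — while making the 350% design feasible on an 8-primary device.
Tabulated fundamentals can be supplied as CSV (`read_sensitivities_csv()`)
and everything downstream is agnostic to their origin. Field size (27.5°)
and pupil diameter (6 mm) are carried as metadata only; no retinal
irradiance conversion is performed because all analyses are in Weber
contrasts and normalized JNDs. Age-predicted lens filtering is applied by
multiplying each curve with an age-scaled synthetic lens-transmittance
template (valid ages 20–80, reference 32) and renormalizing.

# Stimulus design

The device model is linear: output = `primaries %*% settings + ambient`,
settings in $[0,1]^P$, optionally quantized to `quantization_levels`
uniform steps (256 by default — 8-bit control). Receptor excitations are
therefore linear in the settings, and once the target Weber contrast $T$ is
fixed, *every* design constraint is linear:

* silenced mechanisms: $r_c^\top(s_{hi} - s_{lo}) = 0$;
* directed mechanism: $r_m^\top s_{hi} - (1+T)\, r_m^\top s_{lo} = T\,a_m$
  (the ambient excitation $a_m$ enters because Weber contrast is computed
  on the total light).

The solver returns the pair closest (least squares) to a preferred
operating point subject to those equalities, via a closed-form KKT solve;
when that solution leaves the settings box, a penalized bounded
quasi-Newton refinement runs, followed by re-projection onto the equality
manifold. If the target is infeasible in gamut, the maximal achievable
contrast is located by bisection (each probe is a linear feasibility
problem) and returned with a warning. Both modes the original toolbox might
have used — hit a fixed target, or maximize — are thereby available.
Backgrounds keep a settings margin from the gamut edges (0.05 for the
melanopsin-directed pair, 0.04 for the brighter cone-directed control pair)
so the ±5% flicker arms remain realizable; the margins are explicit
constraints, not post-hoc rejection.

Flicker arms solve the same linearized system about a background: equal
Weber contrast on L, M and S with melanopsin unchanged, mirrored negative
arm. Scaling to a nominal contrast snaps to the 0.1% contrast grid
(half-away-from-zero) and scales the settings deviation; a steady scatter
spectrum (e.g. light from an admixed projector) is handled by re-solving
the arms against the total light so that contrasts are delivered as
specified on what actually reaches the eye — a scatter equal to the
background exactly halves uncorrected Weber contrast, which the tests use
as an algebraic fixture.

Temporal structure: 500 ms intervals of 5 Hz sinusoidal flicker drawn at a
60 Hz frame rate (reference intervals refresh identically with zero
modulation, so updating artifacts cannot cue the target), and half-cosine
pedestal ramps interpolated in *settings* space — the space a spectral
synthesizer is actually driven in. The ramp duration defaults to 500 ms
with a configuration override (`ramp_ms`), since descriptions of the
pedestal window in the source material give both 500 ms and 250 ms;
the choice does not affect any threshold statistic because adaptation
dynamics are not modeled.

# Simulated observers and the trial engine

Observers follow the cumulative Weibull used for fitting,
$$ p(c) = \gamma + (1-\gamma-\lambda)\left(1 - e^{-(c/\alpha)^\beta}\right), $$
with guess rate $\gamma = 0.5$ (2IFC), lapse $\lambda \in [0, 0.05]$, and
default $\alpha = 0.013$, $\beta = 3$, $\lambda = 0.01$ — a fixture choice
placing thresholds in the 1–2% contrast range typical of this task. The
observer responds to the **achieved** LMS contrast: the nominal contrast
times the measured/nominal contrast ratio of that session's perturbed
device, optionally plus a weighted $|c_L - c_M|$ term so that chromatic
splatter can mediate detection (`lm_weight`, default 0). A
`condition_effect` multiplies $\alpha$ in the high-melanopic condition
(1 = the null; 4.5 = a Weber's-law-sized effect). Responses are Bernoulli
per trial — inter-trial dependence and structured lapses in real observers
are explicitly out of model.

Contrast is scheduled by three interleaved staircases on the 0–5% grid in
0.1% steps: a correct response steps down, and 3, 2 or 1 *consecutive*
incorrect responses (a fixed rule per staircase) step up. Unstated
engine parameters are package defaults, all configurable: step 0.2%,
starts at 5%/2.5%/5% for rules 3/2/1, 120 trials allocated 40/40/40 in
seeded pseudorandom interleave. Note a structural property of these rules
under a 50% guess floor: the equilibria sit at or below the contrast where
$p = 0.5$, so levels drift low and the rule-3 staircase (rarest up-steps)
concentrates below the rule-1 staircase — the ordering asserted in the
tests was frozen from a pre-build Monte-Carlo run of the engine itself.
A preliminary threshold — used only to reconstruct at-threshold flicker
spectra for the splatter analysis — is the mean of the last four reversals
per staircase, pooled; blocks whose rule-3 staircase never reversed twice
fall back to pooled reversals, then to the median contrast of the last 20
trials.

Device calibration error is emulated by perturbing each primary with a
lognormal gain (SD 1%) and a wavelength shift (SD 1 nm) per session; the
perturbed device plays the role of the session's spectroradiometric
measurement. The same code path accepts externally supplied measured
spectra in a real deployment.

# Threshold estimation and statistics

Each 120-trial block is fit by maximum likelihood over
$(\alpha, \beta, \lambda)$ with $\gamma$ fixed at 0.5, $\lambda$ bounded in
$[0, 0.05]$ (closed bounds) and $\beta$ effectively unrestricted. The
likelihood is multimodal enough to warrant a multistart: a 5×5×3 coarse
grid over ($\alpha$ spanning the data's contrast range, $\beta \in
[0.5, 8]$, $\lambda \in \{0, 0.025, 0.05\}$) is scored and the best points
seed a bounded quasi-Newton (L-BFGS-B on $\log\alpha$, $\log\beta$,
$\lambda$); equal-likelihood ties break toward the lowest $\alpha$. A
brute-force likelihood grid is used as an oracle in the tests. Staircase
data constrain $\alpha$ well but $\beta$ poorly — an inherent property of
adaptive sampling, visible in the wide spread of fitted slopes.

Threshold is the closed-form inversion of the fit at the criterion
$\sqrt{1/2}$ (stored at full precision, displayed as 70.71% correct).
The JND is threshold contrast × measured background LMS content; JNDs are
normalized per participant so the low-condition median is exactly 1, which
makes high-condition values read as fold changes and cancels every
content-scale convention. Summary statistics use the type-7 quantile rule
(R's default) and the interval
$\mathrm{median} \pm 1.58\,\mathrm{IQR}/\sqrt{n}$.

**A caution on that interval.** The $1.58\,\mathrm{IQR}/\sqrt{n}$ rule is
the notched-boxplot heuristic, asymptotically a 95% CI for the median but
strongly anti-conservative at small $n$: for iid normal null samples at
$n = 4$ it covers the true median only ~75% of the time (n = 6: ~79%).
The pipeline reproduces exactly this intrinsic rate over replicate null
studies — with no added bias (the median within-session difference is
centered on zero) — so simulated "CI excludes zero" events at 4 sessions
per participant occur at roughly the 20–25% rate this interval implies,
not at 5%. Interpreting single-participant exclusions from this interval
therefore requires the replication the study design itself provides.

# Splatter (artifact) predictors

All three predictors share the null premise that melanopsin has no effect
on sensitivity, and convert measured stimulus deviations into the
normalized JNDs that premise implies:

1. **Background content (Weber's law):** the low-condition threshold
   contrast is carried to both conditions and multiplied by each
   background's measured LMS content. Fed the *melanopsin* excitations of
   the designed 350% pair instead, this is the Weber's-law positive-control
   bound: a predicted 4.5× JND fold change.
2. **Flicker imprecision:** the carried threshold is additionally scaled by
   each condition's measured/nominal flicker-contrast ratio — a flicker
   stronger than nominal in one condition mimics a sensitivity gain there.
3. **L–M chromatic mediation:** the measured $|L-M|$ contrast at the
   low-condition threshold is held constant across conditions and divided
   by each condition's $|(L-M)/LMS|$ ratio; more chromatic splatter in the
   high condition predicts a *lower* threshold there under the null.

All three return exactly 1 in both conditions when measured spectra equal
nominal spectra. When chromatic splatter is numerically absent (ratios
below $10^{-9}$), the report states the no-difference prediction directly
rather than dividing two rounding errors; the predictor itself treats an
exactly-zero ratio as an error, since mediation by a silent mechanism is
undefined. Per-participant aggregation is the median over sessions with a
standard error of the median approximated as $1.2533\,\mathrm{SD}/\sqrt{n}$.

# Problem sizes and reproducibility

The shipped analyses use 3 participants × 4 sessions (6 in the
projector-flicker mode) × 120 trials per condition, the replicate Monte
Carlo checks use 100 (tests: 60) single-participant replicate studies, and
the synthetic device has 8 Gaussian primaries (SD 14 nm, peaks 410–650 nm)
with 8-bit settings quantization and a small broadband ambient leak. Every
stochastic stage is seeded from a master seed (per-cell seeds are spawned
deterministically), so whole runs are bit-reproducible from their
configuration; `run_config()` accepts YAML/JSON or an in-code list.

# Known limitations

* The synthetic sensitivities and device are fixtures: passing tests show
  the *pipeline* is correct, not that any particular physical device can
  realize these designs; gamut feasibility must be re-established for real
  primaries and tabulated fundamentals.
* Adaptation dynamics, reaction times, inter-trial dependence, macular
  pigment and photopigment polymorphism are not modeled.
* The pedestal experiments simulate the two interleaved conditions as
  statistically independent trial streams; the pseudorandom interleaving
  of the real task matters for observer strategy, which is outside the
  Bernoulli observer model.
* Luminance photometry (cd/m²) is not computed; all quantities are Weber
  contrasts and normalized JNDs, where the unit conventions cancel.
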