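---
title: "Quantifying hemispheric asymmetry of TSPO PET binding: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying hemispheric asymmetry of TSPO PET binding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(petasym)
```

## The model

`petasym` quantifies [11C](R)PK11195 binding with the simplified reference
tissue model (SRTM). The model assumes the target region behaves as one
tissue compartment whose input is shared with a reference region devoid of
specific binding; here the reference is bilateral cerebellar grey matter
used as a *pseudoreference* — a region with some specific TSPO binding that
is assumed uniform across subjects, a standard choice for this tracer. The
operational solution is

$$C_T(t) = R_1\,C_R(t) + \left(k_2 - R_1 k_{2a}\right)\int_0^t
  C_R(s)\,e^{-k_{2a}(t-s)}\,ds, \qquad k_{2a} = \frac{k_2}{1 + BP_{ND}},$$

with three parameters: the tracer delivery ratio $R_1 = K_1/K_1'$ (the
influx constants never appear separately), the target efflux rate $k_2$
(1/min), and the non-displaceable binding potential $BP_{ND}$. The reported
binding measure is the distribution volume ratio $DVR = BP_{ND} + 1$, which
the package maintains as an exact identity everywhere. A late-window
standardized uptake value
$SUV_{40\text{–}60} = \bar{C}_{40\text{–}60}\,[\mathrm{kBq/mL}] \times
\text{weight}\,[\mathrm{kg}] / \text{activity}\,[\mathrm{MBq}]$ (unit tissue
density) summarises cerebellar uptake itself, which the reference-based DVR
cannot see.

## Numerical strategy

**Reference-curve representation.** Measured reference TACs are frame
averages on very uneven schedules (5 s to 10 min bins). The package treats
the reference as piecewise linear through (frame midpoint, value) anchored
at $(0, 0)$ and linearly extrapolated to the end of the last frame. The
convolution with $e^{-k_{2a}t}$ is then evaluated *segment-analytically*
(closed form per linear segment, propagated frame to frame), and model
values are exact integrals over each frame divided by frame duration —
never midpoint samples, which would bias the long late frames. A
fine-grid trapezoid quadrature oracle and the closed-form step-input
solution ($C_T \to DVR$ as $t \to \infty$) verify this machinery in the
test suite to 1e-8.

**Fitting.** `fit_srtm()` uses the basis-function method: for each
$k_{2a}$ on a 256-point logarithmic grid spanning 0.005–1.0 /min (bracketing
plausible PK11195 kinetics), the model is linear in $(\theta_1, \theta_2) =
(R_1,\, k_2 - R_1 k_{2a})$ and solved by weighted least squares in closed
form; the winning grid point is sharpened by two successive parabolic
interpolations of the weighted residual sum of squares in $\log k_{2a}$
(grid spacing is ~2% relative, so this localises the optimum far beyond the
accuracy the parameters support). Weights default to frame duration
(variance of decay-corrected frame means scales inversely with duration);
uniform weights are available. Pre-injection background frames get weight
zero. An independent multi-start Nelder-Mead nonlinear fitter
(`fit_srtm_nls()`) provides the cross-check used throughout the tests; the
two agree to better than 1e-3 in $BP_{ND}$ and $R_1$ on noiseless data.

**Degenerate and boundary fits.** When the target is proportional to the
reference ($\theta_2 = 0$ — including the exact identity case), $k_2$ and
$k_{2a}$ are unidentifiable but $R_1 = \theta_1$ and
$BP_{ND} = \theta_1 - 1$ still are; such fits are flagged `degenerate`
rather than silently reported. All-zero targets return zero parameters with
the same flag. Negative $BP_{ND}$ is admitted down to the grid ceiling
($k_{2a} \le 1$); solutions at a grid endpoint are flagged `boundary`,
never clamped. All TACs are assumed decay-corrected; there is no decay
handling anywhere.

## Laterality metrics and inference

Per region the package computes the asymmetry index
$AI = (R - L)/(R + L)$ and the signed relative difference
$100\,(R - L)/\overline{LR}$, which equals $200\,AI$ identically; positive
always means right larger. The *cohort* relative difference is the mean
paired difference over the mean of the side means — a cohort summary, not a
function of the printed medians. Effect size is paired Cohen's $d$: mean of
paired differences over their sample SD ($n-1$). The literature convention
this mirrors describes the relative difference via an absolute difference
but reports signed values; the package makes the metric signed and notes
that its absolute value reproduces the literal wording.
`percent_above_reference()` (difference as a percentage of a fixed
bilateral reference value) is provided as a helper because worked examples
in the literature sometimes use that formula; it is not used in the
summaries. Quartiles use linear interpolation (`stats::quantile` type 7) —
no convention is standard in the field, so one is fixed and documented.

Paired Wilcoxon signed-rank and two-sample Mann-Whitney tests are
implemented in-package so their exact small-sample paths can be verified by
brute-force enumeration: subset-sum counting of all $2^n$ sign assignments
(used for $n \le 25$, no tied absolute differences; zeros dropped, the
classical convention) and partition counting of all $\binom{n_1+n_2}{n_1}$
labelings (used when $\min(n_1, n_2) \le 8$ without ties). Larger samples
and ties use the tie-corrected normal approximation with continuity
correction. Multiplicity is controlled by the Holm-Šídák step-down rule
$p_{(i)} \mapsto 1 - (1-p_{(i)})^{m-i+1}$ with monotonicity enforcement;
because the literature is ambiguous about the family over which it was
applied, the family is always an explicit choice here: each summary battery
(the regions of one table) forms one family. Shapiro-Wilk and Pearson
tests delegate to the standard `stats` implementations.

The mixed model is
`DVR ~ hemisphere + age + sex + handedness + centre + centre:hemisphere +
(1 | subject)`, REML-estimated via `lme4` with Satterthwaite degrees of
freedom via `lmerTest` (Wald-normal fallback, with the method recorded in
the output). Reference levels are fixed — left hemisphere, female,
left-handed, Manchester — so estimates read as right-vs-left,
male-vs-female, right-vs-left-handed, Turku-vs-Manchester. Subjects with
unknown handedness cannot enter a handedness term and are excluded before
fitting (9 of 76 under the default cohort). Confidence intervals use the
t quantile at the same degrees of freedom as the p-values. In a balanced
paired design with no covariates the hemisphere estimate collapses exactly
to the mean paired difference, which the tests assert to 1e-10.

## What the synthetic generator emulates

`cohort_config()` defaults encode the emulated study conditions: 50 + 26
subjects from two centres scanned on their printed 18/17-frame, 60-minute
schedules (Manchester with a pre-injection background frame represented as
one frame ending at $t = 0$); six bilateral regions plus hemispheric GM and
GMWM aggregates and a bilateral cerebellar pseudoreference; demographics
with exact-count allocation (38/38 male/female; 59/8/9
right/left/unknown-handed); per-centre lognormal injected activities
matching the published medians and IQRs.

Ground-truth binding is built as $DVR_{side} = DVR_{bilat}(1 \pm
\delta/2)$ so the configured relative difference $\delta$ is exact in
expectation on the DVR scale: per-subject bilateral DVRs are baseline plus
a global intercept (SD 0.06, consistent with the published IQRs), and the
right-minus-left residual is Gaussian with per-region SD `pair_sd`.
The per-region baselines and injected differences are the published
regional values (e.g. +3.55% putamen, +1.87% GM); `pair_sd` is
back-calculated from the published Cohen's $d$ as
$\mathrm{sd} = DVR_{bilat}\,\delta / d$, since no within-subject variance
is published — a calibration choice, verified end-to-end by simulation (the
left and right fits share one measured reference, so fitting noise largely
cancels from the paired difference and contributes almost nothing to the
calibrated $d$). Covariate effects on DVR default to zero, matching the
null findings emulated, but slopes are configurable for power studies.
Volumes get mild asymmetries of both signs (left-larger thalamus/putamen,
right-larger cortices) independent of the binding asymmetry, so the
volume-vs-DVR asymmetry correlations are null by construction.

The reference input is a bi-exponential surge
$C_R(t) = A(e^{-\lambda_1 t} - e^{-\lambda_2 t})$ — the simplest shape with
realistic peak-then-washout behaviour and a closed-form peak time for
testing — rather than an arterial-input chain; its amplitude scales with
injected activity per body weight so SUVs land in a realistic range. Frame
noise is Gaussian with $\sigma_j = \alpha\sqrt{\max(v_j,
\mathrm{floor})/\Delta t_j}$, the standard variance model for
decay-corrected frame means, with no decay factor because all simulated
TACs are defined as decay-corrected. The default $\alpha = 0.1$ gives
roughly 1–2% peak-frame coefficient of variation, appropriate for
ROI-average TACs pooled over many voxels (regional DVR estimator bias at
this level is below 0.1%, measured by simulation). Every random draw flows
through one stream per subject derived by hashing the master seed with the
subject index, so cohorts are deterministic, and extending a cohort never
reshuffles earlier subjects' kinetics.

**What it does not emulate.** No arterial input or metabolite kinetics, no
decay, no scanner resolution or partial-volume effects, no attenuation or
scatter, no registration or segmentation error, no genuine biological
covariate structure. Passing tests therefore demonstrate that the
*analysis chain* is correct and calibrated under the stated statistical
structure — not that real data meet that structure.

## Image mode

The ROI layer reproduces the image-side conventions: grey-matter
probability maps are binarized at 0.5 with the threshold value itself
*included* (the boundary case is unspecified in the literature; inclusive
keeps the printed threshold inside the mask); composite regions are unions
of atlas labels, intersected with the GM mask only for GM-tissue regions
(cortices, hemispheric GM, cerebellar reference) and never for the
GMWM regions (thalamus, putamen, whole brain); regional values are
unweighted voxel means after binarization, matching the
binarize-then-apply order; volumes are voxel count times voxel volume.
Label and probability volumes live in voxel-index space — alignment is the
caller's responsibility, since registration is out of scope. The default
analysis path fits the ROI-mean TAC per region; voxelwise fit-then-average
is possible through the same fitter but the two are not assumed
interchangeable. A digital phantom (mirror-placed blobs carrying known
forward TACs, with a probability shell straddling the 0.5 threshold)
exercises the whole image path against exact expectations.

## Problem sizes and reproducibility

The simulation studies shipped with the package use sizes chosen to give
tight Monte-Carlo error at interactive runtimes: 500 noisy replicates for
single-fit recovery, 200 replicate 76-subject cohorts for the
headline-pattern power and estimator-bias checks, 400 cohorts for
mixed-model CI coverage, and 1000 null cohorts for type-I calibration of
the Wilcoxon battery (expected in [4%, 6%] at $\alpha = 0.05$).
`scripts/acceptance.R` averages 25 replicate cohorts. Reports are pure
functions of (configuration, seed): the same inputs yield byte-identical
JSON.

## Known limitations

* The pseudoreference assumption itself (uniform cerebellar TSPO binding)
  is untestable from within the model; violations bias DVR multiplicatively
  but largely cancel from laterality indices.
* $k_2$ is unidentifiable whenever the target is proportional to the
  reference; such fits are flagged, and downstream summaries use DVR, which
  remains identified.
* The exact Wilcoxon path requires untied absolute differences;
  continuous DVRs make ties measure-zero, but heavily rounded input falls
  back to the approximation.
* Satterthwaite p-values are approximate for the 67-subject design;
  coverage is verified by simulation at the default conditions only.
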