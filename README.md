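# petasym

Hemispheric asymmetry analysis of dynamic TSPO PET with the simplified
reference tissue model (SRTM).

## The scientific problem

[11C](R)PK11195 PET images the 18 kDa translocator protein (TSPO), a marker
of microglial state. Clinical TSPO studies routinely compare a lesioned
hemisphere against the "healthy" contralateral side — which is only valid if
healthy brains bind the tracer symmetrically. Testing that assumption
requires a full quantification-and-inference chain: kinetic modelling of
regional time-activity curves (TACs) against a cerebellar grey-matter
pseudoreference, laterality metrics per bilateral region, and inference that
respects the paired, multi-centre structure of the data.

`petasym` implements that chain for R users:

* **Kinetics** — the SRTM operational model
  `C_T(t) = R1·C_R(t) + (k2 − R1·k2a)·∫ C_R(s)·e^(−k2a(t−s)) ds`,
  fitted by the basis-function method (weighted linear least squares over a
  logarithmic `k2a` grid with parabolic refinement), with an independent
  multi-start nonlinear least-squares fitter as a cross-check. Outcome
  measures are the distribution volume ratio `DVR = BP_ND + 1`, the tracer
  delivery ratio `R1 = K1/K1′`, and the late-window standardized uptake
  value `SUV = mean concentration × body weight / injected activity`.
* **Laterality metrics** — asymmetry index `AI = (R − L)/(R + L)`, signed
  relative difference `100·(R − L)/mean(L, R) = 200·AI`, and paired Cohen's
  *d* (mean of paired differences over their SD). Positive always means
  right > left.
* **Inference** — exact-path Wilcoxon signed-rank and Mann-Whitney tests
  (enumeration for small n, tie-corrected normal approximation otherwise),
  Holm-Šídák step-down multiplicity correction, Shapiro-Wilk, Pearson
  volume-vs-binding asymmetry correlations, and a REML random-intercept
  linear mixed model `DVR ~ hemisphere + age + sex + handedness + centre +
  centre:hemisphere + (1 | subject)`.
* **Synthetic cohorts** — a seeded generator producing two-centre cohorts
  (default 50 + 26 subjects on the two centres' printed frame schedules)
  with known ground-truth regional SRTM parameters and configurable
  rightward asymmetry, so every stage is testable without scanner data.
  Tabular (CSV) and image (NIfTI-1 + label volume + grey-matter probability
  map) inputs are supported through the same pipeline.

## Worked example

```r
library(petasym)

# one synthetic subject: reference input and a target region TAC
sch  <- manchester_schedule()
ref  <- simulate_reference_tac(sch, amp = 50)
truth <- srtm_params(R1 = 1.05, k2 = 0.12, BP_ND = 0.25)
target <- add_tac_noise(srtm_forward(truth, ref), alpha = 0.1, seed = 7)

fit <- fit_srtm(target, ref)
round(coef(fit), 4)
#>     R1     k2  BP_ND    k2a    DVR
#> 1.0438 0.1388 0.2605 0.1101 1.2605

# a full 76-subject cohort at the default study conditions
report <- run_full_analysis(run_config(cohort = cohort_config(seed = 7)))
s <- as.data.frame(report$dvr_pooled)
s[s$region %in% c("grey_matter", "brain_gmwm"),
  c("region", "rel_diff_pct", "cohens_d", "p_adjusted")]
#>       region rel_diff_pct cohens_d   p_adjusted
#>  grey_matter     2.113372 1.235699 7.042589e-11
#>   brain_gmwm     1.785929 1.138654 1.362965e-10
```

The fitted `DVR` of 1.2605 recovers the simulated truth of 1.25 to about
1%, at the default noise level. At the cohort level the report reproduces
the configured study conditions: a ~+1.9% rightward grey-matter DVR
difference with paired Cohen's *d* near 1.1 and an adjusted Wilcoxon
p-value far below 0.001, while the mixed model attributes the effect to
hemisphere and not to age, sex, handedness or centre.

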