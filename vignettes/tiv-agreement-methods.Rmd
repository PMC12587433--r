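---
title: "Methods: TIV agreement, harmonization and longitudinal reliability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: TIV agreement, harmonization and longitudinal reliability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the models behind `tivagree`, the assumptions
they lean on, the defaults and why they were chosen, and the numerical
decisions a maintainer would otherwise have to reverse-engineer.

## The measurement model

Every analysis in the package treats a scan's observed TIV value as

$$y_{ipm} = T_i + b_{pm} + \varepsilon_{ipm},$$

where $T_i$ is participant $i$'s latent true intracranial volume,
$b_{pm}$ is an additive bias of procedure $p$ (a site × machine ×
protocol combination) under estimation method $m$ (eTIV or sbTIV), and
$\varepsilon$ is method- and protocol-dependent noise. Two substantive
assumptions follow:

* **Additivity.** Procedure effects shift values; they do not rescale
  them. The harmonization model estimates and subtracts fixed offsets,
  so the generator deliberately omits multiplicative scanner effects —
  the generator should match the model family being tested, and a
  multiplicative world would silently violate it.
* **Adult stability.** True TIV is constant within an adult across
  scans. This is what makes traveling-subject (TS) data informative: any
  within-traveler spread across procedures is bias plus noise.

The registration-based method has one additional, qualitatively
different failure mode: with small probability a scan's eTIV collapses
to a fraction of the truth (gross underestimation). The generator
models this as $y = T_i \cdot U$, $U \sim \mathrm{Uniform}(0.6, 0.85)$,
which reproduces the far-below-identity-line pattern seen in real
multi-site scatter plots without asserting a mechanism nobody has
measured. Only eTIV ever fails; sbTIV does not.

## Agreement: two-way random-effects ICC

`icc_single()` and `icc_average()` implement the absolute-agreement
intraclass correlations from the two-way random-effects decomposition
(subjects × measurements), computed from the mean squares MSR, MSC and
MSE. Numerical decisions:

* **Negative estimates are reported as computed**, never truncated at
  zero: truncation would break the exact correspondence with the
  defining variance-ratio formulas that the test suite checks against a
  brute-force sums-of-squares oracle (to 1e-10 on 200 random matrices).
* **Band boundaries belong to the lower band.** The conventional bands
  are worded "greater than 0.9 excellent, 0.75–0.9 good, 0.5–0.75
  moderate, less than 0.5 poor"; reading "greater than" literally, an
  estimate of exactly 0.9 is "good", 0.75 "moderate", 0.5 "poor". Exact
  ties are measure-zero events, but the tie-break is documented here
  because the wording is ambiguous.
* **A constant matrix is a hard error** ("degenerate-input"), as is any
  missing cell: the designs that feed these functions produce complete
  matrices by construction, and imputation is out of scope.
* Confidence intervals are not computed; the significance test is the
  conventional $F = \mathrm{MSR}/\mathrm{MSE}$ on $(n-1)$,
  $(n-1)(k-1)$ df.

## The mixed-model engine

All "GLMMs" in this domain have Gaussian responses, so they are linear
mixed models. `fit_lmm()` fits 1–2 crossed random intercepts by REML
through `lme4`, with Satterthwaite denominator degrees of freedom from
`lmerTest` — the df convention that produces the fractional df seen in
the field's reports.

One numerical refinement is worth explaining. Derivative-free
optimizers localize an optimum only to roughly the square root of
machine precision in the variance-ratio parameter $\theta$, which
leaves the variance components ~1e-7 away from analytic values on
balanced designs. After `lme4` converges, `fit_lmm()` therefore
*polishes* each interior $\theta$ coordinate by root-finding on a
central-difference derivative (step $h = 10^{-5}$) of the profiled REML
deviance; the derivative carries slope information that pure function
comparison cannot exploit, and the polished components agree with the
closed-form balanced-ANOVA estimators to the 1e-8 asserted in the test
fixtures. Coordinates at the zero boundary are left untouched (there is
no interior root to find). Fixed effects and their covariance are
re-extracted at the polished optimum, so the reported coefficients are
exactly the GLS solution at the reported variance components.

Other engine decisions:

* Rank-deficient fixed designs error out *naming the aliased columns*
  rather than silently dropping them.
* A zero-variance response (e.g., the absolute error of noise-free
  data) returns a degenerate fit with all-zero variance components and
  coefficients instead of an optimizer failure — downstream code
  legitimately produces such responses.
* Grouping factors with as many levels as observations are permitted
  (single-scan-per-participant tables with a participant intercept);
  the participant component is then not separately identified from the
  residual, but the fixed effects — the quantities of interest — remain
  valid GLS estimates.
* Categorical terms use treatment coding with an explicitly chosen
  reference level, because the field reports effects against a named
  reference procedure or protocol.

## Traveling-subject harmonization

`estimate_procedure_offsets()` fits
`value ~ procedure + (1 | participant)` on TS scans and returns the
procedure effects re-centered to **sum to zero** across the procedures
present. The centering is a genuine design choice (nothing pins the
absolute level): sum-to-zero keeps harmonized values centered on the TS
grand mean rather than on an arbitrary reference procedure, which is
the least surprising behavior when the offsets are subtracted from a
full cohort. A `reference =` argument re-centers to a chosen procedure
for workflows that want "procedure X is the truth" semantics. Offsets
standard errors are propagated through the corresponding contrasts of
the fixed-effect covariance.

Scans flagged by the small-eTIV split are *not* excluded from offset
estimation by default — exclusion is a caller decision, not a silent
default. Procedures with fewer than two TS scans are estimated anyway
(with a warning and honestly large SEs); a single-procedure table is an
error because offsets are then meaningless.

## Resampled cross-procedure reliability

`resampled_icc2k()` repeats, a configurable 1000 times: keep travelers
with ≥ 3 scans, draw exactly 3 scans each without replacement, assign
them to the three columns **in random order**, compute ICC(2,3).
Randomizing the column assignment is justified because ICC(2,k) treats
columns as exchangeable raters; the replicate mean is empirically
stable to within ±0.002 under re-randomization (a property the test
suite checks by pinning the triples). A subtle consequence, verified in
the tests: even when every traveler has exactly 3 scans and the triples
are fully determined, replicate estimates vary *slightly* through the
column mean square, so the replicate SD is near — not exactly — zero.

## The synthetic generator and what it does (not) emulate

Defaults are anchored, once, to the published per-procedure summary
table bundled in `inst/extdata/multisite_tiv_summary.csv`:

| Parameter | Default | Anchor |
|---|---|---|
| `mu_tiv` | 1,580,000 mm³ | published overall mean sbTIV |
| `sigma_subject` | 100,000 mm³ | with sex + height effects, marginal SD ≈ 155,000 mm³, matching the published overall SD |
| `beta_sex` | 130,000 mm³ | male−female difference at the scale of published sex effects |
| `beta_height` | 11,000 mm³/cm | published body-height slope scale |
| `bias_etiv` per procedure | printed mean deviation | per-procedure deviation column |
| noise SDs per procedure | split from printed deviation SD (sbTIV side fixed at 30,000 mm³) | deviation SD column; ordering SRPB-isotropic < HARP ≈ CRHD < SRPB-anisotropic emerges from the table itself |
| sampling weights | printed per-procedure n | scan-count column |
| `failure_prob` | 0.025 | published small-subgroup fraction (165/6524) |
| `failure_shrink_range` | (0.6, 0.85) | reproduces the qualitative failure scatter |
| TS design | 134 travelers, 28 eligible procedures, 2–9 scans | published TS design counts |
| adolescent growth | female 8,000 / male 20,000 mm³/yr | sex-specific adolescent increase at published scale |

Sex is drawn 50/50 and height independently of sex; ages are uniform
within cohort ranges (main 10.5–80.1 y, TS 19–62 y, adolescent baseline
10–14 y, adult baseline 20–60 y). The generator therefore does **not**
emulate: empirical age distributions, sex-height correlation,
per-procedure sample-size quirks beyond the weights, drop-out, QC
exclusions, or any image-level mechanism. Passing tests demonstrate
that the *analysis chain* behaves correctly under the stated model
family at realistic scales — not that real data follow that family.

`scans_per_traveler` is drawn uniformly on its range; the published
design's mean (4.7 scans) is below the uniform-on-2–9 mean (5.5), so
simulated TS cohorts are slightly richer than the real one. This is
deliberate: the uniform law is the simplest fully stated sampling rule,
and reliability results are insensitive to it.

## Longitudinal and lifespan models

Adolescent models use age at scan as time; adult models use the gap
from each participant's first scan, so that a nonzero "gap" main effect
is direct evidence of method instability. Methods are stacked long
(two rows per scan) with eTIV as the reference level, so method effects
read as sbTIV − eTIV. The adolescent/adult boundary is age 18 at first
scan.

The lifespan trajectory simplifies a penalized additive model to a
**penalty-free cubic B-spline fixed basis** (default 8 interior knots at
age quantiles, per sex) inside the same mixed-model engine. This keeps
the shape flexibility relevant at cohort scale while avoiding
smoothness selection entirely; the cost is mild undersmoothing in
sparse age ranges, which is why curve tests evaluate the interior of
the age distribution. Standard-error bands come from the fixed-effect
covariance at the polished optimum.

## Problem sizes and tolerances used in the test suite

Simulation-based checks run at sizes chosen to keep Monte-Carlo error
well below the asserted tolerances: cohorts of 2,000 for moment and ICC
calibration (mean sbTIV within 2 SEM; ICC within ±0.03 of analytic
values), 30 travelers × 5 procedures for offset recovery (each offset
within 2 SE of injected truth), 100-replicate coverage runs for
fixed-effect recovery (≥ 93/100 within 2 SE), 20 seeds for the
failure-split pattern (full-sample ICC > 0.7, small subgroup < 0.3),
and 1000-replicate resampling for reliability summaries. The oracle
agreement checks (brute-force sums of squares; balanced-ANOVA closed
forms) are deterministic and asserted at 1e-10 and 1e-8 respectively.

## Known limitations

* Harmonization corrects additive procedure biases only; multiplicative
  or variance (scale) site effects are out of scope, as are
  empirical-Bayes (ComBat-style) approaches.
* The ICC families implemented are ICC(2,1)/ICC(2,k) only, without
  bootstrap or closed-form confidence intervals.
* The failure mode is a phenomenological stand-in; it reproduces the
  observable pattern, not the registration mechanics behind it.
* Satterthwaite df are the only df method offered; likelihood-ratio
  tests and Kenward–Roger are not implemented.
* The spline trajectory has no smoothness penalty; with very uneven age
  coverage, prefer fewer knots.
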