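---
title: "Methods: skinfold-equation validity analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: skinfold-equation validity analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(anthroval)
```

## The problem

Skinfold calipers are the workhorse of body-composition monitoring in
applied sport: cheap, portable, and quick. But a skinfold is converted
into fat mass (FM) and lean mass (LM) through a prediction equation
fitted in some historical reference population, and nothing guarantees
that equation transfers to a squad of late-adolescent athletes whose
body composition is still changing with somatic maturation. `anthroval`
implements the full method-comparison analysis a practitioner needs to
audit that transfer: apply candidate equations, quantify their agreement
with a criterion method (typically DXA), and test whether maturity
status leaks into the predictions.

## Prediction model

Three of the five supported equations (Durnin & Womersley, Withers,
Wilmore & Behnke) predict whole-body density $D$ in g·cm⁻³ as a linear
(or log-linear) function of skinfold thicknesses and convert it with the
Siri-type two-compartment transform

$$\mathrm{FM\%} = \frac{495}{D} - 450,$$

using the constants exactly in the 495/450 form. The other two
(Slaughter, Oliver) predict FM% directly. Slaughter is a two-branch
equation in $s =$ triceps + subscapular: a quadratic for $s \le 35$ mm
and a line for $s > 35$ mm. The two branches do not meet at the
boundary (27.05 vs 29.0 FM% at 35 mm); that discontinuity is a property
of the published equation, and the package records which branch fired
rather than smoothing it. The quadratic's vertex sits at
$1.21/(2 \cdot 0.008) = 75.6$ mm, far beyond its 35 mm domain, so every
equation is monotone non-decreasing in each of its input sites — a
property the test suite verifies over the full caliper range.

Lean mass is derived as $\mathrm{LM} = \mathrm{BM}(1 - \mathrm{FM\%}/100)$.
Published versions of this derivation sometimes typeset the fat term
with kg units inside a percentage division; the percentage reading used
here is the only one that is dimensionally consistent and that
reconciles published per-equation FM% and LM cohort means (e.g.
$79.3 \times (1 - 0.103) = 71.1$ kg). Two-compartment conservation,
$\mathrm{FM_{kg}} + \mathrm{LM_{kg}} = \mathrm{BM}$, then holds by
construction and is asserted to $10^{-9}$ relative error.

Skinfold inputs are validated to (0, 100] mm: calipers cannot produce
values outside that range, and the density equations go non-physical
beyond it. Note that the density equations can still return FM% near or
below zero for site sums leaner than their calibration range (a
documented limitation of the equations themselves); the lean-mass
derivation rejects FM% outside $[0, 100)$ as a domain error rather than
propagating a negative fat mass.

## Maturity offset

Somatic maturity is estimated with the Mirwald male regression on age,
standing height, sitting height and body mass (heights in cm, the
weight/height ratio in kg·cm⁻¹ scaled by 100). The offset is years from
peak height velocity; subjects are grouped into 1–2, 2–3, 3–4 and 4+
years post-PHV. Two conventions are deliberate implementation choices,
since grouping rules are rarely printed:

* bins are half-open $[\ell, u)$, so the partition of $[1, \infty)$ is
  exhaustive and non-overlapping and an offset of exactly 2 belongs to
  the 2–3 group;
* offsets below 1 year post-PHV are flagged `OUT_OF_RANGE` instead of
  being clamped into the lowest bin — the grouping was defined for
  cohorts past PHV and silently binning a pre-PHV subject would hide a
  cohort problem.

## Agreement statistics

All comparisons treat the equation as candidate $x$ and the reference
as $y$; differences are $d = x - y$, so positive bias means
overestimation.

* **Bland–Altman**: bias $= \bar d$, limits of agreement
  $\bar d \pm 1.96\, s_d$ with the $n-1$ sample SD. Per-subject
  coordinates (pair mean, difference) are exported for plotting.
* **Typical-error CV%**: per subject, the within-pair SD
  $|d|/\sqrt 2$ divided by the pair mean, times 100; summarised as
  mean ± SD across subjects. A single pooled typical error cannot carry
  a dispersion, and validity tables in this field report CV% with one
  (e.g. "8.8 ± 6.4"), which forces the per-subject formulation.
* **TEM**: $\sqrt{\sum d_i^2 / 2n}$ over replicate pairs, also as a
  percentage of the grand mean, against the conventional 5% threshold.
* **ICC(A,1)**: single-measure, absolute-agreement, two-way model from
  ANOVA mean squares,
  $(MS_R - MS_E) / (MS_R + (k-1) MS_E + \tfrac{k}{n}(MS_C - MS_E))$ —
  the standard reading of "two-way mixed, absolute agreement". A table
  with zero total variance returns 1 by convention (with a message),
  since two constant, identical raters agree perfectly. The test suite
  checks the implementation against a brute-force sum-of-squares oracle
  to $10^{-10}$ on hundreds of random tables.
* **Percent difference**: $100\,|d|/y$, mean ± SD. The absolute value
  is deliberate: published tables report positive %Diff even for
  equations that underestimate, so a signed definition could not
  reproduce them.
* **Cohen's d**: $|\bar x - \bar y|$ over the SD pooled across the two
  method columns (the scale on which the trivial/small/medium/large
  bands at 0.2/0.5/0.8 were defined), boundaries resolved upward. The
  SD-of-differences variant would conflate effect size with agreement.
* **Location test**: Shapiro–Wilk on $d$ gates a paired t-test
  ($p \ge \alpha$) versus a Wilcoxon signed-rank test ($p < \alpha$).
  The Wilcoxon is reported as a normal-approximation $Z$ with midranks,
  tie correction and zero-difference removal, and no continuity
  correction — the convention of mainstream statistical packages, and
  therefore of the published tables this style of analysis feeds. All
  differences zero is degenerate and returns $p = 1$. Shapiro–Wilk is
  computed on at most the first 5000 differences (its defined range);
  only the large simulation cohorts ever exceed that.
* **Verdict**: acceptable agreement iff CV% ≤ 10 **and** ICC ≥ 0.8,
  both boundaries inclusive as written. Significance of the location
  test is reported alongside but deliberately does not enter the
  verdict: a systematic offset can be statistically significant while
  the thresholds still classify agreement as acceptable, and the rule
  as applied in practice is the two-threshold one. Thresholds are
  config-overridable (`study_config()`); the defaults are the published
  rule.
* **Maturity regression**: ordinary least squares of each equation's
  predicted LM on the *continuous* maturity offset. With $n$ subjects
  this yields $F$ on $(1, n-2)$ degrees of freedom — consistent with
  published $F_{(1,23)}$ at $n = 25$, which a 4-level group factor
  could not produce. $R^2_{adj} = 1 - (1 - R^2)(n-1)/(n-2)$.
* **Post hoc power**: exact noncentral-t power of the two-tailed paired
  t-test, noncentrality $d\sqrt n$ on $n-1$ df; cross-checked in the
  tests against a 100,000-replicate Monte-Carlo simulation to ±0.005.

## The synthetic-cohort generator

No athlete data ships with the package; the generator produces cohorts
with the statistical structure the analysis assumes, with ground truth
known exactly.

* **Anthropometry** is drawn from truncated normals calibrated to a
  late-adolescent male academy squad: age 18.6 ± 0.8 y, height
  182.7 ± 5.9 cm, body mass 79.3 ± 7.6 kg, sitting height 52 ± 1% of
  stature. The truncation windows (e.g. height 150–210 cm) are loose
  physiologic guards.
* **Skinfolds** are multiplicative: site value = per-site median ×
  shared lognormal adiposity factor (SD 0.25 on the log scale) ×
  per-site lognormal noise (CV 10%). The shared factor induces the
  strong inter-site correlation real skinfolds show; the multiplicative
  form guarantees positivity and right skew without clipping
  artefacts. Lognormal tails are truncated at 3 SD so that even
  10,000-subject cohorts stay inside the equations' physiologic range.
  The per-site medians (4–10 mm) put the cohort at the low-teens FM%
  typical of elite late-adolescent players; the resulting
  triceps+subscapular sums (~10–30 mm) sit below Slaughter's 35 mm
  switch, so its quadratic branch is the live one at these adiposity
  levels, while the ten-site total (~45–135 mm) is always well above
  35 mm.
* **Measurement error**: both caliper pulls of every site are
  perturbed with multiplicative error of CV `replicate_cv` (default
  3.5%); the first pull is the recorded value, the second fills the
  `*_rep2` replicate columns. The pooled %TEM this induces is the
  per-measurement CV inflated by the dispersion of site magnitudes,
  $\sqrt{E[v^2]}/E[v]$ (~1.07 at the defaults, giving ~3.74% pooled
  TEM); `calibrate_replicate_cv()` computes the exact factor for any
  parameter set, which is how the calibration-recovery test pins the
  generator to a target %TEM.
* **Reference body composition**: reference FM = generating-equation
  FM + `dxa_fm_bias` + Gaussian noise with SD
  `dxa_fm_noise_sd + dxa_heteroscedasticity × FM`; reference LM = body
  mass − reference FM − a simulated positive bone-mineral compartment
  (3.0 ± 0.25 kg). Defaults (bias −1.6 kg below Durnin & Womersley,
  baseline noise 1.0 kg, mild heteroscedasticity 0.02) reproduce the
  magnitude of bias and limits of agreement such cohorts show against
  DXA, including the fanning-out of differences at higher fat mass.
  Because the reference is built *from* a designated equation, the true
  bias and noise SD between that equation and the reference are known
  exactly — the basis of the parameter-recovery tests. In the rare
  event an extreme noise draw would push a subject's reference FM or LM
  non-positive, that subject's noise is redrawn (a truncation that
  never binds at default settings).
* **Determinism**: one documented `seed` parameter; generation happens
  inside `withr::with_seed()`, so the session RNG stream is untouched
  and identical parameters give byte-identical cohorts.

What the generator does **not** emulate: true DXA physics and its
marginally different total mass, bone-mineral growth curves,
site-specific fat-patterning shifts during maturation, or longitudinal
change. Passing tests therefore demonstrate that the statistics recover
known structure of this generative model, not that any equation is valid
in a particular real population.

## Numerical and testing choices

Internal computation is double precision throughout; rounding to one
decimal (kg, %) and three decimals (ICC, p) happens only in the
reporting layer. Problem sizes in the test and acceptance runs were
chosen so every check is decisive yet the whole suite runs in seconds:
hand-verifiable fixtures for closed-form values, 200 random tables for
the ICC oracle equivalence, cohorts of 10,000 subjects for bias/noise/
TEM recovery (standard-error bounds ~3σ/√n), 100 replicate cohorts per
noise level for the monotone ICC/CV degradation check, and 100,000
Monte-Carlo replicates for the power cross-check.

## Known limitations

The equations are applied as printed, with no re-fitting and no
populations other than the male late-adolescent athletes they are used
on here; no sex-specific maturity variants (Khamis–Roche, Moore) are
included; agreement modelling is the classical Bland–Altman frame, with
no regression-based limits or mixed-effects extensions; and the
acceptability verdict is a binary rule on two thresholds — useful for
screening decisions, but no substitute for inspecting the exported
Bland–Altman coordinates.
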