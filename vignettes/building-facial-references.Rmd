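---
title: "Building normative facial-measurement references"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building normative facial-measurement references}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(facenorms)
```

`facenorms` turns tables of 3D facial landmark coordinates into
population-specific normative references — a fitted mean growth curve, an
age-varying SD and a confidence band per measurement and sex — and scores
individual faces against them. This vignette explains the statistical
model, the choices behind every tunable parameter, what the synthetic
cohort generator does and does not emulate, and the limitations a user
should keep in mind.

## From landmarks to measurements

Coordinates are in mm in a right-handed frame: +x the subject's anatomical
right, +y superior, +z anterior. The default template carries 19 medial and
25 bilateral landmark codes. Four measurement kinds are supported:

* **distance** — Euclidean distance between two landmarks; a *bilateral*
  definition (e.g. palpebral fissure length, ex–en) is computed per side and
  averaged, because a normative reference describes the trait, not the side.
* **angle** — interior angle at the middle of three landmarks, in degrees.
* **depth** — signed distance from a landmark to a reference plane
  (default the midsagittal plane; the sign follows the +x normal).
* **asymmetry** — distance between the left landmark of a bilateral pair
  and the mirror image of its right counterpart across the midsagittal
  plane. The plane itself is the total-least-squares plane through the
  usable medial landmarks (smallest-variance direction of the centred
  medial cloud), so asymmetry is defined even on faces whose midline is not
  at x = 0.

Landmarks can be marked unusable (occlusion, surface artefacts); an
excluded landmark invalidates only the measurements that reference it, so
the rest of the image remains informative. Placement QC compares candidate
and ground-truth placements and fails when any discrepancy strictly exceeds
5 mm — "more than 5 mm" is read as exclusive, so a discrepancy of exactly
5 mm passes. The registry ships the eight standard interlandmark
measurements named in the craniofacial literature (Farkas-style
definitions); it is an ordinary list and extends to any number of
user-defined measurements.

## The growth-curve model

For each (measurement, sex) stratum the mean value over age $x$ is modelled
by one of five candidate families: a three-parameter exponential decay
$y = a(c - e^{1-bx})$ and polynomials of degree 1–4. The exponential form
rises steeply through early childhood and plateaus at $a\,c$ — the shape
comparative model-fitting studies repeatedly find for craniofacial
dimensions.

**Fitting.** Polynomials are solved by QR least squares. The exponential
family is nonconvex in $(a, b, c)$, but for fixed rate $b$ it is linear in
$(ac, a)$, so the fitter profiles the residual sum of squares over $b$ on a
log-spaced grid from 0.02 to 2.5 /year (30 points — the multi-start) and
refines the best bracket with 1-D `optimize()` to tolerance 1e-10. This is
derivative-free, has no starting-value sensitivity, and recovers noiseless
generating coefficients to better than 1e-4. The minimum admissible number
of points is the coefficient count (exact interpolation).

**Selection.** Two criteria are offered. `"rss"` picks the literal minimum
residual sum of squares with ties (within a relative 1e-8 tolerance) broken
towards the family with fewest coefficients. Because the polynomial
families are nested, raw RSS can never prefer a lower-degree family except
by tie-break, and in practice the quartic wins any noisy comparison —
unpenalized RSS selection is therefore degenerate among the candidates.
`"aicc"` applies the small-sample corrected AIC, which charges the quartic
its two extra coefficients; on cohorts generated from an exponential-decay
truth it selects the exponential form in the large majority of strata.
The package default remains `"rss"` for fidelity to the describable
procedure; the reference-building experiments in this package use
`"aicc"`, which reproduces the reported dominance of the exponential form.

**Outlier loop.** After each fit, observations with
$|y - \mu(x)| > 3\,\mathrm{SD}(x)$ (strictly) are flagged. The emulated
workflow sent such images back for landmark reappraisal; a software
pipeline cannot re-place landmarks, so flagged observations are removed and
the stratum refitted, iterating until no new outliers or `max_iter = 5`
passes. The loop is a fixed point: re-running detection on the retained set
flags nothing. This exclusion-instead-of-reappraisal is a documented
divergence from the emulated study.

**Age-varying SD.** Residual dispersion changes with age (and with the
sampling density), so the SD is estimated on a 0.5-year grid as the square
root of a Gaussian-kernel-weighted mean squared residual, bandwidth 2
years. The bandwidth trades bias against variance at the cohort sizes the
package targets (a few hundred per stratum): 2 years keeps the effective
local sample in the tens across a pediatric age range while still tracking
the printed age-5/10/15 SD anchors to within a tenth of a millimetre. Grid
points whose summed kernel weight falls below 3 equivalent observations are
flagged low-confidence rather than dropped.

**Confidence band.** The 95% band for the mean curve is a subject-level
nonparametric bootstrap (default B = 500, percentile method): resample
(age, value) pairs, refit the selected family, evaluate on the grid; the
half-width is half the 2.5th–97.5th percentile distance. Whether the
emulated study's intervals were analytic or resampled is not documented;
the bootstrap makes no curvature assumptions and its pointwise coverage on
preset-like cohorts (n = 760, σ ≈ 7 mm) is measured at 95.0% ± 0.9 by the
test suite's 600-replicate simulation. Refit failures in more than 10% of
replicates abort with an error rather than returning a band built from a
biased subset.

**Sample size.** The per-band recruitment target uses the one-sample
normal approximation
$n_\mathrm{usable} = \lceil ((z_{1-\alpha} + z_{\mathrm{power}})/\Delta)^2 \rceil$
with a half-SD detectable effect, 5% significance, 80% power, inflated by
the assumed 15% image fall-out rate. Sidedness is implemented as an option
because only the one-sided form yields the canonical 30 recruits per band
(25 usable / 0.85 → 30); the two-sided variant gives 38.

## Scoring individuals

A subject's record is scored as $Z = (y - \mu(\mathrm{age}))/\mathrm{SD}
(\mathrm{age})$ against the sex-matched curve, with the SD linearly
interpolated on its grid (constant beyond the grid ends) and an
extrapolation flag when the age lies outside the sampled range. Displayed
Z-scores round halves away from zero to one decimal, matching clinical
screen conventions. A trait flag is emitted iff $|Z| > 2$ strictly — the
±2 SD band bounds ~95.45% of a normal population, so the per-measurement
flag rate for in-distribution subjects is ~4.6%. One flag per measurement
at most; richer trait-inference rules used by clinical software are
unpublished and out of scope. Labels come from an editable illustrative
map (e.g. low palpebral fissure length → "Short palpebral fissure"); it is
not the Human Phenotype Ontology. Reference-switch comparisons assess each
subject under two reference sets and report per-subject flag counts with
medians and ranges; no significance test is attached because none is
defined for this design.

## The synthetic cohort generator

Patient-level 3D facial data are rarely shareable, so the package ships a
generator whose presets encode the statistical structure the pipeline
assumes:

* **Curves.** Each measurement and sex gets an exponential-decay generating
  curve built by an exact closed-form solve through three anchor values at
  ages 5/10/15 (`expdecay_through()`: with equally spaced anchors the rate
  is $b = -\log(D_2/D_1)/h$). Female anchors are standard interlandmark
  magnitudes; the Chinese-preset male bizygomatic anchors are female +
  3.5/5.2/7.2 mm and male PFL is female + 1 mm — with equal increments this
  makes the PFL sex gap exactly 1 mm at *all* ages, and the bizygomatic gap
  exactly the printed values at the anchor ages.
* **Dispersion.** Bizygomatic SD is age-varying through the printed
  anchors (F 6.8/6.6/6.7, M 7.4/7.2/7.6 mm at 5/10/15, linear between,
  flat beyond); other measurements use constant SDs of plausible magnitude
  (e.g. PFL 1.4 mm). Noise is Gaussian, consistent with SD-based
  thresholds bounding ~95% at ±2 SD.
* **Ages and sexes.** A mixture of uniform(0, 18) with weight 0.86 — the
  pediatric share of the emulated cohort (758/879) — and uniform(18, 55)
  otherwise; sexes are balanced Bernoulli(0.5). The adult tail matters:
  fitting over the whole age range, including ages where growth has
  plateaued, is what constrains the curve and keeps evaluation ages like 15
  away from a data boundary.
* **Contamination.** Gross outliers are injected at rate 0.005 by adding
  ±5 local SDs (defaults chosen as a plausible residual error rate after
  trained landmarking), and a 2% fall-out probability marks records
  unusable. Both are configurable, and both are exercised by the outlier
  loop and usability propagation.
* **European preset.** Built from the Chinese curves plus constant offsets
  in the directions the cross-population comparisons describe: bizygomatic
  −8 mm (the Chinese cohort is larger at all ages), PFL +2.5 mm, nasal
  protrusion +3.5 mm, nasal bridge +4.5 mm, innercanthal +3.5 mm, facial
  height and labial fissure width 0 (the groups coincide), and philtral
  length re-anchored to a similar magnitude with a different growth rate.
  Magnitudes are configurable; the defaults are of the size classical
  cross-population anthropometry reports. Because offsets are constant
  across the equally spaced anchors, each European curve is the Chinese
  curve shifted by exactly the offset at every age.
* **Landmarks.** `simulate_landmarks()` realizes a drawn measurement vector
  as an actual symmetric landmark set: the nine anchor landmarks are placed
  so the eight registry measurements are exact by construction, remaining
  landmarks scale with facial height and width, and optional Gaussian
  placement noise produces QC failures and nonzero asymmetries on demand.

Generation is byte-deterministic under the spec's seed.

What the generator does **not** emulate: real age histograms (uniform
within bands, not the clinic's visit pattern), correlation between
measurements within a face (draws are independent given age and sex),
non-Gaussian tails, longitudinal structure (the design is cross-sectional),
or mesh-level artefacts. Passing tests therefore demonstrate that the
pipeline recovers the structure it assumes — calibration, not clinical
validation on real faces.

## The calibration experiment

`sex_dimorphism_experiment()` closes the loop: it simulates 30 independent
Chinese-preset cohorts of n = 760, runs the full reference pipeline per
sex, and recovers the male-minus-female fitted bizygomatic width at ages
5/10/15, the kernel-estimated female bizygomatic SD at age 10, and the mean
PFL sex gap over ages 2–18 — the quantities the preset is anchored to.
Thirty cohorts keep the Monte Carlo error of the seed average (~0.17 mm)
well below the 0.5 mm scale at which the recovered gaps are read.
`scripts/acceptance.R` is a thin wrapper that runs this experiment and
writes the statistics as JSON.

## Numerical conventions and edge cases

* Strict inequalities throughout: QC fails beyond 5 mm, outliers beyond
  3 SD, flags beyond 2 SD; boundary values pass/are retained/are silent.
* Ages are decimal years; the measurement TSV writes them with 3 decimals.
* Reference JSON round-trips at full double precision (`digits = NA`) and
  carries a schema version checked on read; a missing SD grid is an
  incompatibility error, because a reference without dispersion cannot
  score anyone.
* Extrapolation beyond the sampled age range returns values plus a flag,
  never an error: clinical users will present out-of-range ages.
* Degenerate geometry (fewer than three usable medial landmarks, collinear
  midline) raises an error rather than returning an arbitrary plane.
* Collinear/duplicate fit degeneracies surface as fit errors naming the
  family; `select_model` tolerates individual family failures and errors
  only if all five fail.

## Known limitations

* The eight shipped measurement definitions are standard reconstructions;
  commercial software computes dozens more whose exact formulas are
  unpublished. The registry is user-extensible for that reason.
* Outliers are excluded, not re-measured; on real data this loses the
  information a landmark reappraisal would recover.
* LMS/GAMLSS-style quantile references and mixed-effects longitudinal
  models are deliberately out of scope; the pipeline is cross-sectional
  with a symmetric Gaussian dispersion model.
* The trait-label map is illustrative, not an ontology, and flag counts
  from an 8-measurement registry are not comparable in magnitude to
  clinical reports built on much larger measurement panels — only the
  direction of reference-switch effects is meaningful at this registry
  size.
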