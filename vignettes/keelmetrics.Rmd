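---
title: "Methods: radiographic keel bone densitometry and cohort statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: radiographic keel bone densitometry and cohort statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(keelmetrics)
```

## The measurement problem

Keel bone (carina sterni) health in laying hens is assessed on
latero-lateral radiographs. Two obstacles make raw gray values useless as a
density measure: exposure varies image to image, and detector response is
nonlinear. The standard remedy is an aluminium step wedge imaged on the
detector plate next to the bird. Known aluminium thicknesses and their
observed gray values define a per-image calibration, and any region of the
bird can then be expressed in millimetres aluminium equivalent (mmAleq) —
the aluminium thickness that would have produced the same gray value. In
vivo, the measured value includes whatever soft tissue overlies the bone;
that is a property of the method, not an artifact of this implementation,
and is why relative body weight and pectoral muscle thickness enter such
analyses as covariates.

## Calibration model

The calibration is the four-parameter Rodbard sigmoid, fitted with
thickness as the response (known standards regressed on measured grays):

$$t(g) = d + \frac{a - d}{1 + (g/c)^b}$$

with $a$ the thickness asymptote as $g \to 0$, $d$ the asymptote as
$g \to \infty$, $c$ the gray value at the midpoint thickness $(a+d)/2$, and
$b > 0$ the shape. Fitting choices (none of which are forced by the
measurement procedure itself, so they are stated here explicitly):

* **Algorithm**: Levenberg–Marquardt (`minpack.lm::nlsLM`), initialization
  $a_0$/$d_0$ at the thicknesses observed at the smallest/largest gray
  extrapolated outward by 10% of the thickness range, $c_0$ the median
  gray, $b_0 = 1$; tolerance $10^{-10}$ on the sum of squares, at most
  10\,000 evaluations, bounds $b, c > 0$.
* **Acceptance**: a fit is rejected unless $t(g)$ is strictly monotone over
  the observed gray domain; the RMSE (mm) and gray domain are stored with
  the curve.
* **Identifiability**: with wedge data confined to one flank of the
  sigmoid, $(a, b, c, d)$ need not be individually identified; the contract
  tested is observational equivalence — pointwise agreement of $t(g)$ with
  the generator within $10^{-6}$ mm over the gray domain, which is what
  conversion accuracy depends on.
* **Region conversion**: pixels are converted individually and then
  averaged. Converting the ROI's mean gray differs under a nonlinear curve;
  both are exposed (`mean_mmAleq(method =)`) and they agree exactly on
  uniform regions. Per-pixel conversion is the default because the
  calibrated quantity of interest is the thickness of material along each
  ray.
* **Extrapolation** beyond the wedge range warns rather than errors: a keel
  plus overlying muscle can legitimately exceed the thickest step.
* No flat-field or scatter correction is applied; the procedure being
  modelled performs none.

## Morphometry conventions

* Lengths are straight-line landmark distances (cranial tip → caudal tip;
  cranial tip → caudalmost ossified point), in cm. Whether a curved-profile
  length would be preferable is genuinely open; the chord matches the
  straight line the density-square procedure itself draws, and a polyline
  variant is a natural extension point.
* Ossification degree = ossified/total length; *complete* ossification is
  strictly $> 0.95$ (caudal fat pads can mimic incomplete ossification, so
  exactly 95% does not qualify).
* The density square sits at the midpoint of the cranial–caudal line (or
  the line to the caudalmost ossified point when incomplete), side =
  ossified length / 12, axis-aligned; a recorded manual offset shifts it
  when automatic placement falls off a deviated or highly curved keel.
  Axis-aligned was chosen over keel-axis-rotated because the placement
  procedure specifies only "a square in the middle of that line".
* POD = 100 · area(union of deviated regions ∩ keel outline) / area(keel
  outline). Deviated polygons are clipped to the keel so POD ≤ 100, and
  overlaps are not double-counted.
* **Rasterized statistics** use the center-in rule: a pixel belongs to a
  polygon iff its center lies inside (even-odd winding; scanline fill).
  `polygon_area` itself is exact (shoelace). POD is a pure geometry ratio,
  so its raster is refined 4× linearly, keeping discretization error below
  0.1 percentage points for keels spanning a few hundred pixels; at native
  resolution the boundary error is ~0.3 pp.
* Ossified length exceeding total length by more than one pixel raises a
  warning and is never silently clamped.

## Fracture scoring

Scores are observer-entered, not computed from pixels — fracture detection
is a human task here, and the module encodes the data model: three equal
sections along the cranial–caudal axis; per section, fresh fractures and
calluses counted and capped at 2 ("two or more"); binary collapse
`any_damage = 1` iff any of the six scores is positive. A lesion projecting
exactly onto a section boundary goes to the more caudal section
(documented, arbitrary). Non-evaluable images (leg/caudal-tip
superimposition) carry an exclusion reason instead of an outcome, and batch
summaries conserve evaluable + excluded = total.

## Egg and laying metrics

* Relative shell weight = 100 · shell/egg weight.
* The outlier filter removes values strictly outside
  $[Q_1 - 1.5\,\mathrm{IQR},\ Q_3 + 1.5\,\mathrm{IQR}]$; quartiles use
  linear interpolation between order statistics (`quantile type = 7`). The
  convention is stated prominently because the kept set depends on it; a
  value exactly on a fence is kept. Filtering is applied per
  genotype × sampling-period cell by default (the analysis unit of the
  eggshell models), with a global option.
* The 10% laying milestone is the first single day with
  eggs/hens ≥ 0.10 — no rolling mean, since no smoothing rule is part of
  the definition.
* Annualized performance = total eggs × (365/observed days) / hens.

## Cohort statistics

* **Prevalence**: Clopper–Pearson, the standard reading of "exact binomial"
  intervals, via Beta quantiles: lower $= \mathrm{qbeta}(\alpha/2;\,x,\,n-x+1)$,
  upper $= \mathrm{qbeta}(1-\alpha/2;\,x+1,\,n-x)$, with 0/100% at the
  boundaries. Reported percentages round half away from zero to one
  decimal (`fmt_pct`).
* **Ossification survival**: event times are the discrete exam weeks; an
  animal's event is the *first* exam week with degree > 0.95
  (interval observation collapsed to the right endpoint). Interval-censored
  likelihood machinery is deliberately not used — with five exam weeks and
  small groups it would add model burden without changing the ordering the
  log-rank test sees. Dropouts and blocked measurements censor the animal
  at its last informative exam. Kaplan–Meier and log-rank computations go
  through the `survival` package (hypergeometric expected events, standard
  variance, no continuity correction); pairwise tests are Holm-adjusted.
  The dual-age exam schedule (weeks 50/52 and 70/72) normalizes to nominal
  labels {16, 25, 33, 51, 71} for pooling.
* **Correlation**: Pearson r with the Fisher-z interval
  (variance $1/(n-3)$).
* **Duplicate QC**: two-point *sample* SD, $|v_1 - v_2|/\sqrt{2}$ (the
  usual ELISA duplicate convention); repeat only when CV > 15% **and**
  SD > 10 — the conjunction matters and is boundary-tested.
* **Follicle status**: F+ iff a dominant (>10 mm) follicle is seen or an
  egg is visible on sonography/radiograph; the pre-onset baseline week is
  forced F−.
* **Relative body weight**: weight / mean weight of the same genotype at
  the same age; each cell's ratios average exactly 1 by construction.

## What the phantom emulates — and what it does not

`generate_phantom` renders: the 18-step wedge (0.5–4.75 mm, arithmetic
series) as rectangles of exact thickness; an elliptical "bird" of uniform
tissue thickness; a symmetric sine-lens keel silhouette whose pixels add
the keel thickness; an optional deviated band whose polygon area fraction
equals the requested POD (deviation is a *shape* annotation and does not
change thickness); optional radiolucent fracture gaps that remove the bone
thickness in the named third; and additive Gaussian gray noise, clipped to
the bit-depth range. The forward model is the exact inverse of the Rodbard
curve, so the noiseless pipeline must round-trip to numerical precision —
that is the point of the construction. In-memory images stay continuous;
quantization to 16-bit integers happens only at TIFF export and costs
about $10^{-4}$ mm of thickness accuracy.

Default transfer parameters $(a, b, c, d) = (-0.5, 2, 30000, 8)$ put the
wedge and plausible keel+tissue thicknesses (0–8 mmAleq) on a well-curved
part of a 16-bit-range sigmoid with $a < 0$ so the bare detector (zero
thickness) renders; brighter = thicker is the default polarity, and the
opposite is representable. The noise model is additive Gaussian (read-noise
proxy) — Poisson photon statistics, beam hardening, scatter, plumage and
viscera are *not* modelled. Consequently, passing phantom tests
demonstrates correctness of the measurement arithmetic and calibration
fitting, not robustness to the physics of real radiographs; on real data
the calibration inherits whatever scatter and beam-hardening bias the
wedge shares with the bird.

The cohort generator encodes the study conditions as defaults: three
genotypes (a high-performing layer and two low-performing lines) with 12,
14 and 12 hens; first eggs in weeks 18/24/31 and 10% laying performance in
weeks 21/26/32 (the generated daily series hit these milestones exactly by
construction: one egg per day between onset and the 10% day, then a ramp
and a Poisson plateau calibrated to 315/83/92 eggs/hen/year); egg-quality
cell means taken from the least-squares means of such a study with per-egg
SDs chosen at realistic dispersions (egg weight ±2–4 g, shell ±0.4–0.9 g);
ossification completion first observed at week 25 (75%) or 33 in the two
earlier genotypes and at week 33 (75%) or 51 in the late one; three
dropouts in one low-performing group and one in the other; five of twelve
layer hens with the binary fracture outcome and none elsewhere. It
reproduces *structure* (milestones, group means, censoring patterns,
completion-week distributions), not biology — individual laying curves,
seasonal effects and between-hen correlation of egg traits are not
modelled.

## Problem sizes and determinism

Everything is seeded and deterministic: identical seeds give bit-identical
phantom images and cohort tables. The test suite and the acceptance script
run at desk scale: 480×560-pixel phantoms at 0.5 mm/pixel (the wedge then
occupies 40×356 pixels, ~800 pixels per step; the keel ~9000 pixels), a
batches of 8–12 phantoms for the whole-keel vs square correlation, 500-replicate
coverage and permutation checks for the Fisher interval and the log-rank
p-value, and 200 replicate cohorts at n = 12/group for the power of
detecting a later-ossifying genotype with Holm-adjusted pairwise log-rank
tests.

## Known limitations

* No automatic segmentation, landmark detection or fracture detection —
  annotations and scores are inputs, as in the observer-driven procedure.
* POD from 2-D projections underestimates small deviations by geometry;
  nothing here corrects for projection.
* The linear (mixed) models, robust-variance ANOVAs, Tukey–Kramer post
  hocs and bias-reduced logistic regressions that typically accompany
  these measurements are off-the-shelf statistics; the package exports
  tidy tables consumable by any modelling environment instead of wrapping
  them.
* The exact-interval upper bound for 5/12 at 95% is 72.33%; published
  one-decimal roundings of this interval vary in the last digit.
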