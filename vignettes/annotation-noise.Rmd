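---
title: "Simulating citizen-science annotation noise: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating citizen-science annotation noise}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(csannosim)
```

## Overview

`csannosim` studies a pipeline in which untrained citizen scientists (CS)
detect objects in seafloor images with square markers, and a patch
classifier trained on expert gold-standard annotations assigns the class
labels. Because real CS detections are noisy — wrong positions, wrong
marker sizes, spurious detections, missed objects — the package simulates
each error mode as a parametrized transformation of a gold standard and
measures the consequence for classification accuracy.

An annotation is the tuple `(x, y, r, image, label)`: continuous pixel
coordinates of the center of a square, origin at the image's top-left
corner, x rightwards, y downwards; `r` is the *radius*, meaning half of the
square's side length. All geometry in this package is square-based (the
marker is drawn as a circle in annotation front-ends, but stored and
processed as the enclosing square). Crop windows are closed intervals
rounded outward to whole pixels at extraction time.

## The error models and their parameters

### Inaccurate position (IP)

$$x' = x + Z_x r, \qquad y' = y + Z_y r, \qquad
Z_x, Z_y \sim U(-2(1-o),\, 2(1-o))$$

`o` (dimensionless fraction in (0, 1], default grid: 0.875, 0.75, 0.5) is
the guaranteed minimum *per-axis* overlap retained with the source square:
the shifted interval `[x'−r, x'+r]` always shares at least a fraction `o`
of its length with `[x−r, x+r]`. Under this sampling law the guaranteed
*area* overlap of the two squares is only `o²`; the published description
of `o` ("minimum overlap in percent") does not distinguish the two notions,
so the package implements the printed sampling law verbatim and exposes
both overlap statistics — `pairDeviations()` and `deviationStats()` report
the area overlap per match, while the per-axis bound is what the law
guarantees. Four simulated annotations are drawn per expert annotation
(`nPerAnnotation = 4`), the multiplicity stated for the IP experiment. Only
the validation split is ever perturbed, preventing leakage of training
positions into evaluation.

At `o = 1` the shift interval degenerates to `{0}` and the output is
bit-identical to the input — this identity is asserted in the tests down to
the extracted patches.

### Inaccurate radius (IR)

$$r' = (1 + Z_r) r, \qquad Z_r \sim U(0, s)$$

`s` (signed fraction, default grid: +0.1, −0.1, +0.25, −0.25) bounds the
relative radius change. The source notation `U(0, s)` is used for both
signs; we read it as the uniform distribution on the interval *between* 0
and `s`, so negative `s` underestimates the radius. `s ≤ −1` is rejected
(the radius could reach zero). Multiplicity is 1 per source annotation:
a multiplicity was stated only for IP, so IR keeps one perturbed copy per
validation annotation.

### Background false positives (FP)

Per image, `perImage = 2` background annotations of patch size
`patchSide = 64` px are placed uniformly at random (rejection sampling,
cap `maxAttempts = 10^4`) subject to

$$d\big((x_b, y_b), (x, y)\big) > r + 64$$

for every expert annotation `(x, y, r)` on that image, with `d` the
Euclidean metric, and to the patch lying fully inside the image. One
wrinkle: the source stores 64 in the *radius* slot of the background tuple
while calling the patch "64 × 64". We store `r = patchSide/2 = 32` so the
patch is literally 64 × 64 pixels, and keep the additive slack of the
distance constraint at the printed 64. Both are configuration fields
(`fpConfig()`), so the other reading is one argument away. An image too
crowded to admit a placement is a hard error naming the image, not a silent
shortfall.

### Gaussian (CSP-like) deviations

Radius-relative Gaussian errors emulate what a small primer experiment with
real citizen scientists showed — occasionally large position offsets and
radii routinely overestimated, sometimes by an order of magnitude:

$$\frac{x'-x}{r} \sim N(\mu_{dx}, \sigma_{dx}^2), \quad
\frac{y'-y}{r} \sim N(\mu_{dy}, \sigma_{dy}^2), \quad
\frac{r'}{r} \sim N(\mu_{rr}, \sigma_{rr}^2)$$

The primer experiment's fitted parameters were never published, so the
defaults here are the package's own choice, made once: `μ_dx = μ_dy = 0`,
`σ_dx = σ_dy = 0.5` (shifts mostly within half a radius, tails beyond one
radius), `μ_rr = 2`, `σ_rr = 1` (radii typically doubled, occasionally much
larger). These reproduce the qualitative observations — near-complete
overlap despite sloppy centering, because the CS squares are so large, and
a collapse of classifier accuracy on the CSP-like column. When real
deviation records are available, `fitGaussianDeviationModel()` estimates
all six parameters from data after outlier removal (records with
`|dx_rel|` or `|dy_rel|` above a threshold, default 2, are dropped — the
source says only that "outliers were removed", so the rule and threshold
are declared configuration, not reproduction).

Sampled `r'/r` is kept strictly positive by clamping at 0.05 (resampling is
available by flag). Clamping was chosen as the default because it keeps the
draw count fixed per annotation — exact reproducibility with substreams —
and the clamp frequency is negligible for sane parameters.

## Matching and quality statistics

A CS annotation is *valid* if its square overlaps (area > 0) at least one
expert annotation on the same image; otherwise it is a false positive. An
expert annotation is *found* if at least one CS annotation overlaps it;
otherwise a false negative. Matching is many-to-one: several CS annotations
can be valid against one expert annotation, which is the only reading
consistent with published counts where valid CS annotations far outnumber
found expert annotations. Each valid CS annotation is paired to the expert
annotation of maximal overlap, ties broken by smaller center distance, then
stable input order.

The overlap fraction uses the *expert* square's area as denominator. CS
squares are often much larger than expert squares, and near-complete
overlap of generous CS markers is only coherent when the expert square is
the reference. The symmetric identity
`overlap(a,b)·area(a) = overlap(b,a)·area(b)` is tested.

Percentages (valid/FP over the CS total, found/FN over the expert total)
are rounded for display only; with an empty denominator they are reported
as undefined (`NA`), never as a division failure.

## The synthetic scene generator

The real imagery behind this problem (10 052 AUV images, 54 894
annotations, 10 classes) is not publicly deposited, so the package ships a
synthetic stand-in designed to reproduce the *statistical structure* the
analysis depends on, not the appearance of the seafloor:

* **Class imbalance.** Default 6 classes with frequencies
  (0.45, 0.40, 0.05, 0.04, 0.03, 0.03): the two dominant classes hold 85 %
  of the mass, matching the field observation that 80–90 % of annotations
  belong to a small subset of classes.
* **Appearance families spanning the robustness axes.** `texture` is a
  disc of high-contrast speckle — discriminative signal spread evenly, the
  IP-robust analogue of taxa with uniform texture. `feature` is a plain
  body with one bright compact cue (< 25 % of the sprite, at one end) — the
  IP-sensitive analogue of taxa with prototypical features at specific
  parts; shifting the crop can lose the cue. `faint` is a low-contrast
  object, the FN-prone analogue. `ring`, `dark` and `stripe` fill out the
  inventory.
* **Small objects on a correlated background.** Radii 8–32 px on 512 × 512
  images; the background is smoothed Gaussian noise (correlation length 6
  px, sd 0.06 around intensity 0.45) with a radial vignette (strength
  0.15), emulating flash lighting.
* **Exact ground truth.** Objects are placed by rejection sampling with no
  mutual overlap, each annotation's square tightly containing its object.

What the generator does *not* emulate: photorealistic seafloor texture,
occlusions between animals, marine snow, nodules, within-class shape
variation of real taxa, or the real 10-class inventory. A green end-to-end
test therefore establishes that the *mechanism* (accuracy degradation under
annotation noise, IP worse than IR, localized-feature classes more
IP-sensitive, background rejection) operates as described — it does not
reproduce any published accuracy number, which depended on the unavailable
imagery and a GPU-trained deep network.

## The classifier harness

Patches are extracted as the annotation window rounded outward, padded with
the image mean where it leaves the image, and bilinearly resized to 64 × 64
(the resize is exact when no resampling is needed, which keeps the
identity-perturbation tests bit-exact). The default backend is a
multinomial ridge-regularized logistic model (glmnet) on 8 × 8 block means
and block standard deviations plus global mean/sd — 130 features. The
backend is a contract (`trainClassifier()` / `predictLabels()`), chosen
because it is deterministic, dependency-light and fast at desk scale; a
GPU-trained deep convolutional backend could satisfy the same contract but
is deliberately not bundled.
Two numerical details: the ridge path descends geometrically from 10 to the
working penalty (coordinate descent needs the warm starts), and classes
observed exactly once in training are duplicated (the backend rejects
singleton classes; rare classes are legitimate under class imbalance).

Per-class accuracy is the recall of the true class — the only reading
consistent with a per-taxon accuracy table plus a separately reported
background accuracy. The weighted average is the support-weighted mean of
per-class accuracies, identical to pooled accuracy; this identity is
asserted on every emitted table.

The experiment grid trains **once** on the expert training split and
evaluates all simulated sets against that single model, mirroring the
published protocol. Because the published background-rejection experiment
does not state how its classifier learned the background class, the harness
declares its own recipe: background patches are additionally sampled from
the training images (same distance constraint, default 2 per image) and
added to the training set. This operationalizes — rather than reproduces —
the claim that FP can be absorbed by a background class.

## Reproducibility and numerical choices

* Every stochastic operation draws from R's global RNG under
  `withSeed()`; all generators are bitwise reproducible given (config,
  seed), and never mutate their inputs.
* One global seed fans out into named substreams (`deriveSeed(seed,
  stage)`, a small polynomial hash kept below 2^31), so changing one
  stage's parameters does not shift another stage's draws.
* Text round trips are lossless: CSV numerics are written with 17
  significant digits; the COCO-style JSON dialect stores the center and
  radius redundantly beside the bbox because recovering the center as
  `bbox[1] + bbox[3]/2` is not bit-exact in floating point. Foreign COCO
  files without the extra keys are still read via the bbox.
* The annotation index convention: the source text indexes annotations
  `a = 0…M` while stating `M` annotations in total; the package treats `M`
  as the set size.
* The split is over annotations, not images (the gold-standard protocol
  splits the annotation set; annotations of one image may land on both
  sides). Image-stratified and label-stratified splits are available by
  flag, off by default.

## Known limitations

* The synthetic classifier problem is much easier than real benthic
  classification; absolute accuracies are near 1 on the unperturbed
  validation set, so degradation effects are if anything easier to detect
  than in the field.
* False negatives are measured but not simulated (no published FN
  generator exists to follow); a uniform drop-out would be easy to add but
  is deliberately absent from the defaults.
* The Gaussian deviation defaults are a stand-in for unpublished fitted
  parameters; conclusions about the CSP-like column are qualitative.
* Background placement by rejection sampling can fail on small or crowded
  images with the default 64-px slack; this is reported as an error rather
  than silently relaxing the constraint.
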