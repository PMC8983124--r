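---
title: "Methods: models, parameters and design choices in ferretlung"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in ferretlung}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

ferretlung implements the quantitative phenotyping chain used to
characterize emphysema in ferret models of alpha-1 antitrypsin
deficiency. This vignette records the models each stage assumes, the
parameters that matter (with units and defaults), and the design
decisions taken where the underlying procedures are conventionally left
to software or to a trained operator. Every number quoted here is
either a package default or a quantity the test suite computes.

## Quantitative CT

**Lung segmentation.** Aerated tissue is selected by a single HU
threshold (`lung_threshold`, default −320 HU): low enough to reject
soft tissue (+40 ± 20 HU in the phantom mixture), high enough to keep
even dense parenchyma (−700 ± 60 HU). Every low-attenuation connected
component touching the grid border is discarded — that rule identifies
exterior air without any seed or atlas, and it also removes the airway
lumen wherever the trachea opens onto a volume face. Up to
`keep_components = 2` components are retained, because ferret lungs may
or may not fuse at the carina.

**Airway extraction.** A 26-connected region is grown from a tracheal
seed over voxels at or below a growth threshold, starting at −950 HU
and relaxing in +10 HU steps. The leak rule is volumetric: if one
relaxation step multiplies the region volume by more than
`leak_factor = 2`, the step has breached the airway wall into
parenchyma and the pre-leak region is returned. Automatic seeding takes
the darkest low-attenuation 2-D component on the top slice that does
not touch the slice edge (the exterior air does), and seeds at the
voxel nearest its centroid.

**Mask refinement.** The refined lung is
`fill(close(lung − airway)) − airway`: a morphological closing with a
ball of physical radius `close_radius_mm = 2` (converted per axis to an
ellipsoid in voxels, with the array padded by the element radius so the
border cannot clip the closing), 3-D hole filling by border-flooding
the complement, and a final subtraction that guarantees disjointness
from the airway mask. Because closing and hole filling are idempotent
and the final subtraction only re-removes what the closing re-absorbs,
applying the refinement twice at the same radius changes nothing — the
suite asserts this on the default phantom.

**%LAA.** For each threshold in
`c(-950, -910, -900, -870)` HU the profile reports
`100 × #(lung voxels ≤ threshold) / #(lung voxels)`; the comparison is
inclusive ("at or below"), and the profile is non-decreasing in the
threshold because the threshold sets are nested. Both −910 and −900 are
carried, since both appear in practice; neither is privileged. The
%LAA-versus-obstruction analysis is an ordinary least-squares fit of
%LAA on the FEV~0.4~:FVC ratio across subjects, one fit per threshold;
designs with fewer than two subjects or zero ratio variance raise an
explicit degenerate-design error.

## Spirometry and mechanics

**Onset.** Forced-expiration traces carry no explicit t = 0, so onset
is detected by standard back-extrapolation: a line fitted to the flow
samples between 25% and 75% of peak on the rising limb, with its
zero-crossing (clamped to the trace) as t~0~. Traces whose flow steps
directly to peak fall back to the first sample at or above 25% of peak.

**FEV~x~ and FVC.** FEV~x~ interpolates the cumulative volume linearly
at t~0~ + x. The end-of-test rule — flow below 1% of peak sustained for
at least 50 ms — decides whether the maneuver is complete; FVC is read
at the end of the trace, with a `truncated` flag when the rule never
fires. Reading FVC at the 1%-crossing itself would leave the tail of an
exponential limb (about 1% of FVC at that point) permanently unexhaled
and bias every ratio upward by the same amount; treating the rule as an
adequacy gate keeps noiseless analytic traces within 0.1% of their
closed forms, which the suite verifies.

**FEV timepoint calibration.** `calibrate_fev_x()` returns the smallest
grid x (default 0.1–1.0 s by 0.1) at which a summary of control
FEV~x~:FVC ratios stays *strictly* above the 0.7 obstruction floor. The
summary is `min` by default — all controls must clear the floor — but
is configurable (e.g. `median`), because in practice not every control
male clears 0.7 at the selected timepoint; the choice is recorded in
the returned table. For mono-exponential controls with τ = 0.2 s the
analytic crossing of 0.7 is at 0.2408 s, so the 0.1 s grid selects
0.3 s; the suite checks both this value and the two monotonicity
properties (lowering the floor, or adding a uniformly healthier
control, never raises x\*).

**Multistroke IC.** Delivered volume is a state-function difference, so
the sum of abutting 3→15 and 15→30 cmH₂O strokes equals a single 3→30
stroke for any monotone PV relation. In vivo the second stroke recruits
extra volume; the correction divides the sum by `1 + delta` with
`delta = 0` by default, since the observed ~5% overestimate is an
empirical figure, not a physical constant.

**Quasistatic compliance.** The deflation limb is fitted with the
single-exponential PV relation `V(P) = A − B·e^(−KP)` by
Levenberg–Marquardt least squares (starts from the log-linearized
model; `ftol = ptol = 1e-14`, which recovers noise-free parameters to
10⁻⁶ relative), and `Cst = B·K·e^(−K·P_ref)` at `P_ref = 5` cmH₂O.
Fits with R² ≤ 0.9 are flagged `accepted = FALSE` and excluded from
averages. An (essentially) exactly linear limb is the K → 0 degeneracy
of the model: it is detected up front (linear R² > 1 − 10⁻⁸) or via a
collapsed K (< 10⁻⁴ cmH₂O⁻¹), and handled by a straight-line fit whose
slope is Cst, flagged `fallback_linear`.

## Morphometry

Airspaces are the low-stain (bright) phase; grayscale images are
binarized by Otsu's threshold by default. Labelling is 8-connected;
regions smaller than `min_size_px = 10` are specks; any region
overlapping the airway-exclusion mask by even one pixel is removed
entirely (the mask is the deterministic stand-in for the investigator
who removes pseudostratified-epithelium airways); border-touching
regions are flagged and excluded from SA/P by default because truncated
airspaces bias the ratio upward.

The perimeter estimator is a 4-direction Crofton intercept count. The
textbook uniform direction weighting underestimates axis-aligned
rectangles by about 5%, so the two weight classes (axial, diagonal) are
solved so the estimator is exact for axis-aligned rectangles and for
disks in the continuum limit:
`beta = (1 − π/4)/(π(√2 − 1))` on diagonal counts (spacing 1/√2) and
`alpha = 1/4 − beta` on axial counts. The suite checks rectangles to
1% and digitized disks (r ≥ 20 px) to 3%.

SA/P is aggregated as the mean of per-airspace ratios within a lobe,
then the unweighted mean of lobe means per animal; the pooled
alternative (total area / total perimeter) is available via
`method = "pooled"` since the operator software's convention is not
documented.

## Longitudinal statistics

The mixed model is `response ~ sex + genotype:age + (1 | animal)`,
fitted by REML with Satterthwaite degrees of freedom: a
genotype-specific fixed age slope (mL/cm per day for IC/Ln), a separate
intercept per sex, and a random intercept per animal. No random slope
is included — cohorts of 6–19 animals cannot identify one — and no
genotype main effect is added beyond the slope interaction, matching a
design where genotypes are compared through their slopes. Pairwise
slope contrasts are tested via single-degree-of-freedom contrasts.
Designs in which every animal contributes a single observation make the
random intercept unidentifiable and raise an explicit error.

Paired case/control comparisons are performed on log ratios with a
one-sample t test against 0 (geometric mean ratio versus unity);
repeated measures should be collapsed to per-animal means first.
Inhibition capacity is the trapezoidal AUC of residual protease
activity over added sample volume — trapezoid rather than Simpson
because assay volumes (0, 1, 3, 5, 7, 10 µL) are unevenly spaced — with
lower AUC meaning more antiprotease capacity.

## The synthetic-data generators

The generators exist to give every stage a ground truth; they emulate
structure, not physics.

* **CT phantom.** An elliptic soft-tissue cylinder (body) spanning the
  full craniocaudal axis inside exterior air, two ellipsoidal lungs,
  and a three-generation airway tree whose trachea opens on the top
  face collared by soft tissue. HU mixtures: parenchyma N(−700, 60),
  emphysema N(−930, 30), airway lumen N(−1000, 5) truncated at ±2 SD,
  soft tissue N(+40, 20), exterior −1000 — chosen so the scoring
  thresholds (−950…−870) sit between the two parenchymal modes. The
  lumen truncation keeps every airway voxel at or below −990 HU so that
  region growing at −950 recovers the complete lumen. Each tube wears a
  2-voxel soft-tissue wall, which is what region growing leaks through
  only when a test constructs a breach. Emphysema is voxelwise
  Bernoulli(f) within lung by default — giving exact expected fractions
  — with a blob mode (union of random spheres) when spatial coherence
  matters. The inter-lung gap is wider than twice the default closing
  radius so mask refinement cannot bridge the mediastinum. Not
  emulated: reconstruction kernels, beam hardening, lobar anatomy,
  breathing motion; passing tests say nothing about those.
* **Expiration traces.** Cumulative volume
  `V(t) = FVC·Σ aᵢ(1 − e^(−(t−t₀)/τᵢ))`; flow is its forward
  difference plus optional Gaussian noise, while the volume channel
  stays noiseless so the analytic FEV truths attached to the trace are
  exact. Default sampling 1 ms; default duration 8·max(τ), leaving
  under 0.04% of FVC unexhaled.
* **PV loops.** Both limbs follow the exponential PV relation over
  3–30 cmH₂O; the deflation limb is offset by the hysteresis volume.
* **Airspace images.** Non-overlapping squares and disks with analytic
  area and perimeter attached.
* **Cohorts.** `y = β·age + sex intercept + animal intercept + ε` with
  presets matching the three study genotypes: slopes 0.000093 (PiMM,
  19 animals, 6 visits over 100–1000 d), 0.00043 (PiZZ, 6 animals,
  6 visits over 100–700 d) and 0.00036 mL/cm per day (AAT-KO,
  13 animals, 7 visits over 100–1100 d). Noise defaults — sex
  intercepts 0.85/0.95 mL/cm, random-intercept SD 0.15, residual SD
  0.10 mL/cm — put simulated IC/Ln on the ~1 mL/cm scale of an adult
  ferret and give single-cohort slope standard errors comparable to the
  slopes themselves, a deliberately unflattering regime for recovery.
* **Inhibition curves.** Linear or saturating decay of residual
  activity, re-normalized to the 0 µL well so the anchor holds even
  with noise.

## Problem sizes and reproducibility

The oracle-equivalence check runs on a 160³ phantom (the full QCT chain
in well under a minute on one CPU); routine tests use 96³ and smaller.
Parameter recovery uses 200 replicate cohorts per genotype preset, with
the mean recovered slope accepted within two Monte-Carlo standard
errors of the generating value; `scripts/acceptance.R` regenerates
exactly that computation from a single `--seed`. All generators are
pure functions of (spec, seed), and every pipeline run writes its fully
resolved configuration as JSON so a run is reproducible from its
sidecar alone.

## Known limitations

The phantom's Bernoulli emphysema has no spatial correlation, so it
cannot probe cluster-size-based LAA analyses; the airway tree is
three-generation and symmetric, exercising region growing but not
airway-wall metrics; DICOM series are not read (convert to NIfTI
first); the forced-oscillation mechanics parameters reported by
ventilator software (Rrs, Crs, Ers, Rn, G, H) are out of scope, as
their fitting models are proprietary to that software; and lobar CT
segmentation is not attempted.
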