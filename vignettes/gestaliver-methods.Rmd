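---
title: "Methods: models, defaults and design choices in gestaliver"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, defaults and design choices in gestaliver}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Scientific setting

The package implements the computational chain behind a maternal-liver
volumetry study design: healthy pregnant participants are imaged early
(12–16 wk) and late (32–36 wk) in pregnancy and again months after
weaning; liver volume is measured by slice-summation of freehand ROIs;
abdominal fat compartments come from a five-class MRI segmentation;
insulin sensitivity from a hyperinsulinemic-euglycemic clamp with stable
isotope tracer; body composition from air-displacement plethysmography;
and bile-acid markers from LC-MS/MS with weighted calibration curves.
The statistical questions are whether the liver grows beyond measurement
error during gestation and regresses after weaning ("gain-loss"), and
whether that trajectory tracks body composition, metabolic measures or
gestational hypertension.

No participant data ship with the package. Every pipeline runs on
synthetic inputs whose generating parameters are the published summary
statistics, so each stage can be tested against known ground truth.

## Abdominal phantoms

`make_abdomen_phantom()` renders a 2.5D geometry: identical-topology
axial sections (elliptical body, subcutaneous fat ring, muscle wall,
organ interior, scattered visceral fat blobs) with a slow cosine taper
along the slice axis. This mirrors thick-slice (6 mm) axial abdominal
acquisitions, where in-plane structure dominates and slice-to-slice
change is gradual, and it keeps the watershed and contour stages
meaningful without anatomical realism. Key choices:

- **Intensity ordering** is fixed as adipose > organ > muscle >
  background (defaults 1000/550/300/40), the T1 fat-hyperintense
  situation that makes adipose thresholding well posed. Specs violating
  the ordering are rejected.
- **Bias field**: Gaussian-blurred white noise in the log domain
  (correlation length 60 mm), rescaled so the peak log-amplitude equals
  the requested amplitude (default cap 30%) and exponentiated. A
  multiplicative, smooth, unstructured field is the standard working
  model for receive-coil inhomogeneity; nothing finer is claimed.
- **Noise** is additive Gaussian; "SNR 10" in the tests means adipose
  mean / noise SD = 1000/100. At that level the muscle-background
  contrast is only 2.6 SD, which is exactly why the body-mask and
  hole-filling design below matters.
- **Uterus and liver stand-ins**: a bright (adipose-like) lower slab and
  a large organ-class upper slab, each with a matching binary exclusion
  mask. They exist to exercise the false-positive-exclusion step; they
  are not anatomical models.
- **VAT blobs** keep a margin (default 6 mm) from the muscle wall so
  that subcutaneous and visceral fat remain morphologically separable —
  the situation the SAT/VAT pipeline assumes; heavily abutting fat
  compartments are out of the phantom's scope.

`make_liver_slice_stack()` produces per-slice areas under a smooth dome
profile with multiplicative per-slice jitter, rescaled exactly to the
target volume, so slice-summation volumetry round-trips by construction.

What the phantom does **not** emulate: partial-volume voxels, MR physics
(no k-space, TE/TR, ghosting), fetal anatomy, station-to-station affine
misalignment (station merging is modelled as overlap elimination only),
and anatomy-correlated bias. A green segmentation gate therefore
establishes correctness and robustness of the algorithmic chain on
piecewise-constant anatomy with realistic noise and bias — not clinical
accuracy on patient scans.

## Segmentation pipeline

**Bias correction** (`correct_bias_field()`) follows the N4 idea —
alternate between a piecewise-constant tissue model and a smooth
multiplicative field in the log domain — but replaces the B-spline /
histogram-sharpening machinery with quantile-initialised k-means class
means and masked Gaussian smoothing of the class residuals, computed on
a ~5 mm coarse grid (the field is smooth by definition, so estimating it
at full resolution buys nothing). Four iterations, field scale 40 mm,
four classes by default; the field is normalised to unit geometric mean
over the body so the intensity scale is preserved. On phantoms this
recovers a 30% field to about 1% RMS. The estimation is fully
deterministic (stride subsampling, quantile-seeded k-means), so a fixed
input always yields the same field. A constant image returns a unit
field unchanged.

**Body mask**: a single Otsu split of an abdominal histogram lands
*between tissue classes*, because air dominates the voxel count. The
body mask therefore uses hierarchical Otsu — split once, then re-split
the dark half — which places the threshold in the air-to-darkest-tissue
gap. At SNR 10 roughly a tenth of muscle voxels still fall below any
such threshold; these reappear through hole filling. Hole filling is
**in-plane per slice**: dark speckle inside the muscle wall can
percolate into a connected cluster that touches the first or last slice
of the stack, which full-3D filling would misread as exterior. In-plane,
each slice's body section encloses its holes regardless of axial
position.

**Adipose threshold**: Otsu within the body mask by default (the split
between the bright fat mode and everything else is the dominant one
there), overridable by an absolute value; components below 27 voxels
(a 3×3×3 cube) are dropped.

**Muscle** (`segment_muscle()`): a seeded compact watershed grown on the
gradient magnitude of the (lightly smoothed) corrected image, restricted
to the non-adipose body. Flood priority is
`|∇I| + c · d(x, seed)` with `d` the physical (mm) distance to the
originating seed voxel and `c = 0.5` intensity-units/mm by default: flat
terrain floods freely, but distant growth pays a penalty, which keeps
regions compact across the unseeded slices of a sparse (e.g. 11 of 30
slices) manual seed map. Non-muscle seed classes from the same map
compete as a second label; ties on priority resolve FIFO for plateau
stability. Muscle seeds are always retained in the output.

**Subcutaneous shell** (`segment_sat()`): the paper-named geodesic
active contour is implemented morphologically — initialise at the body
boundary, erode the adipose mask by the in-plane morphology radius
(default 2 voxels) to cut thin noise bridges, propagate the boundary
front geodesically through the eroded mask (capped iterations), then
re-dilate. The front's claim is applied at the level of connected
adipose components (majority rule): the peripheral shell component(s)
become SAT, untouched internal components stay visceral. Component-level
assignment makes "no visceral fat ⇒ SAT equals total adipose" exact and
avoids voxel-level morphology artefacts at the ring boundary.

**VAT** is the set difference of total adipose and SAT, so SAT and VAT
partition the post-exclusion adipose mask *exactly* — the five-class
contract asserts this as an identity, not a tolerance. Uterus/liver
exclusion masks are subtracted from the adipose mask before the split
(those two organs are systematic adipose false positives). Axial
analysis bounds (top of liver, L4/5 disk) crop with 0-based, half-open
`[lower, upper)` indexing.

The study protocol's slice-by-slice manual refinement has no analyst in
the loop here; it is replaced by a quantitative acceptance gate: at
SNR 10 with a 30% bias field on a 160×160×30 phantom, the default
pipeline must reach Dice ≥ 0.90 (SAT, VAT) and ≥ 0.85 (muscle).
Measured values are ≈ 0.998 / 0.93 / 0.99.

## Volumetrics and the change classifier

Liver volume is `Σ areaᵢ × interval` (cm³). Two denominator conventions
are fixed deliberately:

- **Interoperator percent difference** uses the pair mean,
  `100 (a − b) / ((a + b)/2)`, symmetric in the operators; the published
  two-operator exercise reports only the resulting ±7% band.
- **Pregnancy change** uses the early volume as denominator; **postwean
  change** uses the late volume — each leg of the trajectory is judged
  against its own baseline, matching a per-participant two-bar display.

`classify_change()` calls a change real only beyond the tolerance
(default 7%, from the printed interoperator range; configurable);
`classify_pattern()` labels a trajectory "gain-loss" iff pregnancy gain
**and** postwean loss, with subtypes (loss-gain, no-change,
continuous-gain, continuous-loss, other) for the rest. Station merging
keeps overlapping slices from the upper (liver-centred) station and is
exactly volume-conserving when the overlap is a true duplicate.

## Clamp physiology, densitometry, calibration

Steele's equations are implemented in their steady-state form — the
protocol samples 90–120 min of the basal infusion and the final 30 min
of the clamp, i.e. plateau conditions — so basal
`EGP = F (E_inf/E_p − 1)`. Non-steady-state Steele is out of scope. The
insulin-suppressed estimate treats clamp-period tracer dilution as total
glucose appearance and subtracts the exogenous infusion, floored at
zero; the cited suppression method's exact correction terms are not
restated in the source literature available here, so the appearance
formula is a pluggable strategy (`ra_fn`), with the steady-state
dilution as default. `Rd = GIR + EGP_clamp` by conservation at the
glucose clamp. Tests validate all three against an independent
one-compartment mass-balance ODE integrated to steady state, across a
grid of infusion and appearance rates (recovery within 2%).

Body composition uses the two-compartment density model with
`d_fat = 0.9007 g/cm³` and a *stage-indexed* fat-free-mass density table
to represent pregnancy hydration of the fat-free compartment. The
published pregnancy coefficients are not printed in the source; the
default table (1.100 nonpregnant/postwean, 1.099 early, 1.087 late) is a
**placeholder** with the standard nonpregnant value and a plausible
late-pregnancy reduction, and real analyses should supply their own.
Densities outside the model range clamp the fat fraction to [0, 1] with
a warning rather than erroring, since slightly out-of-range densities
occur in practice.

Calibration curves are weighted least squares with `wᵢ = 1/xᵢ` (the
assay convention that stabilises relative error), closed-form slope and
intercept, and a stored calibration range; back-calculated
concentrations outside it are flagged, not rejected. Weighting affects
variance, not bias, for zero-mean noise — asserted by Monte-Carlo test.

## The synthetic cohort

`simulate_cohort()` draws, per participant, an early liver volume
`N(1239, 220.8²)` and a change `N(182, 197²)`, independently: the
printed late-pregnancy SD (298.6) implies a negligible early–change
correlation (≈ 0.02 by the variance identity), and independence
reproduces the late SD within 1% (295.9). Covariate *changes* carry the
correlation structure through a one-factor Gaussian copula with the
standardised liver change as factor — each covariate hits its published
correlation target and the implied matrix is positive semi-definite by
construction. Baseline weight is tied to early liver volume (r = 0.5 by
default) to encode the baseline liver–body-size coupling; the source
shows the scatter but prints no r, so this is a package default, chosen
once. Covariate baselines, change scales and newborn anthropometrics
use ordinary clinical magnitudes (e.g. weight 70 ± 12 kg, gestational
gain 11 ± 4 kg, newborn 3400 ± 450 g); they set plausible scales, and
the correlation targets — not these scales — are what the tests pin.

Subgroups are enforced by **stratified quota sampling** (default): draws
are classified by `classify_change()` and sampled per stratum to the
exact printed counts (34/10/3 at n = 47), so desk-scale runs match the
printed table; with `quota = FALSE` membership is emergent and the
copula correlations are exact — the large-n recovery tests use that
mode. The natural classification probabilities under the generating
distributions (≈ 0.68/0.24/0.08) are close to the printed proportions,
so quota selection distorts the copula only mildly.

Postwean structure: 17 of 47 complete; the completer trajectory quota
is gain-loss 9, loss-gain 3, no-change 3, continuous-gain 1, plus one
gain-then-no-change. The published secondary-pattern counts (3 + 3 + 1
+ 1 around 9 gain-loss) are internally inconsistent with only 3
pregnancy losses in the whole cohort — they would require 4 — so the
default quota replaces the continuous-loss completer with a
gain-then-no-change one; the counts that *are* jointly printed
(34/10/3, 17, 9 gain-loss, hypertension 0% vs 50%) are reproduced
exactly. Hypertension is placed only among not-gain-loss completers
(50%). Gain-loss completers receive +1 SD shifts in late-pregnancy EGP
and Rd; the source reports the direction and significance but no group
means, so the effect size is a spec parameter, not a published constant.
Newborn measures are simulated independent of pattern group, encoding
the published null finding.

`attach_imaging()` gives each participant-visit slice stacks whose
computed volume matches the table (exactly, or under multiplicative
operator noise). One stated expectation could not be honoured: with 3%
operator noise, "the two-operator range stays within ±7% in ≥ 95% of
replicates" is mathematically unattainable (the max of ten ±4.2%-SD
pair differences exceeds 7% in roughly half of replicates); the test
instead asserts distributional agreement between the pipeline-recovered
range and a direct simulation oracle of the injected spread.

## Statistics stage

All tests are two-sided. `correlation_p_from_r()` uses the exact
transform `t = r√(n−2)/√(1−r²)` on `n − 2` df, applied to Spearman's rho
as the usual large-sample approximation (the published table marks IHL
and EGP as Spearman; the method map defaults accordingly). Printed
percentages use half-up integer rounding (`floor(x + 0.5)`); p values
are reported to 3 decimals. Missingness is complete-case per variable,
which is how a published table acquires its varying per-row n. No
multiple-testing adjustment is applied anywhere, mirroring the source;
reports carry raw p only.

Reproducing the published correlation table from its own printed (r, n)
pairs: three rows round cleanly to the printed p at 3 decimals (0.335/47
→ 0.021; 0.260/47 → 0.078; 0.245/47 → 0.097) and are asserted exactly;
eleven further rows agree within ±0.002; two rows (M value −0.015/43 →
0.926; insulin 0.095/45 → 0.537) sit 0.0021 away, consistent with the
printed r itself being rounded to 3 decimals (an r perturbation of
±0.0005 moves these p values by ~0.003), and are asserted within
±0.003.

The headline percent change is reported both as the ratio of the mean
change to the mean early volume (the default headline — it reproduces
the printed 15% exactly from the printed means) and as the mean of
per-participant percent changes; the source does not say which it used.

Group comparisons use Welch's t for continuous metrics (the robust
default when group variances are not asserted equal) and Fisher's exact
test for hypertension counts. The paired t test's type-I error is
verified at the nominal 5% over 2,000 null replicates.

## Numerical conventions and degenerate inputs

- Otsu maximisation over a 256-bin histogram; across a flat plateau
  (empty gap between modes) the first maximising bin wins.
- Watershed priority ties resolve FIFO (insertion order), making floods
  deterministic on plateaus; 6-connectivity for floods and components.
- Morphology radii are voxel radii per axis; slice-axis radius 0 keeps
  operations in-plane, the default for 6 mm slices.
- Seeded determinism throughout: phantoms, cohorts and the bias
  estimator produce identical output for identical seeds/inputs.
- Degenerate inputs fail loudly and early: empty body masks, reversed
  crop bounds, seedless watersheds, non-subset SAT masks, zero plasma
  enrichment, nonpositive reference volumes, sub-3-point calibrations.
  Two deliberate soft failures: an adipose threshold that excludes
  everything warns and returns an empty mask, and an out-of-model body
  density warns and clamps.

## Limitations

The segmentation is validated on piecewise-constant phantoms; partial
volume, motion, anatomy-correlated bias and fat-water chemical-shift
artefacts are untested. The clamp module implements steady-state algebra only. The
van Raaij-style density table is a placeholder. The cohort generator
reproduces first- and second-moment structure and subgroup logic, not
longitudinal weight-gain trajectories or EHR-style missingness. The
statistics stage intentionally stops where the source does: no
regression modelling, confounder adjustment or multiplicity control.
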