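---
title: "Measuring the Evans Index from label volumes: models, conventions and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring the Evans Index from label volumes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(evansindex)
```

## The measurement

The Evans Index (EI) is the ratio of the maximal width of the frontal horns
of the lateral ventricles to the maximal inner-skull diameter at the same
axial level. It is a standard linear marker of ventriculomegaly; values at
or above 0.30 are conventionally read as enlarged, which matters most in
normal pressure hydrocephalus (NPH), where ventricular size guides
diagnosis and shunt decisions. The measurement is only well defined
relative to a reference orientation: the axial plane must be parallel to
the line joining the anterior commissure (AC) and the posterior commissure
(PC), and the frontal horns are the ventricular compartment anterior to the
interventricular foramen (IVF, the foramen of Monro).

`evansindex` implements the measurement as a deterministic geometric
pipeline on label volumes. The package deliberately starts *after*
segmentation and landmark detection: its inputs are a binary
lateral-ventricle (LV) mask, a binary intracranial-volume (ICV) mask on the
same grid, and the AC/PC/IVF positions in world millimetres. Producing
those inputs (by neural networks, atlas methods or by hand) is upstream of
this package; everything downstream — alignment, mask cleanup, width
measurement, the ratio, robustness protocols, and agreement statistics —
is implemented and validated here.

`compute_evans_index()` chains the steps:

1. **AC–PC realignment.** `acpc_rotation()` returns the minimal-angle
   rotation taking the unit vector from PC to AC onto the world anterior
   axis, pivoted at the AC–PC midpoint. Volumes are resampled with
   nearest-neighbour interpolation (`apply_rigid()`), which preserves
   label identity exactly; landmarks are mapped analytically.
2. **Mask postprocessing.** The ICV mask keeps its largest connected
   component and has internal voids filled; the LV mask drops components
   smaller than 1% of its foreground.
3. **Frontal-horn extraction.** Voxels of the aligned LV mask with
   voxel-center world `y` strictly greater than the IVF's `y`.
4. **Width and diameter.** `max_lateral_width()` scans axial slices for
   the largest left–right extent of the frontal mask;
   `inner_skull_width_at_slice()` measures the ICV extent at that same
   slice, along the same left–right direction.
5. **Ratio and classification.** EI = width / diameter; `ei >= threshold`
   (default 0.30) flags ventriculomegaly.

## Conventions that affect the number

Several small conventions move the result by up to a voxel, so they are
fixed and documented rather than left implicit.

**Edge-to-edge widths.** A slice width is the extent of foreground voxel
*centers* plus one x-spacing. Calipers on a workstation measure between
structure walls, not between voxel centers; the bare center-to-center
extent would bias the EI low by about one voxel over the diameter
(roughly 0.01 at a 100 mm skull). `width_convention = "center"` exposes
the alternative for sensitivity analysis.

**Diameter direction.** The inner-skull diameter is measured along the
same left–right axis as the horn width, keeping the two measurements
parallel; `diameter_mode = "max_chord"` provides the maximal any-direction
in-plane chord as a variant but is not the default.

**Ties and rounding.** The measurement slice is the smallest axial index
achieving the maximal width; world-to-voxel rounding is half-up per axis.
Both choices only matter at exact ties and make endpoint reporting
deterministic.

**Roll is left uncorrected.** Two collinear landmarks cannot constrain
rotation about their own axis: AC–PC alignment removes pitch and yaw of
the AC–PC line but cannot observe roll about it. `acpc_rotation()`
accepts an explicit `roll_deg` when roll is known from another source
(e.g. a prior whole-head registration); otherwise roll passes through,
and the robustness protocol below quantifies the consequences.

**Axis-aligned grids only.** `reorient_to_ras()` canonicalizes axis
permutations and flips exactly, but refuses oblique affines (off-axis
direction cosine above 0.2). Pipelines that produce oblique grids are
expected to resample during their upstream rigid registration; silently
resampling labels here would blur the provenance of measurement error.

## The phantom model

All quantitative validation runs on synthetic head phantoms with
closed-form ground truth (`phantom_spec()`, `make_phantom()`):

* the inner skull is an ellipsoid with semiaxes (a, b, c), default
  (50, 60, 43) mm — a typical adult inner vault (about 140 x 170 x 120 mm)
  scaled to the 100 mm lateral diameter used throughout the validation
  phantoms;
* the frontal horns are mirrored spheres of radius r = 5 mm centered at
  (±x_h, 32, 0), so the true width is W = 2(x_h + r) and, because the
  horns sit on the skull's equatorial plane z = 0, the true matched-slice
  diameter is exactly 2a and the true EI is W/(2a) in closed form;
* the ventricle bodies are boxes strictly posterior to the IVF plane.
  The LV compartments are therefore disconnected — intentionally, since
  the pipeline's small-cluster rule must keep both ventricles rather than
  delete one;
* landmarks sit on the midline: AC (0, 18, 0), PC (0, −8, 0) (26 mm
  AC–PC distance), IVF (0, 16, 0).

Cohorts (`generate_cohort()`) sample the true EI uniformly on 0.22–0.42,
spanning normal to NPH-like geometry around the 0.30 threshold, and vary
`x_h = a·EI − r` accordingly. All randomness flows through explicit seeds.

Two numerical choices make the phantom a clean instrument:

* **Strict voxel-center inclusion.** A voxel belongs to a curved shape if
  its center is strictly inside. With closed inclusion, a surface that
  passes exactly through voxel centers creates tangent voxels that flip
  under any resampling — and round-number phantom dimensions place
  surfaces on the grid constantly.
* **Cell-centered grid.** The phantom grid has even dimensions with voxel
  centers at half-integer millimetres, so integer-valued surfaces fall on
  voxel boundaries. Together these make the neutral default phantom
  measure exactly W = 30, D = 100, EI = 0.300.

Rotated phantoms (`make_rotated_phantom()`) are voxelized directly in the
rotated frame: the analytic shapes are rotated before voxelization and the
landmarks are transformed exactly. The fixture therefore carries no
resampling error of its own, and any deviation measured after corrected
realignment is attributable to the pipeline.

What the phantom does *not* emulate: real ventricular shape (occipital and
temporal horns, asymmetry), partial-volume effects at mask boundaries,
segmentation failure modes beyond boundary jitter, and gantry-tilted or
oblique acquisitions. Passing phantom tests therefore demonstrates the
geometric correctness and rotational behaviour of the measurement, not
segmentation quality on clinical scans.

## The rotational-robustness protocol

`perturbation_study()` rotates each phantom about the AC–PC midpoint by
±5°, ±10°, ±15° and ±20° around each of three axes (pitch = left–right
axis, yaw = inferior–superior, roll = anterior–posterior) and re-measures
the EI in two modes:

* **blind** — measure in the acquisition frame without re-alignment,
  emulating a reader (or a naive pipeline) that trusts the scanner
  orientation; the frontal-horn cut still uses the detected (rotated) IVF.
* **corrected** — run the full pipeline, which re-aligns from the rotated
  landmarks.

On phantoms the corrected mode removes pitch and yaw exactly (residuals at
or near zero across all angles), while blind-mode error grows with angle,
fastest for roll and yaw. Roll is the designed exception in corrected
mode: because the AC–PC line *is* the roll axis, the corrected run is
identical to the blind run, and the roll error survives correction. That
asymmetry is the quantitative content of the protocol: alignment from
AC–PC landmarks is necessary and sufficient for pitch/yaw, and
insufficient for roll.

One consequence for the statistics: a signed-rank test of roll's blind
errors against roll's *own* corrected residuals is degenerate (all
differences are exactly zero). The protocol therefore compares each axis's
±20° blind errors against the pitch-corrected residuals, which estimate
the pipeline's discretization-noise floor under an equivalent rotation and
resampling load. `perturbation_report()` additionally reports the
per-cell blind-vs-corrected test where it is defined.

## Agreement statistics

`bland_altman()` reports the mean difference (oriented automated minus
manual, so positive bias means the automated method reads high), the
sample SD of differences (n − 1 denominator), 95% limits of agreement at
bias ± 1.96·SD, the mean absolute error, and the Pearson correlation.
`wilcoxon_signed_rank()` implements the signed-rank test with zeros
dropped and mid-ranks for ties; for up to 25 effective observations the
two-sided p-value is exact, computed from the full null distribution of
the statistic via a rank-polynomial convolution (equivalent to enumerating
all 2^n sign assignments), otherwise a normal approximation with tie
correction and a 0.5 continuity correction is used. The exact branch is
cross-checked in the test suite against an independent brute-force
enumeration, and against `stats::wilcox.test()` on tie-free cases.
`covariate_bias_screen()` tests absolute errors against continuous
covariates (correlation t-test) and binary ones (Welch t-test).

One algebraic note: the Bland–Altman bias is a difference of means and is
therefore invariant to re-pairing the two vectors; pairing only affects
the SD, limits of agreement and MAE. The test suite pins this down
explicitly.

## Problem sizes and runtime

The validation suite uses 1 mm isotropic phantoms (about 150 x 165 x 140
voxels), a 20-phantom deterministic EI grid on 0.22–0.41, a 30-phantom
cohort for the rotational protocol (24 rotated variants each in blind
mode, ±20° in corrected mode), 500 simulation seeds for
agreement-parameter recovery, and 100 random masks up to 32³ for the
morphology oracles. A resolution-consistency check compares 1 mm against
0.5 mm phantoms. These sizes keep the full suite in the tens of minutes on
a single core while leaving the geometric conclusions unchanged at finer
resolution.

## Known limitations

* Labels are resampled with nearest-neighbour interpolation only; there is
  no sub-voxel surface model, so single-voxel effects (about 0.01 in EI at
  a 100 mm skull) are the resolution floor of the measurement.
* Oblique acquisition grids are rejected, not resampled.
* The frontal-horn boundary is a plane through the IVF perpendicular to
  the anterior axis; oblique anatomical boundaries between horn and body
  are not modelled.
* The phantom validates geometry, not segmentation; agreement with manual
  readings on clinical data must be established with
  `bland_altman()`/`cmd_agree()` on real paired measurements.
* Landmark error is out of scope: AC/PC/IVF positions are taken as given,
  and their uncertainty propagates to the EI through the alignment without
  being modelled here.

## A worked example

```{r example, eval = FALSE}
library(evansindex)

# a synthetic case with known truth (EI = 0.30)
ph <- make_phantom(phantom_spec())
res <- compute_evans_index(ph$lv, ph$icv, ph$landmarks)
res
#> <ei_result>
#>   Evans Index:          0.3000
#>   frontal-horn width:   30.00 mm
#>   inner-skull diameter: 100.00 mm
#>   measurement slice z:  66
#>   ventriculomegaly (>= 0.3): TRUE

# robustness of that case to a 20-degree roll
rot <- make_rotated_phantom(phantom_spec(), rotation_spec("roll", 20))
compute_evans_index(rot$lv, rot$icv, rot$landmarks)$evans_index
#> [1] 0.255102
```
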