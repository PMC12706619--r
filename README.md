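# evansindex

Automated measurement of the **Evans Index (EI)** — the ratio of the
maximal frontal-horn width of the lateral ventricles to the maximal
inner-skull diameter at the same axial level — from NIfTI label volumes.
The EI is the standard linear marker of ventriculomegaly (conventionally
EI ≥ 0.30), central to the workup of normal pressure hydrocephalus and
related CSF disorders, but it is only reproducible when the head is
aligned to the anterior commissure–posterior commissure (AC–PC) plane and
the frontal horns are delimited consistently at the interventricular
foramen (IVF).

The package takes a lateral-ventricle mask, an intracranial-volume mask
and AC/PC/IVF landmark coordinates, and computes

    EI = W / D,   W = max_z [ x-extent of the frontal-horn mask at slice z ]
                  D = x-extent of the inner-skull mask at the same slice z

after rigidly realigning masks and landmarks so the AC–PC line runs along
the anterior axis (nearest-neighbour label resampling), cleaning the masks
(largest component + void filling for the skull, small-cluster removal for
the ventricles), and cutting the frontal horns strictly anterior to the
IVF. Widths use an edge-to-edge convention (voxel-center extent plus one
spacing). It also ships the surrounding scientific tooling:

* **Rotational-robustness protocol** — controlled pitch/yaw/roll rotations
  (±5°…±20°) about the AC–PC midpoint, measured *blind* (no re-alignment)
  and *corrected* (full pipeline), with median-error and signed-rank
  summaries. On phantoms, correction removes pitch and yaw exactly while
  roll — unobservable from two collinear landmarks — passes through.
* **Agreement statistics** — Bland–Altman bias/SD/95% limits of agreement,
  MAE, Pearson r, an exact Wilcoxon signed-rank test (full null
  distribution up to n = 25; tie- and continuity-corrected normal
  approximation beyond), and a covariate bias screen.
* **Synthetic head phantoms** — ellipsoid skull plus spherical frontal
  horns with closed-form ground truth (true EI = 2(x_h + r)/2a), rotated
  variants voxelized analytically in the rotated frame, boundary-jitter
  noise, and seeded cohorts spanning EI 0.22–0.42.

## Worked example

```r
library(evansindex)

ph  <- make_phantom(phantom_spec())          # default phantom, true EI 0.30
res <- compute_evans_index(ph$lv, ph$icv, ph$landmarks)
res
#> <ei_result>
#>   Evans Index:          0.3000
#>   frontal-horn width:   30.00 mm
#>   inner-skull diameter: 100.00 mm
#>   measurement slice z:  66
#>   ventriculomegaly (>= 0.3): TRUE
```

The frontal horns measure 30 mm across at axial slice 66, the inner skull
100 mm at that same slice, so EI = 0.300 — exactly the phantom's analytic
truth — and the case is flagged as ventriculomegalic at the 0.30
threshold. The same measurement on files:

```r
cmd_measure("lv.nii.gz", "icv.nii.gz", "landmarks.json",
            out_json = "result.json")
```

where `landmarks.json` is
`{"AC":[x,y,z],"PC":[x,y,z],"IVF":[x,y,z],"space":"world_ras"}` in
millimetres. A misaligned acquisition is handled by the same call — the
pipeline re-aligns from the landmarks; to quantify what alignment buys on
a given case:

```r
study <- perturbation_study(phantom_spec(), axes = "roll", angles = c(-20, 20))
perturbation_report(study)
#>   axis angle_deg median_abs_err iqr  W  p monotone_axis
#> 1 roll       -20     0.04489796   0 NA NA          TRUE
#> 2 roll        20     0.04489796   0 NA NA          TRUE
```

A 20° roll shifts this phantom's EI by ≈ 0.045 — and stays there after
correction, because roll cannot be recovered from the AC–PC line alone.

A command-line wrapper with subcommands `measure`, `batch`, `perturb`,
`agree` and `phantom` is installed under `inst/cli/evansindex`.

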