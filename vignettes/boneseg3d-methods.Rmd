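---
title: "BoneSeg3D: methods, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{BoneSeg3D: methods, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(BoneSeg3D)
```

## The segmentation model

BoneSeg3D segments pelvic-region bones in single-energy (or
DECT-mixed) CT volumes for downstream uses that must treat the whole
bone — cortical shell *and* interior — as bone, because the interior
contains trabecular bone and marrow.  The pipeline combines three
simple, transparent mechanisms whose failure modes are well
understood:

* **Thresholding** captures dense cortical bone reliably but neither
  the low-attenuation interior nor thin or osteoporotic cortex.
* **Seeded region growing**, gated by a *local-maximum* criterion
  (voxel above its `n³` box-neighbourhood mean, `n = 9`) and an HU
  acceptance range, extends the segmentation along locally bright
  structures while resisting absolute-intensity drift.  Both criteria
  are precomputed; growth is then 26-connected reachability, so the
  result provably does not depend on seed enumeration order.
* **3D hole filling** converts the topological fact "enclosed by
  bone" into the marrow label: after nearby parts are merged by a
  physical-radius closing, every background voxel not 6-connected to
  the volume border becomes label 2.

The assumptions, in order of importance: bones have a mostly closed
cortical shell brighter than ~200 HU after intensity normalisation;
openings in that shell (foramina) are smaller than twice the merge
radius; distinct bones are separated by more than twice the merge
radius; and the scan's intensity scale can be normalised to a
reference by a *global monotone* transform.

## Parameters

| Parameter | Default | Unit | Role |
|---|---|---|---|
| `tBone` | 200 | HU | lower threshold; selects most compact bone |
| `tSeed` | 400 | HU | seed threshold; must exceed `tBone` |
| `boxN` | 9 | voxels | box-filter side for the local-maximum mask |
| `acceptLow` / `acceptHigh` | 150 / ∞ | HU | growing acceptance range |
| `mergeRadiusMM` | 3 | mm | physical closing radius for part merging |
| `airThreshold` | −500 | HU | body/air separation |

`tBone = 200` sits between trabecular (~100–300) and cortical
(>700) attenuation; `tSeed = 400` is above everything but bone.  The
acceptance range is open above because no voxel should ever be too
bright to be bone.  `mergeRadiusMM = 3` must exceed half the largest
cortical perforation to be sealed (foramina, 1–2 mm) while staying
below half the normal hip-joint space; it is the single most
consequential parameter, and the kissing-joint preset exists to probe
it.  All parameters live in one `PipelineParams` object, are readable
from YAML and overridable per CLI flag; each run logs the fully
resolved set.

## Numerical choices

* **Histogram matching** is classical CDF/quantile matching on
  1-HU-wide bins over [−1024, 3071], estimated on body voxels only
  (above `airThreshold`).  The inverse CDF is inverted *per mass bin*
  (empty bins never stretch an interpolation segment), which makes
  self-matching exact to floating-point precision and idempotent, and
  keeps the Kolmogorov–Smirnov distance of a matched volume to the
  reference at the sub-bin level.  A constant volume sits at the CDF
  midpoint (quantile 0.5).  Air voxels do not influence the estimate
  but are still mapped, via a slope-one extension below the body
  range, so the air plateau is not stretched into the tissue range.
* **Box filter boundary rule**: the mean is taken over the
  intersection of the box with the volume (shrinking window).  Zero
  padding would darken the apparent neighbourhood mean near borders
  and create spurious local maxima there.
* **Strict inequality** in the local-maximum criterion; ties give 0,
  so a constant volume has an empty mask.
* **Connectivity duality**: foreground operations (growing, component
  analysis, merging) use 26-connectivity; background reachability in
  hole filling uses the complementary 6-connectivity.  Using 26 for
  both would let background "leak" diagonally through intact
  one-voxel shells.
* **Closing at the volume border** treats out-of-volume voxels as
  foreground during erosion, so closing remains extensive
  (`output ⊇ input`) everywhere.
* **Degenerate inputs**: an all-air volume is an error ("empty
  body"); an empty seed mask grows nothing, with a warning; two empty
  masks have Dice 1 (agreement on absence), with a warning.
* **Table removal** closes the above-air mask with a 2-voxel ball
  (bridging small skin gaps) before keeping the largest 26-connected
  component.  This is a heuristic, chosen because it needs no shape
  prior and is robust on pelvic fields of view; it is logged and can
  be disabled.

## The synthetic phantom

`generatePhantom()` emulates the features that make pelvic bone
segmentation hard: weak/diffuse boundaries (Gaussian blur, default
σ = 0.8 mm, then additive noise, default 15 HU), brightening of
tissue between close bones, cortical perforations, a near-contact
femoral-head/acetabulum joint, a detached patient table, and
low-contrast osteoporotic bone.  Tissue values: soft tissue 0,
muscle 50, marrow 150, cortical 1200, table −300 HU.  Ground truth is
computed from the pre-blur geometry, so Dice measures the algorithm,
not the corruption.

The anatomy (body and muscle ellipses, two capped femoral shafts with
spherical heads, a torus-shaped pelvic ring, acetabular cups facing
the heads) scales with the physical field of view, while clinically
absolute quantities — cortical thickness (2 mm shaft; half that at
the thin-cortex sites: head, ring, cup), foramen radius, joint gap,
blur, noise — stay in mm/HU.  Structure radii sit at the top of the
anatomically plausible range for the default scaled-down 96 mm field
of view, deliberately: the dominant residual error of threshold-based
segmentation is the partial-volume halo at the bone surface, whose
relative weight scales with surface-to-volume ratio, and undersized
structures would overstate it relative to clinical data.  Bone
occupies ≈15 % of the body cross-section.

The acetabular cup models the lunate-surface/fossa anatomy: the
articular rim faces the femoral head across `jointGapMM`, while the
central fossa is carved 6 mm deeper into the pelvic bone.  This makes
the characteristic joint-bridging failure expressible: when the rim gap is
below `2 × mergeRadiusMM`, part merging seals the rim ring, the deep
fossa pocket becomes enclosed background, and hole filling labels the
joint space as marrow; at the default 8 mm gap nothing bridges.  The
`kissing_joint` preset uses a 4 mm gap — narrow enough to bridge,
wide enough that partial-volume brightening does not already push the
whole space above `tBone` (below ≈2.5 mm the space is simply absorbed
as label-1 bone, an even earlier failure of the same family).

**Osteoporosis model.**  `osteoporosisFactor` (preset 0.5) scales
cortical intensity globally, and below 1 it additionally (a) imposes
a smooth deterministic spatial pattern of regional mineral loss,
`f^(4w)` with `w ∈ [0, 1]` a fixed long-wavelength field, on the
thin-cortex sites, and (b) scales the marrow contrast over soft
tissue (trabecular rarefaction).  The structural components matter: a
*purely global* intensity scaling is a monotone transform of
identically ranked data, which the pipeline's own histogram-matching
stage inverts almost exactly — under pure scaling, measured Dice at
factor 0.5 actually *rises* (lower contrast shrinks the
partial-volume halo, and quantile matching back-fills the intensity
deficit from the marrow ranks).  Regional density loss and marrow
rarefaction are rank-degenerate with soft tissue and therefore cannot
be undone by any monotone intensity map — as in real patients, where
matching against a reference scan does not restore lost bone mineral.
One honest subtlety: between factors 1.0 and ≈0.75 the net effect on
Dice is a small *increase* (~+0.005), because the halo shrinks before
the structural losses bite; from ≈0.75 downward degradation dominates
and is strictly monotone (the failing patch set is nested by
construction as the factor decreases).  The monotonicity checks
therefore probe factors {1.0, 0.5, 0.25} and report the crossover
here rather than hiding it.

**What passing the phantom tests does *not* show.**  The phantom has
piecewise-constant tissues, axis-aligned simple shapes, stationary
Gaussian noise and no beam hardening, scatter, metal, contrast agent
or anatomical variability.  Results on it bound the algorithm's
geometric/topological behaviour (that is what the oracle and
failure-mode tests target); they do not certify clinical accuracy.

## Problem sizes and determinism

The test-suite and acceptance script run the full pipeline on 96³
phantoms (5 seeds × {default, osteoporosis}), a 30-case mixed cohort
at 64³, and kernel-oracle comparisons on 12³–20³ random instances
(100 region-growing, 60 box-filter, 50 hole-filling cases) — sizes
chosen so the whole suite completes in a few minutes on one CPU while
every mechanism is exercised at full fidelity; the pipeline itself is
resolution-independent.  All randomness is seeded: phantom noise from
`PhantomSpec@seed` (the generator saves and restores the caller's RNG
state), test/acceptance draws from fixed seeds.  Two runs on the same
inputs produce bit-identical label volumes.

## Known limitations

* Bones are not separated into anatomical instances (left/right
  femur, pelvis, sacrum); the output is bone vs marrow vs background.
* The 200/400 HU defaults presume successful intensity normalisation;
  for scanners with unusual calibration, supply a site reference
  histogram (`--reference`) or adjust the thresholds.
* Orientation matrices are carried through but never resampled;
  oblique acquisitions are segmented on their native grid.
* The 2D slice-wise fill exists only as a baseline: it fabricates
  marrow inside axially open canals and misses near-polar shell
  caps — the two errors the 3D fill avoids.
* A joint space narrower than twice the merge radius will be bridged
  and mislabelled as marrow (reproduced by the `kissing_joint`
  preset); lowering `mergeRadiusMM` trades this against unfilled
  foramina.
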