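# BoneSeg3D

Fully automated 3D segmentation of pelvic-region bones in CT volumes,
for workflows — such as model-based iterative reconstruction with
material decomposition, or the preparation of training labels for
learning-based segmenters — that need the *whole* bone labelled:
compact (cortical) bone **and** the enclosed trabecular/marrow
interior, kept as two distinct codes.

## The algorithm

Given a CT volume `V` (Hounsfield units), the pipeline runs five
stages:

1. **Histogram matching + table removal.** `V` is mapped through the
   monotone transform `m(v) = F_ref⁻¹(F_V(v))`, where `F_V` and
   `F_ref` are the body-restricted intensity CDFs of the input and of
   a reference volume (1-HU bins, piecewise-linear interpolation).
   This normalises acquisitions taken at different tube voltages.  The
   patient table is removed by keeping the largest 26-connected
   component above the air threshold (−500 HU) after a small skin
   closing.
2. **Dual-threshold segmentation.** `B = {v ≥ t_bone}` (default
   200 HU) captures most compact bone; `S = {v ≥ t_seed}` (default
   400 HU, `t_seed > t_bone`) marks high-confidence seed regions.
3. **Locally gated 3D region growing.** A copy of the volume is
   averaged with an `n×n×n` box filter (`n = 9`); the *local-maximum
   mask* `L` is 1 where the original voxel exceeds its neighbourhood
   mean.  Starting from `S`, growth proceeds through 26-connected
   neighbours that satisfy both `L = 1` and the acceptance range
   (default `[150, ∞)` HU).  Both criteria are precomputed, so the
   result is pure reachability — independent of traversal order.
4. **Combination.** `G ∪ B`, the union of grown and thresholded masks.
5. **Hole filling.** Nearby bone parts are merged by morphological
   closing with a spacing-aware ellipsoid of physical radius
   `merge_radius` (3 mm), then every background voxel that cannot
   reach the volume border through a 6-connected background path is
   labelled **2** (interior/marrow); mask voxels are labelled **1**.

Segmentation quality is quantified with the Dice similarity
coefficient `D = 2|A∩B| / (|A|+|B|)`.

Because clinical CT with expert ground truth cannot ship with a
package, BoneSeg3D includes a **synthetic pelvic phantom generator**
(`generatePhantom()`) producing body, muscle, two femurs, a pelvic
ring with acetabular cups, cortical foramina, a detached patient
table, partial-volume blur and noise — with exact voxel ground truth
— plus presets for the interesting failure regimes (osteoporosis,
kissing joint, perforated cortex, axially open canal).

## Worked example

```r
library(BoneSeg3D)

ph  <- generatePhantom(phantomSpec(seed = 7))   # 96³ voxels, 1 mm
lab <- runPipeline(ph$volume)                   # full five-stage run
#> histogram_matching: 884736 voxels mapped
#> table_removal: body = 502656 voxels
#> threshold_segmentation: bone = 49438, seed = 32294 voxels
#> local_maximum_mask: 287005 voxels
#> region_growing: 40803 voxels
#> combination: 49681 voxels
#> part_merging: 53379 voxels
#> hole_filling: bone = 53379, interior = 40354 voxels

diceCoefficient(lab, ph$truth, caseId = "default_seed7")
#>         case_id      dice n_truth n_pred n_intersection
#> 1 default_seed7 0.9072988   77829  93733          77829
```

The log shows the voxel count after each stage: thresholding finds
~49k compact-bone voxels, region growing contributes a few hundred
more through the union, closing merges nearby parts (+3.7k), and the
3D fill labels the 40k enclosed interior voxels as marrow.  The final
Dice of 0.907 against the known ground truth is dominated by the
partial-volume halo at the cortical surface, where the 200 HU
threshold sits well below the blurred bone/soft-tissue midpoint —
every true bone voxel is recovered (`n_intersection == n_truth`).

The same run from the shell:

```sh
boneseg3d phantom --preset default --seed 7 --out vol.nii.gz --truth gt.nii.gz
boneseg3d segment vol.nii.gz --out seg.nii.gz
boneseg3d evaluate --pred seg.nii.gz --truth gt.nii.gz
```

`segment` accepts NIfTI, MetaImage or a DICOM series directory, a
YAML config plus per-flag overrides for every pipeline parameter, a
`--holefill 2d` slice-wise baseline (to see why 3D filling is the
better idea) and `--binary` to collapse the two labels.

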