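---
title: "Automated quantification of TRAP-stained osteoclast cultures: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated quantification of TRAP-stained osteoclast cultures: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(osteoquant)
```

## The problem

In vitro osteoclastogenesis assays read out the differentiation of
monocyte-derived precursors into bone-resorbing osteoclasts. After TRAP
(tartrate-resistant acid phosphatase) staining, osteoclast-lineage cells
appear magenta/purple, and the standard endpoints are the number of
multinucleated TRAP+ cells and the culture area they cover. Manual tracing
of whole wells is slow (hours per well) and operator-dependent, which is
why the measurements are usually compared between annotators with Pearson
correlations over well regions rather than treated as exact.

`osteoquant` automates the readout with a single-shot object detector
trained at patch level. The package covers the full workflow: polygon
annotation I/O, training-set amplification from a handful of annotated
wells, detector training, tiled whole-well inference, count/area
quantification, and the per-region agreement statistics used to judge the
result against human annotators.

## Cell taxonomy

Four classes are distinguished, following the standard in vitro
convention that an osteoclast is a TRAP+ cell with at least 3 nuclei:

| class | nuclei | note |
|---|---|---|
| `preosteoclast` | 1–2 | TRAP+, not yet fused |
| `osteoclast_i` | 3–14 | classical osteoclast |
| `osteoclast_ii` | ≥ 15 | abnormal "giant" cell |
| `ghost` | — | vanished cell, visible only as a faint silhouette |

`classify_cell_type()` enforces the boundaries; nucleus counts on
annotations are validated against it. The 3/15 boundaries follow the
convention above; the package treats them as the definition, not a
tunable.

## Patch-level training

The central idea is that culture images, unlike natural images, keep
their semantics at any crop: a 10–15% window of a well is a perfectly
valid (and perfectly annotated) training image. `sample_random_patch()`
draws patch width and height independently and uniformly over the
admissible integer side lengths and positions; `count_patch_space()`
gives the exact number of distinct patches — about 2·10⁹ for a
1,000 × 1,000 well — which is what makes a ten-well training set
sufficient for a deep detector.

Ground-truth polygons are converted to the tightest square box containing
the cell (`tightest_square_bbox()`). We define the box on the pixel grid:
the side is the larger pixel extent of the polygon (`ceil(max) −
floor(min)` per axis), the square is centered on the extent and shifted —
never shrunk — to stay inside the image, and squareness yields to
containment only when the side exceeds an image dimension. The pixel-grid
definition keeps every box an integer-aligned, half-open pixel set, which
makes rasterized area bookkeeping exact; for fractional-coordinate
polygons it can be one pixel larger than the real-valued tightest square,
a deliberate trade.

Boxes clipped by a patch boundary are kept when at least 25% of their
area survives (`keep_threshold`). The rule avoids training on slivers of
cells while keeping most boundary cells; the original annotators faced
the same ambiguity at region boundaries.

Augmentation (`augmentation_config()`) applies photometric distortion
(brightness ±0.08, hue ±0.03 of the circle, saturation ×0.8–1.2), a
vertical flip with probability 0.5, and a rotation from
{0°, 90°, 180°, 270°}. Photometric changes never touch boxes; geometric
changes remap them exactly (property-tested against rotated masks).
Random streams are split per stage, so disabling augmentation does not
change which patches are sampled.

## The detector

The detector is a single-shot multibox network with **four** detection
heads. The classic six-head layout devotes its coarsest scales to objects
spanning most of the image; cells never do, so the coarsest heads are
removed and the four heads sit on the finest useful feature scales. In
the reference profile (input 300) the heads see 38², 19², 10² and 5² feature
maps; in the desk profile (input 128, five backbone blocks) they sit one
block earlier — 32², 16², 8², 4², finest stride 4 — because at the desk
pixel scale most cells are 8–35 px and a stride-8 anchor grid
under-matches them. Either way the anchor set covers physical cell sizes
from below 51 μm to above 383 μm at the documented pixel scale
(`anchor_size_range_um()` checks this as a property).

Anchors use aspect ratios {1, 2, ½} plus one extra square anchor at the
geometric mean of adjacent scales (4 per position). Boxes are encoded
against anchors with the standard center-offset / log-size
parameterization (variances 0.1/0.2). Matching is two-step: each ground
truth claims its best-IoU anchor, then every anchor with IoU ≥ 0.5 joins
its best ground truth. The loss is cross-entropy with hard negative
mining (3:1 negatives:positives, picked by confidence loss) plus
smooth-L1 localization, normalized by the positive count. None of these
choices is exotic; they are surfaced in `detector_config()` rather than
hard-coded.

Two named profiles exist:

* **reference** — input 300, VGG16-scale channels, 120,000 iterations, batch
  32, Adam, learning rate 10⁻⁵ (intended for a large pretrained
  backbone on real imagery).
* **desk** — input 128, a small randomly initialized backbone
  (8–32 channels over five 3×3 conv + ReLU + 2×2 max-pool blocks),
  2,000 iterations, batch 8, Adam, learning rate 10⁻³ stepped down
  tenfold for the final fifth, with weight averaging over the final
  tenth. This is the profile the tests and the acceptance script train
  on one CPU, in about ten minutes.

Convolutions run through im2col GEMM kernels (RcppArmadillo); training is
plain Adam with per-seed reproducibility, and a non-finite loss aborts
with a diagnostic rather than continuing silently.

## Whole-well inference

`detect_well()` tiles the well into a non-overlapping 8 × 8 grid (64
tiles, matching patch scale), runs `detect_patch()` per tile, translates
boxes by the tile origin and concatenates. There is **no cross-tile
merging by default**: cells split across tiles are a measured error mode
(`split_cell_audit()` reports the fraction of cells whose box touches a
tile boundary — about a quarter of cells at the default synthetic
geometry, though only a small minority of those yield confident
duplicate detections), duplicates can only inflate counts, and the
union-area endpoint is provably invariant to them. An optional `cross_tile_nms` flag exists for users who want
deduplication, but it is off: the naive union is the method under study.

### Operating-point calibration

Patch-level training has a structural side effect: the detector learns to
fire on partial cells, because clipped boxes (≥ 25% of their area inside
the patch) are legitimate training targets. At inference, a cell
straddling a tile boundary can therefore be detected once per tile, and
counts inflate; fragment detections carry systematically lower confidence
than whole-cell detections. `calibrate_confidence()` turns this into an
operating-point choice: after training, it runs tiled inference on the
*training* wells at a permissive confidence floor and, per class, picks
the threshold at which predicted whole-well counts best match the
annotated counts. No held-out data is involved — this is the standard
practice of selecting a detector's operating point on data whose labels
you already have. The thresholds are matched against *per-region* counts
(the statistic the agreement analyses report), which penalizes
compensating errors in different regions, and the candidate grid extends
low enough (0.12) that the optimum is interior rather than clipped. The
calibrated per-class thresholds ride along in the model configuration;
the scalar default (0.5) remains for uncalibrated models. The area
endpoint is union-based and never needed the correction.

## Quantification and agreement

Counts are exact per class and never pooled. Covered area is the **union**
of shapes, rasterized at native resolution with pixel-center membership —
the only semantics under which a double-boxed cell has no effect on the
area estimate. Annotation-side area uses the polygons; detection-side
area uses boxes; every report records which (`basis` column), since
box-based area is biased upward relative to polygon area and
model-vs-human area comparisons should state their basis.

Agreement mirrors the human evaluation protocol: the well is split into
regions (4 × 4 by default), one measurement per region per class
(`per_region_vector()`; cells are assigned by center so none is counted
twice; region areas are the union mask restricted to region rectangles
and therefore sum exactly to the whole-well union), and sources are
compared pairwise by Pearson correlation (`agreement_matrix()`). Regions
empty in every source are dropped, mirroring the practice of discarding
cell-free regions. `residual_normality()` implements the D'Agostino &
Pearson omnibus K² test (skewness and kurtosis z-transforms, χ² with
2 df) on the residuals of the least-squares fit, since no installed R
package provides it; it is calibrated by simulation in the tests and
cross-checked against an independent implementation on a frozen vector.

## The synthetic-culture generator

No public image set accompanies the assay, so `generate_well()` renders
annotated wells with exact ground truth. Design targets, in order: exact
bookkeeping (every rendered cell has its polygon, class and nucleus
count; internal tallies match `count_cells()`/`covered_area()` exactly),
plausible difficulty structure, and only then visual realism.

Defaults and what they emulate:

* 1,024 px wells at 6 μm/px — a ~6 mm culture well (a 96-well plate
  well) imaged at 4× magnification into a ~1,000 px frame. At this scale
  the 8 × 8 inference tiles are 128 px ≈ 770 μm, so a typical cell spans
  a tenth to a half of a tile and only giant type II cells approach tile
  size. Getting this ratio right matters: it is what keeps cells split
  across tiles a minor error mode (about a quarter of cells touch a
  boundary; confident duplicate detections are much rarer) rather than
  the dominant one.
* ~900 cells per well (Poisson), i.e. tens of cells per 4 × 4 region —
  the regime in which per-region correlations between annotators are a
  meaningful statistic. Cells are placed from a smooth random density
  field (a few Gaussian blobs over a base level,
  `density_heterogeneity`), because real cultures are spatially uneven —
  per-region counts in real cultures range from a handful to over a hundred —
  and per-region agreement needs that between-region variance to
  measure anything.
* Class mixture 35/35/10/20% (pre/I/II/ghost); nuclei uniform on 1–2,
  3–14, 15–40 per class.
* Diameters per class: 51–85, 90–200, 210–383, 70–180 μm — inside the
  51–383 μm detectable range, ordered by maturity.
* TRAP stain: magenta/purple hue (0.84–0.92 of the circle) with
  saturation increasing with maturity (0.30/0.50/0.65), per-pixel jitter,
  a darker rim, dark ~14 μm nuclei placed inside the cell body, one blur
  pass and additive noise over a pale background.
* Ghost cells get polygons but a near-background silhouette — they are
  genuinely hard, by design: low ghost-cell agreement is reproduced as a
  property of the data, not a defect of the detector.

Cells are smoothed random-star polygons (three radial harmonics on a
rotated ellipse), rescaled so the larger extent equals the drawn
diameter, placed largest-first by rejection sampling under a maximum
center-overlap constraint (a cell that cannot be placed after 150
attempts is skipped, so realized density can fall slightly below the
Poisson draw at hard settings).

What the generator does **not** model: focus gradients, vignetting,
staining debris, touching-cell fusion ambiguity, and real nucleus
texture. Passing tests on synthetic wells therefore demonstrate that the
pipeline's machinery is correct and that the detector can learn this
class of imagery end to end; they do not certify performance on any
particular microscope's output, which requires training on annotations
from that setting (the intended use of the package).

`generate_difficulty_suite()` varies only contrast (down), density and
overlap (up) to produce an easy→hard ladder for degradation studies.

## Scaled-down validation

The acceptance suite trains the desk profile on 10 synthetic wells
(2,000 iterations, batch 8 — about 10 minutes on one CPU), calibrates
the per-class operating thresholds on those training wells, and
evaluates tiled inference on 2 held-out wells, requiring per-region
Pearson r ≥ 0.9 for type-I counts and ≥ 0.75 for type-I area against
ground truth. The thresholds sit at the agreement level reported in the
osteoclast-quantification literature between such models and trained
human annotators (roughly 0.92–0.95 for counts, 0.77–0.88 for area) on
a deliberately easier, fully synthetic task; they are a regression gate
for the pipeline, not a claim about real data. Problem sizes throughout
the tests (well size, wells counts, iteration counts, replicate counts)
are chosen to keep the full suite in the tens of minutes on a single
CPU.

## Numerical choices and edge cases

* Coordinates are 0-based pixels, origin top-left, boxes half-open;
  stated once, used everywhere (annotation I/O, rasterization, tiling,
  detection).
* Rasterization is even-odd scanline filling at pixel centers; box and
  polygon area therefore share one membership convention.
* `pearson_r()` refuses zero-variance input (an explicit error, never a
  silent 0), and `residual_normality()` refuses n < 8 and degenerate
  perfect fits.
* Degenerate polygons (zero extent) get a 1 px box rather than an error:
  they occur as annotation slips and should surface downstream as
  obviously wrong sizes, not crashes.
* Remainder pixels of non-divisible grids go to the last row/column, so
  grids always partition the image exactly.
* All randomness flows from explicit seeds through one helper; training,
  sampling and generation are reproducible run-to-run to the bit.
* `pixel_scale_um` (μm per pixel) has no silent default at the CLI: it
  is instrument-specific and physical-size claims are meaningless
  without it.

## Known limitations

* The desk backbone is small; it learns the synthetic task and the
  training *mechanics* are identical to the reference profile, but real
  imagery needs the reference profile plus a pretrained backbone, which is
  out of scope here (no pretrained weights ship with the package).
* Counts are inflated by split cells at tile boundaries (no cross-tile
  merging by default, the naive union being the method under study); the audit
  quantifies it and the optional NMS flag mitigates it.
* Box-union area overestimates polygon-union area systematically;
  comparisons should stay within one basis.
* Ghost-cell detection is poor by construction of the task (near-zero
  contrast); treat ghost counts as indicative only.
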