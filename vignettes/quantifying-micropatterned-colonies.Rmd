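---
title: "Quantifying micropatterned stem-cell colony images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying micropatterned stem-cell colony images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mpcolony)
```

## The measurement problem

Human pluripotent stem cells confined to adhesive micropatterns and pushed
through a brief mesoendoderm induction followed by neural induction
self-organize into a layered, folding neuroepithelial tissue: a
mesoendodermal (Brachyury/T-positive) band forms at the colony edge, an
endodermal (SOX17-positive) band just inside it, and a SOX2-positive
prospective neuroepithelium occupies the interior, which then bends along a
circumferential folding axis a couple of hundred micrometres from the edge.
Reading this process out from multichannel immunofluorescence images
requires a chain of per-cell and per-tissue measurements: where each
nucleus is, how much of each marker it carries in the nucleus versus the
surrounding cytosol, how far it sits from the colony edge, which fate it
should be called, how marker intensity varies with edge distance, and how
round or folded the resulting tissue outline is.

`mpcolony` implements that chain as composable functions plus a synthetic
image generator that renders colonies with complete ground truth, so every
stage can be validated quantitatively without access to a microscope.

## Per-cell quantification model

**Segmentation.** The nuclei (DAPI) channel is processed by the classical
sequence: local contrast equalization (CLAHE), an adaptive Wiener noise
filter (local mean/variance shrinkage), a global Otsu threshold, binary
cleanup (disc opening, minimum-area filter, hole filling), and watershed
splitting of merged blobs, followed by labeling and moment-based ellipse
fits. Two deliberate refinements:

* *Watershed surface.* Distance-transform watershed alone cannot separate
  nuclei whose centroids sit at 1.2 nuclear radii: after thresholding, the
  merged blob's distance map has either no saddle or one much shallower
  than a pixel. The watershed therefore runs on the distance map plus a
  weighted normalized-intensity term (`watershed_intensity_weight`, default
  3 px per intensity unit); touching nuclei dim at their contact interface,
  which deepens exactly the saddle that needs cutting. Setting the weight
  to 0 recovers the pure distance watershed. The seed-suppression
  neighborhood (`watershed_ext`) defaults to 1 px: any larger and the
  weaker of two touching nuclei is swallowed by its neighbor's maximum.
* *Blank-image guard.* Otsu thresholding of a signal-free image happily
  splits noise into a percolating foreground. A guard requires the
  foreground/background mean separation (on the noise-filtered raw image,
  not the CLAHE output, which stretches empty-tile noise to full range) to
  exceed `guard_k` (default 3) background standard deviations; otherwise
  the image is declared background-only and an empty result is returned.

CLAHE helps when the colony fills the field of view, its usual situation.
For sparse preparations (colonies occupying a small fraction of the frame)
the equalization amplifies empty background and should be disabled
(`seg_params(clahe = FALSE)`); the package's own sparse benchmark fixtures
do so.

**Intensity sampling.** Each nucleus is sampled through a fixed-radius
binary disk at its centroid — 5 px, i.e. 3.12 µm at the default 0.624
µm/px calibration — averaging non-zero pixel values (`Nuc`). The cytosolic
estimate (`Cyt`) is the mean over the annulus obtained by dilating the
disk radius by a factor of 2 and subtracting the disk; annuli of
neighboring cells may overlap, by construction. The disk is rasterized at
the continuous centroid (pixel centers within the radius), not at a
quantized pixel, which removes an up-to-half-pixel alignment bias.

The `Nuc:Cyt` ratio is formed on background-subtracted values when
per-channel background statistics (median and MAD outside the colony mask)
are supplied: a shared additive offset would compress every ratio toward
1. Two geometric properties of the fixed-disk convention are worth knowing
when interpreting ratios on real data: if nuclei are larger than the disk,
the inner rim of the annulus lies inside the nucleus and inflates `Cyt`;
and in dense monolayers neighboring nuclei intrude into the annulus. Both
bias ratios toward 1. The package's ratio-recovery benchmarks therefore
use nuclei matched to the disk radius at moderate density, where the
annulus is a clean cytosol proxy; on dense tissue the ratio remains a
relative, not absolute, readout — which is how such profiles are used.

**Colony geometry and edge distance.** The colony mask is found by
smoothing the punctate nuclei channel at the nucleus-spacing scale
(default sigma 15 µm) into a plateau and thresholding halfway between the
background level (median over an image-border frame) and the plateau
(median over the Otsu foreground): the half-maximum crossing of a blurred
step sits on the true edge, making the outline unbiased to first order.
The boundary polygon is traced at subpixel contour level 0.5. Edge
distance is the minimum Euclidean distance from the centroid to that
polygon; cells outside get negative, flagged distances. Accuracy is
limited by boundary placement statistics: with ~300 nuclei per colony the
area estimate scatters by roughly ±3%, falling below 1% at full scale
(~3500 nuclei), which is where the package's 2%-accuracy checks run.

**Fate classification.** Cells are called SOX2+, T+ or SOX17+ by
winner-takes-all comparison of background-subtracted nuclear intensities:
the maximal marker wins if it exceeds the runner-up by a configurable
margin (default 1.2x) and an absolute floor (default 2 background MADs);
anything else is `unclassified`. Ties are unclassified by construction.
A count ratio with an empty numerator or denominator group is reported as
undefined (with the counts), never as 0 or infinity.

## Radial profiling

Per-cell statistics are regressed against edge distance with a
tricube-weighted local-linear smoother (`loess`, degree 1) and evaluated
on a fixed grid (default 5 µm step), so that colonies whose cells sit at
different positions can be averaged pointwise; pooling returns the
pointwise mean and standard error across replicates. The span (default
0.3) trades step sharpness against noise; within one span of a sharp
transition the smoother is biased by construction, so recovery checks
exclude that window. The smoother preserves constants exactly and is
shift-equivariant in intensity.

## Morphometrics

* **Circularity** is the standard shape factor `4*pi*A/P^2` on a closed
  simple contour — exactly `pi/4` for a square, 1 only for a circle;
  invariant to rotation, translation and scaling.
* **Gyration index** is contour perimeter over convex-hull perimeter, the
  planar gyrification convention: 1 for any convex outline, growing as
  the tissue folds.
* **Ring position** builds the radial intensity profile from the colony
  centroid and reports the innermost rising-edge half-maximum crossing
  over the equivalent radius; a profile already above half-max at the
  center has no rising edge and is flagged "no ring".
* **Cable angles** threshold the actomyosin (ppMLC) channel and decompose
  each connected component into straight segments by greedy extraction of
  the hull chord with the most collinear pixels (within about one cable
  width); this deterministic scheme also separates the arms of crossing
  cables, which defeat principal-component splitting. Segments of at
  least 10 µm are kept; each is measured against the local tangent of the
  circular folding axis at its midpoint azimuth, folded into [0, 90]
  degrees. The folding-axis offset is supplied from configuration
  (~200 µm from the edge at full scale) rather than detected. On mixed
  populations the recovered orthogonal fraction runs a few points below
  truth — crossing-decomposition artifacts — well within the package's
  stated ±10-point recovery band.
* **Apical/basal mitosis split** divides the cell layer at the
  mid-surface between the apical and basal boundaries and reports the
  percentage of PH3+ nuclei on each side (summing to 100%).
* **Wedge ratio** measures, per cell outline, the boundary length within
  a thin band (default 0.5 µm) of the basal surface over that within the
  band of the apical surface. Lateral membranes contribute about one band
  width per side to each surface, so the band must remain well below the
  apical/basal edge lengths; degenerate apices are capped at a
  configurable maximum and flagged; cells touching only one surface are
  excluded and counted.
* **Trilaminar map** overlays classified cross-section cells and fits a
  local-linear centerline through the reference (SOX2) layer; each fate's
  layer-order statistic is its mean signed offset from that centerline.
  The permutation test compares grand-mean-centered offsets against label
  shuffles (an exchangeability null) — note the middle layer of an evenly
  spaced stack sits near the grand mean and is correctly not flagged.

## Reporting statistics

Two groups are compared by a two-sided equal-variance Student's t-test
(Welch behind a switch); three or more by one-way ANOVA with Tukey-Kramer
pairwise comparisons honoring unequal group sizes. Groups are reported as
mean ± sem; zero-variance inputs are flagged degenerate rather than
erroring. The ECDF colormap transform maps values to average-rank ECDF
positions scaled to (0, 1], giving equal color separation between data
points regardless of their numeric spacing; it depends only on ranks and
so is invariant under any strictly increasing transform. For matrices the
scope (global, per-row, per-column) is a switch, defaulting to global.

## The synthetic colony generator

`generate_colony()` renders what the pipeline is meant to measure:

* Geometry: circle, square, triangle, rectangle or annulus sized to the
  area of a circle of the stated equivalent diameter (default 1000 µm),
  with nuclei placed by rejection sampling at 4444 cells/mm² and a
  minimum centroid separation of two nuclear radii. A stated fraction of
  nuclei is placed as touching pairs at 1.2 radii — guaranteed merged
  blobs for watershed testing. Infeasible packings fail with an error
  naming the density and separation.
* Fate zones: radial bands measured from the colony edge, defaulting to a
  T band within 50 µm, a SOX17 band at 50–100 µm and SOX2 inside.
* Rendering: nuclei are Gaussian blobs (sigma = radius/2) truncated at
  the nuclear outline, combined per-pixel by maximum so touching nuclei
  keep an intensity neck at the interface (summation would make the
  bridge brighter than either peak — unsplittable by any thresholding
  chain). Marker channels are painted flat: each nucleus carries its
  zone's stated nuclear intensity exactly, the surrounding cytosol that
  intensity divided by the marker's Nuc:Cyt ratio; this makes mean
  nuclear recovery exact before noise, a property the tests assert
  literally. Nuclear stain may overhang the pattern edge slightly, as in
  real images; cytosol is confined to the pattern.
* Cables: line segments of stated lengths in a radial band (default
  40 µm) about the circular folding axis, at angles drawn from a stated
  population realized as exact counts (a 70/30 mixture is 70 and 30
  cables), with optional angular jitter. The band prevents distinct
  tangential cables from collinearly merging into arcs.
* Noise: the standard fluorescence stack — Poisson shot noise, additive
  background, Gaussian read noise, linear illumination gradient — each
  term independently switchable. `noise_snr(s)` fixes the ratio of
  nuclear amplitude to Gaussian sd and sets the background three noise
  standard deviations above zero, as camera offsets do; with background
  below the noise floor, zero-clamping combined with the non-zero-pixel
  averaging rule would inflate dim-region means.
* Determinism: identical spec and seed give bit-identical images and
  ground truth, and the generator restores the caller's RNG state.

`generate_cross_section()` renders the side view of one cell layer:
trapezoidal cells whose basal:apical width ratio equals the wedge
parameter inside the hinge region (flanks absorb the excess so both
surfaces span the section), elongated nuclei with region-specific aspect
ratios, and mitotic nuclei placed apically with a stated bias. Ground
truth carries the exact cell polygons, surfaces and flags.

What the generator does not emulate: real chromatin texture, intensity
variation within nuclei, out-of-focus light, segmentation-relevant debris,
or any mechanics of folding (it paints outcomes in 2D; there is no
volumetric rendering). Passing the recovery tests therefore shows the
measurement chain is correct and calibrated on images with known answers,
not that segmentation accuracy on any particular real dataset will match.

## Problem sizes and numerical choices

The validation suite runs colonies of ~200 nuclei (equal-area diameter
239 µm at 4444 cells/mm²) for segmentation/classification benchmarks, five
replicates for profile pooling, full-scale 1000 µm colonies (~3500 nuclei)
for the geometry-accuracy checks, and 600 µm colonies for cable recovery;
statistical calibration uses 1000 simulated datasets per test. Tabular
output is CSV with 17-significant-digit floats (exact IEEE round-trip);
images are 16-bit TIFF with per-channel scale, pixel size and channel
names in a JSON sidecar, making write–read–write cycles byte-identical.
All distances are exported in micrometres; pixels are 0-based with x
rightward and y downward.
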