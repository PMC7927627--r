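# mpcolony

Quantitative image analysis of micropatterned human pluripotent stem-cell
colonies differentiating toward neuroepithelium.

When hPSC colonies confined to geometric adhesive islands receive a brief
mesoendoderm induction before neural induction, they self-organize into a
layered, folding tissue: a Brachyury (T)⁺ mesoendodermal band at the colony
edge, a SOX17⁺ endodermal band just inside it, and a SOX2⁺ prospective
neuroepithelium in the interior that bends along a circumferential folding
axis. `mpcolony` turns multichannel immunofluorescence images of such
colonies into numbers, for researchers using micropatterned colonies as
models of neural-tube morphogenesis or as screening substrates for
neurodevelopmental toxicity.

## What it computes

Per cell, for every nucleus found by the classical segmentation chain
(contrast equalization → adaptive Wiener filter → Otsu threshold → binary
cleanup → distance-plus-intensity watershed):

- nuclear mean intensity **Nuc** over a fixed disk (5 px = 3.12 µm at
  0.624 µm/px) at the centroid, averaging non-zero pixels;
- cytosolic mean intensity **Cyt** over the annulus from dilating the disk
  radius ×2 and subtracting the disk, and the ratio **Nuc:Cyt** on
  background-subtracted values;
- distance from the colony periphery, and a fate call (SOX2⁺/T⁺/SOX17⁺ or
  unclassified) by winner-takes-all marker comparison with a 1.2× margin.

Per colony or tissue:

- radial marker profiles (tricube local-linear smoothing of per-cell
  statistics against edge distance on a fixed grid, poolable across
  replicates);
- circularity `4πA/P²`; gyration index `P/P(convex hull)` (1 = unfolded);
- annular ring position (innermost half-max rising edge of the radial
  profile over the colony radius);
- actomyosin cable segments ≥ 10 µm and their angles to the folding-axis
  tangent, folded into [0°, 90°];
- apical vs basal percentages of mitotic (PH3⁺) nuclei; basal:apical
  (wedge) cell-length ratios; trilaminar localization maps with a
  layer-order statistic and permutation test;
- Student's t / one-way ANOVA + Tukey–Kramer group comparisons, and the
  rank-based ECDF colormap transform for expression heatmaps.

A synthetic colony generator (`generate_colony()`,
`generate_cross_section()`) renders all of the above with complete ground
truth — geometry, fate zones at 50/100 µm from the edge, seeding density
4444 cells/mm², Nuc:Cyt ratios, oriented cables, realistic noise — so the
whole chain is validated against known answers.

## Worked example

```r
library(mpcolony)

spec <- colony_spec(equivalent_diameter = 239, cell_density = 4444,
                    noise = noise_snr(5), seed = 7)
sim  <- generate_colony(spec)

seg   <- segment_nuclei(sim$image)
geom  <- detect_colony(sim$image)
bg    <- background_stats(sim$image, geom)
cells <- sample_cell_intensities(sim$image, seg$records, background = bg)
cells <- edge_distances(cells, geom)
cells <- classify_fate(cells, background = bg)

geom
#> <colony_geometry> area 4.345e+04 µm², equivalent radius 117.6 µm
nrow(seg$records)            # ground truth: 199
#> [1] 199
table(cells$fate)
#>         SOX2            T        SOX17 unclassified
#>            7          131           61            0
fate_count_ratio(cells, "T", "SOX2")$ratio
#> [1] 18.71429
```

All 199 nuclei are recovered and every fate call matches its ground-truth
zone. T⁺ cells dominate because the fixed 50 µm edge band covers most of
this small test colony — the size dependence that makes smaller colonies
fold more strongly. The radial profile of nuclear T intensity shows the
edge band as a plateau (~150 counts over a ~90-count background) dropping
to background past the 50 µm zone boundary:

```r
profile_colony(cells, "T", "nuclear", grid_max = 100)[c(1, 11, 21), ]
#>    distance     mean      sem  n
#> 1         0 238.8830 9.118535 46
#> 11       50 135.9555 4.128936 60
#> 21      100 102.2405 9.721516 10
```

Shape metrics come from the detected outline:

```r
ct <- tissue_contour(geom$boundary_polygon, check_simple = FALSE)
circularity(ct)      #> 0.871
gyration_index(ct)   #> 1.038
```

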