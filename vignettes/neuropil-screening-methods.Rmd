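---
title: "Screening hippocampal ISH images for neuropil-enriched transcripts"
author: "neuropilScreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening hippocampal ISH images for neuropil-enriched transcripts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neuropilScreen)
```

## The problem

Most mRNAs stay near the neuronal cell body, but a functionally important
minority is transported into dendrites and translated locally at synapses. In
colorimetric in situ hybridization (ISH) images of the hippocampus these
transcripts show a characteristic signature: besides the dense dark staining
of the cell-body layers — the stratum pyramidale (sp) of Ammon's horn (AH) and
the stratum granulosum (sg) of the dentate gyrus (DG) — they produce punctate
signal in the adjacent *neuropil*, the dendrite- and axon-rich tissue flanking
those layers. `neuropilScreen` implements an image-screening pipeline that
turns this visual signature into a quantitative ranking: it localizes the AH
and DG in a section, partitions them into 13 canonical sub-regions, describes
each section by a 220-dimensional texture vector, learns a discriminative
feature subset from a small labeled training set (3 positive prototypes, 17
negatives), and ranks candidate genes by the Pearson correlation of their
selected features to the positives' prototype vector.

Everything is exercised on synthetic sections with known ground truth, so the
whole chain is testable without any external image corpus.

## Synthetic sections

`generateSection()` renders one parasagittal-like section: two non-intersecting
elliptical arcs (the sp and sg band midlines), a solid base darkening plus a
Poisson point process of dark Gaussian puncta inside the bands (density
`soma_density` per 100 px²), and puncta at density `e * soma_density` in a
neuropil margin flanking each band, on a light noisy background. The planted
enrichment `e` is the dimensionless quantity the screen must recover.

Defaults (chosen once as a realistic regime and left alone): 200 × 280 px
sections, 6 px band width, `soma_density = 8`, puncta radius 1.6 px, background
220, noise SD 6, band base darkening 90, puncta amplitude 140. The training
cohort plants `e` in [1.2, 1.6] for positives and [0, 0.3] for negatives
(disjoint by construction, mirroring the 3/17 training design); the graded
screen spaces `e` evenly over [0, 2].

Three generator decisions matter for testability and are deliberate:

* **Bands are solid, not purely punctate.** Real sp/sg layers are near-uniformly
  dark; a base darkening under the puncta reproduces that, and it is what makes
  "band pixels are Otsu foreground" a meaningful property.
* **A guard gap of `ceiling(puncta_radius) + 1` px separates band and margin**,
  so no band punctum can bleed into the margin: a zero-enrichment margin is
  *exactly* background before noise, which gives the generator an exact
  invariant instead of an approximate one.
* **Margin puncta counts are coupled across `e`** (`qpois` of one fixed
  uniform, positions drawn from a per-structure stream with a prefix
  property): raising `e` under a fixed seed only *adds* puncta, so margin
  darkness is provably monotone in `e` — a property independent Poisson draws
  would only satisfy on average.

What the generator does **not** emulate: real stain variability, section
artifacts (tears, bubbles, uneven illumination), anatomical detail beyond the
two bands, or 3-D effects. Passing tests therefore demonstrate the machinery
is correct and recovers planted structure; they do not certify accuracy on
atlas imagery.

## Localization

`preprocessRoi()` applies the enhancement chain: optional median/IQR intensity
normalization against pooled training ROIs, CLAHE, saturation of the darkest
and brightest 1% of intensities, then Otsu binarization (dark class) keeping
the five largest connected components (size ties broken by raster order).
The 1% saturation tail is a fixed default of this package.

The deformable model is a point-distribution model in the Active Shape Model
tradition: 15 landmarks (8 AH + 7 DG), mean shape plus principal-component
deformation modes learned from training shapes (ground-truth shapes of the
synthetic cohort), coefficients bounded at ±3 SD. The fit optimizes pose
(translation, rotation ±0.3 rad, isotropic scale 0.75–1.3) plus mode
coefficients with Differential Evolution — DE/target-to-best/1, uniform
crossover rate 0.9, F = 0.7, 64 individuals, 200 generations, synchronous
generational update — against the energy

> E = −(mean inverted intensity along the model polylines) − λ · (fraction of
> polyline samples inside the binary foreground), λ = 1, lower is better,

with polylines sampled at six evenly spaced steps per segment (approximately
equidistant in arc length for near-equidistant control points) and
out-of-image samples taking the worst value of both terms. The energy form is
this package's choice: both terms are computable from the preprocessing
outputs and both attract the polyline to the dark, foreground-dense cell-body
bands. On noise-free synthetic sections the fitted control points land about
1–2 px from the true band midlines, well inside the 6 px band.

Atlas-slice selection (`registerToAtlas()`) is a two-step affine registration:
a Levenberg–Marquardt least-squares refinement of a 6-parameter affine on
intensity residuals per slice, then PSO refinement (24 particles, 40
iterations, c1 = c2 = 2.05, inertia 1.0 → 0.1) of the best candidates on
normalized cross-correlation, both on lightly smoothed images. The similarity
metric and the NCC ≥ 0.5 acceptance floor are declared defaults — the fallback
to slice retry, not inferred from any source.

## Segmentation and quality control

`selectAreas()` centers square boxes on the maximum-curvature locus of each
half of the AH chain (the CA1 and CA3 bends; the locus is the
curvature-weighted centroid of that half's interior points, robust when
discrete turn angles are nearly tied along a smooth bend) and on the midpoint
of the medial half of the DG polyline. Box sides are proportional to the mean
control-point spacing (1.5× for the AH boxes, 2.8× for the shorter-segment DG
chain so the box still holds band, strips and the largest 36 px window), so
the construction is scale-equivariant. Collinear chains fall back to near-end
points with a flag.

`partitionRegions()` Otsu-segments each box, takes the largest dark component
as the band, and splits geometry along the band's principal axis: "a" is the
central half along the axis, "b"/"c" the lateral quarters, "d" (and "e" on the
far side, DG only) the neuropil strips from just beyond the band boundary
(98th percentile of the perpendicular spread, +1 px) to one band-width further
out. The exact split rules are geometric conventions of this package,
consistent with the window sizes the descriptor uses per region (neuropil
windows 14/28, band cores 18/36, flanks 24). Pixels are assigned to at most
one region, so the 13 masks are disjoint by construction; any empty region
fails the segmentation.

QC is two random forests (100 trees each, seeded): a pixel classifier
(intensity plus 9 × 9 local mean/SD/entropy — a declared default feature set)
trained to distinguish in-band from out-of-band pixels, and an accept/reject
forest fed the accuracy of 12 random points per probed region (CA1a, CA1d,
CA3a, CA3d, DGa, DGd — 72 points, sampled uniformly over the region mask, a
declared choice) plus area and intensity-SD summaries. Reject training
examples are manufactured by shifting good segmentations three band-widths off
the bands. `processSeries()` tries atlas level 145 first and then alternates
−1/+1 outward through the levels present in [117, 175], discarding the gene
when every slice fails.

## Texture descriptor

Per region and window size, windows tile the region's bounding box from its
top-left corner; windows at least 50% inside the mask are kept (fallbacks: the
single best-covered window, or one window centered on the centroid for regions
smaller than the window in both dimensions — both flagged). Eleven features
per window, averaged across kept windows:

* First order, on raw 8-bit intensities: mean, SD, coefficient of variation,
  population skewness and kurtosis, and energy/entropy of the 16-bin
  normalized intensity histogram (entropy in bits). Computing energy/entropy
  on the histogram rather than raw squared intensities keeps both bounded and
  mirrors the GLCM level count; it is a declared default.
* Second order: the gray-level co-occurrence matrix at 16 uniform levels
  (level = ⌊v/16⌋), pooled over the four unit-distance directions with both
  pair orders counted ("symmetric and non-directional"), normalized, then
  contrast, correlation, energy and homogeneity in their standard Haralick
  forms.

Degenerate windows use fixed conventions (cv, skewness, kurtosis, GLCM
correlation → 0) so blank regions produce finite vectors. The window map —
"a" regions and DGe at 18/36, "b"/"c" at 24, "d" at 14/28 — gives 20 (region, window)
pairs × 11 features = 220 named values in a fixed canonical order.

## Feature selection and ranking

Features correlated above |r| > 0.99 across the 20 training sections are
collapsed greedily in canonical order (zero-variance features all map to the
first such column). A binary GA — population 50, 300 generations, one-point
crossover 0.8, per-bit mutation 0.06, tournament size 4, keep-1 elitism —
maximizes the mean silhouette of positives vs negatives, s = (b − a)/max(a, b),
with Euclidean distances over z-scored selected features; z-scoring is this
package's choice (the features live on wildly different scales, and the
downstream Pearson ranking is itself scale-free, so standardization keeps the
two consistent). The crossover/mutation/elitism operators are canonical
simple-GA defaults, all seeded. Fifteen runs with derived seeds vote; features
selected in ≥ 8 of 15 runs form the consensus (an empty consensus falls back
to the maximal-frequency features, flagged).

The prototype is the mean z-scored selected-feature vector of the positives.
Screened probes are standardized with the training parameters and scored by
Pearson r against the prototype; rows sort by r descending with probe-id tie
break, and the r ≥ 0.8 / r ≥ 0.7 candidate cut lines are reported as columns,
not hard-coded filters. Before scoring, probes whose reported hippocampal
expression level *or* density is not strictly above 20 are excluded.
`stabilityProfile()` summarizes per-gene r across sections from nearby atlas
levels (min/median/max/IQR) to expose sections that would produce false
negatives.

## Numerical and design notes

* Coordinates are 1-based (row, col) with closed boxes, the R convention.
* All stochastic stages consume seeds derived from one master seed
  (`deriveSeed()`, a 31-bit integer hash), so `runPipeline()` is reproducible
  byte for byte; re-running with the same seed rewrites identical TSVs.
* Otsu thresholding is computed from the cumulative histogram and is tested
  against an exhaustive 256-threshold search; the dark class is always the
  foreground (ISH signal is dark).
* Problem sizes used by the test suite and the acceptance script — 20-section
  training cohorts, a 30-gene graded screen, 20 noise-free sections for
  localization recovery, 100–200 random oracle windows — are the package's
  validation design.
* The qPCR helper implements 2^−ΔCt with a reference gene, mean ± sample-SD
  replicate aggregation (the published tables print mean ± spread), and strict
  propagation of not-detected values (never coerced to 0).

## Known limitations

* The energy functional and the region-split geometry are principled but not
  canonical; on real atlas images both would need re-validation, and the QC
  forests would need retraining on expert-labeled segmentations.
* The synthetic screen saturates at high enrichment (dense margins stop
  getting darker per added punctum), which compresses rank differences among
  the strongest positives.
* Registration assumes modest affine misalignment; it is not a substitute for
  full brain-wide registration.
* Multiple probes per gene are treated as independent rows throughout.
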