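# neuropilScreen

Texture-based screening of hippocampal in situ hybridization (ISH) images for
**neuropil-enriched transcripts** — mRNAs that are transported into dendrites
and translated near synapses instead of staying in the neuronal cell body.

In colorimetric ISH sections such transcripts show a recognizable signature:
besides the dense dark staining of the cell-body layers (stratum pyramidale of
Ammon's horn, AH; stratum granulosum of the dentate gyrus, DG), they produce
punctate signal in the adjacent neuropil. `neuropilScreen` turns that
signature into a quantitative, reproducible ranking:

1. **Localization** — an Active-Shape-Model-style deformable model
   (8 AH + 7 DG control points) is fitted to each preprocessed section
   (CLAHE, 1% saturation, Otsu binarization keeping the 5 largest components)
   by Differential Evolution (DE/target-to-best/1, CR 0.9, F 0.7, 64
   individuals, 200 generations), minimizing an energy that attracts the model
   polylines to dark, foreground-dense pixels. A two-step affine registration
   (Levenberg–Marquardt, then particle-swarm refinement with 24 particles, 40
   iterations, c1 = c2 = 2.05, inertia 1.0 → 0.1) matches sections to a
   reference atlas (levels 117–175, default 145 with outward retry).
2. **Segmentation** — the CA1, CA3 and DG areas are Otsu-segmented and split
   into 13 named regions (CA1a–d, CA3a–d, DGa–e: band cores, band flanks, and
   flanking neuropil strips); a two-stage random-forest QC (12 probe points in
   each of 6 regions, then region statistics) accepts or rejects each
   segmentation, with slice retry and gene discard.
3. **Texture** — each region is tiled with windows (sizes 18/36, 24 or 14/28
   by region) and described by 7 first-order statistics plus 4 gray-level
   co-occurrence (GLCM, 16 levels, symmetric non-directional) features,
   averaged per region: a **220-dimensional named descriptor** per section.
4. **Feature selection** — features with |r| > 0.99 across the 20-section
   training set (3 positive prototypes, 17 negatives) are collapsed; a binary
   genetic algorithm (population 50, 300 generations, crossover 0.8, mutation
   0.06, tournament 4) maximizes the silhouette index s = (b − a)/max(a, b)
   between groups; features selected in ≥ 8 of 15 runs form the consensus.
5. **Ranking** — candidate genes passing the expression pre-filter (level or
   density > 20) are scored by Pearson correlation between their selected,
   z-scored features and the prototype vector (mean of the positives), with
   the r ≥ 0.8 and r ≥ 0.7 candidate cut lines reported.

A synthetic ISH-section generator with full ground truth (known band geometry,
planted neuropil enrichment `e` = neuropil/band puncta density ratio) makes the
whole chain testable end to end, and a small qPCR helper implements 2^−ΔCt
quantification with synaptosome/total-brain enrichment ratios for candidate
validation.

## Worked example

```r
library(neuropilScreen)

res <- runPipeline(pipelineConfig(
  seed = 42, n_train_pos = 3, n_train_neg = 7, n_screen = 8,
  ga = gaParams(generations = 120, runs = 7, seed = 42)))
cat(res$log, sep = "\n")
head(res$ranking, 8)
```

```
master seed: 42
simulated 10 training and 8 screen sections
shape model: 4 mode(s); QC forests trained
screen gene008 discarded: empty region after partition
features: 10 train x 220, 7 screen
dedup: 161 of 220 features kept (|r| > 0.99 collapsed)
consensus: 58 features selected in >= 4 of 7 runs
expression filter (>20): 7 of 7 probes retained

    gene   probe atlas_level      r rank pass_0.8 pass_0.7
 gene006 gene006         145  0.950    1     TRUE     TRUE
 gene005 gene005         145  0.892    2     TRUE     TRUE
 gene007 gene007         145  0.874    3     TRUE     TRUE
 gene003 gene003         145  0.757    4    FALSE     TRUE
 gene004 gene004         145  0.742    5    FALSE     TRUE
 gene002 gene002         145 -0.115    6    FALSE    FALSE
 gene001 gene001         145 -0.826    7    FALSE    FALSE
```

The screen plants enrichment evenly over e ∈ [0, 2] in genes 001…008, so the
ranking should (and does) follow the planted order: high-e genes score close
to the prototype (r ≥ 0.87, passing the 0.8 cut line), the e ≈ 0 genes score
negatively. The Spearman correlation between planted e and the output r in
this run is 0.86. One section was discarded by segmentation QC with a logged
reason — the same retry/discard policy applied to real image series. Every
number above is reproducible byte for byte from `seed = 42`.

The qPCR helper, for candidate validation tables:

```r
enrichmentRatio(c(16.72, 5.23, 8.46), c(17.21, 3.83, 13.71))$rounded
#> [1] 0.97 1.37 0.62
```

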