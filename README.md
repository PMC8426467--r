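# histotile

Headless, scriptable pre-processing of histology image tiles for deep
learning, plus the evaluation layer that turns per-tile CNN probabilities
into region-of-interest (ROI) and patient-level calls.

## The problem

Patch-based CNNs for histopathology — here, classifying tumour stroma as
**mature** (fine, parallel collagen fibres) or **immature** (disorganised
fibres, oedema) on H&E tiles — are only as good as their input image sets.
Before any training happens, a typical workflow must:

- cut annotated regions into fixed-size tiles (e.g. 250×250 px) with
  traceable, coordinate-stamped names;
- drop tiles that are mostly unstained background ("whitespace"), using a
  binary tissue mask and a minimum-coverage cutoff;
- balance class sizes, creating new examples by the 7 non-identity
  symmetries of the square (dihedral group D4: rotations and mirrored
  rotations) rather than duplicating images;
- normalise staining batch effects by matching each tile's per-channel
  cumulative intensity histogram to one fixed target image;
- optionally accentuate structure with pixel-level operators such as
  embossing.

After training, per-tile probabilities must be aggregated: tile → ROI →
patient by majority voting, with evaluation via confusion matrices,
precision/recall/F1, rank-based ROC AUC, exact binomial confidence
intervals, and Fleiss' κ for multi-rater concordance.

`histotile` implements all of this as a tidyverse-style R package: dataset
indexes, coverage tables, plans and reports are tibbles that chain with the
pipe; fitted evaluation objects have `tidy()`/`glance()` methods and
`autoplot()` figures; every mutating operation writes a JSON manifest so
any derived image can be traced to its source.

## The core rules, precisely

- **Tissue masks.** A gray pixel `v` is tissue iff `v < T` (fixed `T`,
  default 220 — H&E background is bright). Otsu's variant picks `T`
  maximising the between-class variance `w0·w1·(mu0 − mu1)^2` over all 256
  thresholds; the adaptive variant compares each pixel with its
  `block×block` local mean minus an offset. Coverage is the exact tissue
  fraction; tiles with coverage strictly below the cutoff are removed,
  boundary tiles kept.
- **Balancing.** Augmentation modes require the *one-eighth rule*: no class
  may hold fewer than 1/8 of the largest class's tiles (each source has
  only 7 distinct dihedral images, so larger deficits would force
  duplicates). `{800, 100}` passes — the bound is inclusive; `{900, 100}`
  fails. Sources are drawn in rounds of sampling without replacement,
  transforms without repetition per source, so no `(source, transform)`
  pair is ever used twice.
- **Histogram matching.** Each source value maps to
  `m(v) = min{ u : F_target(u) ≥ F_source(v) }` per channel: monotone,
  rank-preserving, deterministic. Single-channel tiles are promoted to RGB
  first.
- **Emboss.** Channels are convolved with
  `K = (1−α)·E + α·M(s)`, `M(s) = [[−1−s, −s, 0], [−s, 1, s], [0, s, 1+s]]`
  (reflective borders, clipped to 8 bits). `M(s)` sums to 1, so constant
  tiles are fixed points; the default `s = 2, α = 1`.
- **Voting.** A tile is called immature iff `P(immature) ≥ 0.5` (inclusive
  boundary). ROIs take the majority of their tiles, patients the majority
  of their ROIs; an exact tie resolves to **mature** at both levels
  (configurable).

## Worked example

```r
library(histotile)

# a fully synthetic dataset: 4 patients x 2 ROIs x 5 tiles,
# mature = parallel-fibre texture, immature = disorganised
idx <- build_dataset(file.path(tempdir(), "demo"), n_patients = 4,
                     rois_per_patient = 2, tiles_per_roi = 5,
                     tile_size = 64, seed = 42)
class_counts(idx)
#> # A tibble: 2 × 2
#>   class_label     n
#>   <chr>       <int>
#> 1 immature       20
#> 2 mature         20

# tissue coverage of one tile under an Otsu mask
read_tile(idx$path[1]) |> to_grayscale() |> binary_mask_otsu() |> tissue_coverage()
#> # A tibble: 1 × 5
#>   coverage n_tissue n_total method threshold_used
#>      <dbl>    <int>   <int> <chr>           <int>
#> 1    0.845     3463    4096 otsu              158
```

The Otsu scan put the threshold at gray level 158 and 84.5% of pixels fall
below it — a tissue-rich tile that would survive any sensible whitespace
cutoff.

Aggregating a table of per-tile CNN probabilities (2 patients, 2 ROIs
each, 3 tiles per ROI):

```r
agg <- aggregate_predictions(predictions)   # columns: patient_id, roi_id,
glance(agg)                                 #   tile_id, true_label, prob_immature
#> # A tibble: 3 × 11
#>   level      tn    fp    tp    fn total accuracy precision recall    f1
#> 1 tile        5     1     5     1    12    0.833     0.833  0.833 0.833
#> 2 roi         2     0     2     0     4    1         1      1     1
#> 3 patient     1     0     1     0     2    1         1      1     1

roc_auc(agg$tile$true_label, agg$tile$prob_immature)
#> [1] 0.9166667
exact_binomial_ci(11, 13)   # e.g. a patient-level sensitivity of 11/13
#> # A tibble: 1 × 4
#>   estimate   low  high level
#> 1    0.846 0.546 0.981  0.95
```

Two tiles are misclassified at the tile level, but majority voting heals
both at ROI level and the patients are called perfectly; the Clopper–
Pearson interval shows how wide patient-level certainty really is at
n = 13.

A shell entry point mirrors the library (see `exec/histotile`):

```sh
histotile simulate --out tiles --patients 4 --rois 2 --tiles 5 --seed 1
histotile patch --src tiles --dst patched --size 250
histotile threshold --src patched --method fixed --min-coverage 0.8 --action relocate --relocate-dir removed
histotile balance --src patched --mode to-max --seed 7
histotile normalise --src patched --target target.png --dst normalised
histotile aggregate --predictions preds.csv --out metrics/
```

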