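---
title: "Methods: tile pre-processing, balancing, normalisation and aggregation in histotile"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tile pre-processing, balancing, normalisation and aggregation in histotile}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(histotile)
```

`histotile` prepares haematoxylin-and-eosin (H&E) image tiles for
convolutional neural network training and aggregates per-tile predictions
to region-of-interest (ROI) and patient level. This vignette is the
package's account of the procedures it implements, the parameters that
matter, and the choices made where more than one reasonable design exists.

## The unit of work

Everything operates on 8-bit tiles (`tile_image`): integer arrays in
[0, 255], one or three channels, carrying their source path. The working
geometry throughout is 250×250 px — large enough to capture stromal fibre
architecture, small enough for large training batches — but every function
accepts arbitrary sizes. Datasets live on disk as
`root/<class>/<patient>[/<roi>]/<tile>.png`; whole patients belong to
exactly one of train/test/validation so that a model can never "recognise"
a patient across splits. `split_by_patient()` gives test and validation
`floor(fraction × n_patients)` patients each and the remainder to train
(70/15/15 over 20 patients → 14/3/3): training is never starved by
rounding.

Every mutating operation writes a JSON manifest (operation, parameters,
effective seed, one action per file) beside its output root. The
convention exists because traceability claims are empty unless some
machine-readable record backs them; the format is this package's own.

## Patching

Tiles are cut on a grid anchored at the top-left pixel, stride defaulting
to the patch size (non-overlapping), partial edge tiles dropped. Dropping
rather than padding is deliberate: a CNN needs whole, consistent tiles,
and padding invents pixels that a whitespace filter would then have to
reason about. Patch names append 0-based grid coordinates
(`stem_r2_c5`), an injective mapping, so a stitched reconstruction of the
source is always possible — and is tested bit-exactly.

## Tissue thresholding

Masks call a pixel tissue iff it is *darker* than a reference: stained
tissue absorbs, unstained background transmits. Three references are
available:

- **fixed** (default `T = 220`): typical H&E background exceeds 220; the
  value is exposed because staining intensity varies between labs;
- **Otsu**: `T` maximises between-class variance `w0·w1·(mu0 − mu1)^2`
  over all integer thresholds, ties broken toward the lowest threshold;
  constant images are rejected as degenerate;
- **adaptive** (`block = 51`, `offset = 10`, reflective borders): pixel
  vs. local mean minus offset, for unevenly illuminated tiles. A 51-px
  window is about a fifth of a standard tile: wide enough to straddle
  fibres, narrow enough to track illumination.

Coverage is the exact tissue fraction of the mask. Filtering removes
tiles with coverage *strictly below* the cutoff; a tile at exactly the
cutoff survives. The inclusive boundary is a choice (either convention is
defensible); it is frozen here and tested so downstream counts are
reproducible.

## Class balancing

Only augmentation — never interpolation — creates new images: the 7
non-identity symmetries of the square (three clockwise rotations, a
left-right mirror, and the mirror followed by each rotation). These
permute pixels exactly, so no gray value is invented. The group structure
(closure, inverses) is verified bit-exactly in the tests.

Balancing modes equalise to the largest class (`to_max`), smallest
(`to_min`), or the rounded mean (`to_mean`, rounding half up for platform
determinism; classes above the target reduce, classes below augment —
reducing the over-sized classes keeps the result an actual equalisation
rather than only a partial one). Augmentation planning enforces the
*one-eighth rule*: no class below 1/8 of the largest, inclusive at the
boundary, because 7 distinct transforms per source bound the achievable
duplicate-free growth at 8×. Deficits are filled in rounds of sampling
sources without replacement, each selected source drawing a transform it
has not used; at most 7 rounds are ever needed, and no
`(source, transform)` pair repeats — checked exhaustively for every
deficit up to 7× the class size. Removals relocate to a
`Removed Images/` directory by default (hard delete is opt-in).

Seeding: balancing accepts an explicit integer seed and always records
the effective seed in its manifest; a time-derived seed is used only when
the caller provides none (CLI behaviour). Identical
`(dataset, mode, seed)` reruns are byte-identical.

Symmetric tiles are a documented caveat: transforms of a constant or
mirror-symmetric tile may coincide pixelwise ("up to 7 unique images"),
and the planner does not inspect pixel content to detect this.

## Stain normalisation

Normalisation matches each tile's per-channel cumulative histogram to one
fixed target image chosen by the user — a single target for the whole
cohort is what removes between-batch colour drift. The map is the
min-inverse of the target CDF,

    m(v) = min{ u : F_target(u) >= F_source(v) },

computed independently per RGB channel (single-channel tiles are
replicated to RGB first). It is monotone, hence rank- and
architecture-preserving, and deterministic (ties resolve to the smallest
eligible gray level).

Numerical facts worth knowing, all tested:

- self-matching moves no pixel by more than one gray level;
- the output CDF never overshoots the target's, and the sup-distance
  between them is bounded by the largest single-level mass of the
  *source* histogram (a whole source level lands on one target level);
- matching twice to the same target is idempotent up to ±1 gray level.

The 8-bit grid sets a hard limit: a batch effect that *merges* gray
levels (a contracting gain, or clipping at the 0/255 rails) destroys
information no exact histogram method can recover, because merged pixels
are indistinguishable afterwards. The package's stain-shift fixtures
therefore model recoverable batch effects — mild channel-affine maps
(gains around 1.0–1.1, biases within ±20 levels, no rail contact) — and
under those conditions matching drives the per-channel CDF sup-distance
back below 0.02. Histogram matching can also create artefactual
whitespace when the target contains more background than the input; the
package documents rather than suppresses this failure mode, which is a
known cost of the method's cheapness relative to stain-deconvolution
approaches.

## Augmentation operators

The catalogue is a representative subset of classical pixel-level
operators: emboss, Gaussian blur, sharpen, additive Gaussian noise,
contrast adjustment, pixel dropout and channel dropout, composable into
seeded pipelines (one master seed derives per-step and per-file
sub-seeds). All preserve shape, channel count and the 8-bit range;
stochastic operators are pure functions of `(input, parameters, seed)`.

Emboss, the operator the stromal-maturity workflow actually uses,
convolves each channel with `K = (1−α)·E + α·M(s)` where

    M(s) = [ -1-s  -s   0 ]
           [  -s    1   s ]
           [   0    s  1+s ]

with defaults `s = 2`, `α = 1`. `M(s)` sums to 1 for every `s`, so flat
regions are fixed points and interior mean brightness is preserved before
clipping; the diagonal structure accentuates oriented fibre edges, which
is precisely the mature/immature distinction. Borders are padded by
reflection — zero padding would ring dark halos around every tile and
corrupt any later whitespace estimate. The kernel form follows the common
convention of image-augmentation libraries with "intensity" mapped to
`s`; any other emboss kernel would change downstream pixel values, which
is why it is spelled out here.

Rounding is half-up throughout (`floor(x + 0.5)`) rather than banker's
rounding, for cross-platform determinism; the tests allow ±1 gray level
only where fractional kernel blends can produce exact half-integers whose
resolution depends on floating-point summation order.

## Prediction aggregation and metrics

The evaluation layer is deliberately boring and exactly specified:

- tile call: immature iff `P(immature) ≥ cutoff` (default 0.5, boundary
  inclusive);
- ROI call: majority of its tiles; patient call: majority of its ROIs;
- an exact tie resolves to **mature** at both levels. The patient-level
  rule is fixed by the workflow this package serves; extending the same
  conservative direction to ROI level is this package's choice, and both
  tie policies are exposed as a parameter.

Ground truth above tile level is derived by the same voting applied to
the tile truth labels — heterogeneous ROIs and patients are legitimate
(stromal maturity genuinely varies within patients) and are voted, not
rejected. Confusion matrices fix immature as the positive class
(TN = true mature, FP = false immature, TP = true immature, FN = false
mature). Precision, recall/sensitivity, F1, accuracy and specificity are
the standard ratios, returning `NA` (never a silent 0) on empty
denominators. ROC AUC is the rank-sum (Mann–Whitney) form with midranks
for ties, so it is invariant under strictly monotone rescaling of the
probabilities and equals the O(n²) pairwise count (tested to 1e−12,
including against an independent ROC implementation). Binomial intervals
are Clopper–Pearson exact — appropriate at patient-level sample sizes
where normal approximations fail; the method choice is the package's, as
is stating it. Fleiss' κ implements the standard
`(P̄ − P̄_e)/(1 − P̄_e)` for items×raters tables, `NA` when a single
category is used throughout (expected agreement 1).

## Synthetic fixtures

The generators exist so that every code path is testable with no external
data; they emulate structure, not biology:

- `make_fiber_tile()`: band-limited oriented noise. High coherence sums
  sinusoidal bands across one orientation (mature-like, near-parallel
  fibres); low coherence mixes random orientations and adds bright
  oedema-like blobs (immature-like). Blob highlights are renormalised
  rather than clipped — clipping would pile pixels into one gray level
  and put an artificial atom in the histogram — and ~1.5 gray levels of
  Gaussian sensor noise keep channel histograms smooth, as in real
  captures. Tiles are tinted with an H&E-like palette so grayscale
  conversion and per-channel matching are both exercised.
- `orientation_coherence()`: the gradient structure tensor's dominant
  orientation and eigenvalue anisotropy `(λ1 − λ2)/(λ1 + λ2)`. On
  generated tiles, orientation is recovered within ±5° and the coherence
  statistic separates the two texture regimes cleanly (a
  threshold-at-0.7 classifier exceeds 90% accuracy on default fixtures) —
  giving end-to-end pipeline tests a recoverable signal.
- `make_whitespace_tile()`: bright background (≥240) with a blob-shaped
  dark region (≤120) occupying an exact pixel count, so coverage
  estimates can be checked against ground truth.
- `apply_stain_shift()`: channel-affine gain/bias, the simplest model of
  staining batch drift.
- `build_dataset()`: a full on-disk `class/patient/roi` tree, mature
  patients at coherence 0.95, immature at 0.15, byte-reproducible from
  its seed, refusing to overwrite non-empty directories.

What passing tests on these fixtures does *not* show: that the
thresholding defaults suit any particular scanner, that histogram
matching is artefact-free on real cohorts, or anything about CNN
accuracy. The fixtures validate the mechanics (exact crops, exact
permutations, exact CDF algebra, exact vote counting), which is what a
pre-processing library can and should guarantee.

## Problem sizes and determinism

The shipped tests use small geometries — tiles of 4–96 px, datasets of a
few dozen files, 50–200 randomised property cases — chosen so the full
suite and the acceptance script each run in seconds while still covering
every boundary (the 0.8 coverage cutoff tile, the 800:100 one-eighth
boundary, exact ROI ties, half-integer rounding). All randomness flows
through explicit integer seeds via `withr::with_seed()`, so no test or
script perturbs the session RNG state, and identical seeds give identical
results on any platform.

## Known limitations

- Whole-slide formats (.svs/.ndpi), slide viewers and annotation are out
  of scope; inputs are already-extracted PNG/JPEG tiles.
- JPEG support needs the optional `EBImage` backend; 16-bit PNGs are
  rejected rather than rescaled.
- Per-channel RGB matching is the only normalisation method; stain
  deconvolution (Reinhard, Macenko) is intentionally not implemented.
- The augmentation catalogue is seven operators, not a full library;
  runtime (data-loader) augmentation is not provided.
- `to_mean` semantics (reduce above, augment below the rounded mean) is
  one of several defensible readings; it is fixed and documented rather
  than configurable.
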