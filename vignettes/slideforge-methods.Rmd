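---
title: "slideforge: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{slideforge: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the conventions it fixes and
why. Whole-slide-image (WSI) preprocessing is mostly bookkeeping — grids,
coordinate systems, thresholds, filters — and nearly every step admits two
or three defensible conventions. Each section below states the convention
slideforge uses, the alternatives considered, and what the choice implies.

## Coordinates, levels and the tile grid

A slide is a pyramid: level 0 at full resolution, higher levels
downsampled. slideforge reads any multi-page TIFF whose pages it can sort
by decreasing width; the per-level downsample factor is
`width[0] / width[l]`. All coordinates are 0-based pixels with origin at
the top-left, `x` horizontal; tile regions are half-open
`[x, x + t) × [y, y + t)`. Annotation files are always interpreted in
level-0 coordinates (the convention of the annotation tools themselves)
and rescaled by the downsample factor wherever tiles live on another
level.

Tile overlap is specified as a *fraction of the tile side*, giving stride
`s = t − ⌊o·t⌋`; a fraction generalises across tile sizes where a pixel
count would not. Tiles that would extend past the level edge are dropped
rather than padded: padding would manufacture pixels with no defined
content, and a model should never see them. The resulting grid-count
formula `⌊(W − t)/s⌋ + 1` is property-tested against brute-force offset
enumeration. Only pixel units are supported; micron-based tiling would
require slide metadata (microns per pixel) that synthetic and plain-TIFF
inputs do not carry.

The per-slide *tile dictionary* maps each `(col, row)` address to its
coordinates, annotation overlap fractions, foreground intensity,
tissue-detector probabilities, and inference outputs. `save_state()`
persists it (with the tile properties, level table and source path) to a
single gzip-compressed, versioned `.pml` file; pixels are deliberately not
stored — reloading re-opens the source image — which keeps state files in
the kilobyte range and round-trips the dictionary identically.

## Foreground detection

Both classical operators work on the 256-bin greyscale histogram of a
chosen (normally low-resolution) level, with luma weights
0.299/0.587/0.114 for the grey conversion. Otsu returns the bin
maximising the between-class variance of the `≤ t` / `> t` split;
triangle returns the bin farthest (perpendicular distance) from the chord
joining the histogram peak to the occupied extreme on the longer-tail
side. Exact ties break toward the lowest bin, with a small relative
tolerance so floating-point noise in the cumulative sums cannot flip a
genuinely tied symmetric histogram; one consequence worth noting is that
on a perfectly flat histogram the triangle distances are *not* tied (they
grow along the chord), so the operator returns the far end of the span
rather than the lowest bin.

Two conventions the histogram operators do not determine had to be fixed:

* **Direction.** A tile *passes* a method when its mean grey is at or
  below the threshold — darker than the cut. Stained tissue is dark;
  glass is bright.
* **Scale.** Per-tile mean intensity is reported on a 0–100 scale
  (mean/2.55; 0 black, 100 white), and plain integer cuts are expressed on
  that scale. A cut of 88 then admits typical stained tissue while
  rejecting near-white glass.

Thresholds are computed once from the whole detection level and applied
per tile via tile means, so detection at a coarse level carries over to a
fine tiling grid; the per-tile means computed at level 2 versus level 0
agree within about 2 intensity units on the synthetic fixtures (mean
pooling commutes with averaging up to 8-bit quantisation). A slide whose
detection level is a single intensity (e.g. all white) yields a
no-foreground warning and fails every tile rather than erroring the
pipeline.

## The tissue detector

The three-class (artefact / background / tissue) detector is deliberately
a *contract*, not a bundled network: `tile_model()` wraps any function
mapping a batch of RGB tiles to per-class probability rows summing to 1,
so externally trained weights plug in with no other behavioural change.
Detection runs on its own grid (its own level, tile size and overlap);
each working tile then receives the probability vector of the detection
tile containing its centre, with coordinates mapped through the
downsample ratio and centres over a dropped detection-grid edge clamped
to the nearest tile. Centre lookup was chosen over area-weighted
averaging of all overlapping detection tiles: it is exact when the grids
align (the recommended configuration — pick a detection tile size whose
level-0 footprint matches the working tile), cheaper, and easier to
reason about; area-weighting would blur labels across tile boundaries.
Re-running detection requires an explicit overwrite flag so a slow step
is never silently repeated or clobbered.

The bundled training harness fits a multinomial softmax classifier on
per-tile colour summary features (channel means and standard deviations
plus mean grey) by minibatch gradient descent. The features, not the
optimiser, carry the signal: the synthetic fixtures are colour-separable
by design, and a detector for them needs colour statistics, not spatial
filters. The harness's load-bearing properties are the ones the package
tests: *class-balanced sampling* (every draw picks a class uniformly,
then a tile uniformly within the class, so minority classes are not
drowned — the per-epoch draw log is kept on the model for auditing),
*determinism under a fixed seed*, and held-out balanced accuracy ≥ 0.9 on
colour-separable tiles. Users training real detectors on real slides
should use a proper vision model through the `tile_model()` contract;
the harness is for fixture-scale work.

## Annotation geometry

Polygon booleans go through the Clipper library (`polyclip`): same-class
polygons are unioned (so overlapping annotations of one class are not
double-counted), every ring of the negative "doughnut-hole" class is
subtracted from every other class, and per-tile overlap fractions are
exact clip-and-measure area ratios. Input winding is not trusted —
regions are normalised through a union before use — and rings that
self-intersect are rejected up front with their centroid in the message,
since a bow-tie ring has no well-defined interior. Rasterization
(point-in-polygon at pixel centres) is used only where a raster is the
*product* (segmentation masks), and independently as a test oracle for
the exact path.

Clipper operates on an integer grid; slideforge fixes that grid at 2⁻²⁰
px. Powers of two are exactly representable, so integer-coordinate
inputs — tile rectangles, axis-aligned annotations — clip *exactly*
(a tile half-covered by a rectangle gets fraction 0.5, not 0.4999998),
while curved inputs resolve to ~10⁻⁶ px, far below any tolerance that
matters at pixel scale.

All coverage comparisons are inclusive (`≥`): a threshold of 1.0 then
means "fully covered" rather than being unsatisfiable, and the same rule
is used for tissue-probability and foreground filters and for prediction
positivity in metrics, consistent with the positive-tile count's
"greater than or equal to" semantics.

## Extraction

A tile is eligible for a class when its overlap fraction reaches that
class's threshold (scalar or per-class; default 0.5) *and* it passes the
optional tissue-probability (recommended operating point 0.995) and
foreground filters. Per class, up to `num_per_class` (default 100)
eligible tiles are drawn uniformly under the seed; asking for more than
exist extracts everything with a warning rather than failing. A tile
eligible for several classes is written once per class — deduplication
would silently bias whichever class happened to be processed second, and
a duplicated boundary tile is the more honest dataset artefact; the
behaviour is documented where it happens. Filenames encode slide, class
and level-0 offsets, so re-runs are byte-identical and collisions are
impossible. The layout (`tiles/<slide>/<class>/…`) is the image-folder
convention that dataset loaders consume directly, and empty directories
can be created for classes absent from this slide so a multi-slide
dataset sees a consistent class set.

Channel statistics accumulate `(count, sum, sum of squares)` per channel
on the 0–1 scale — a form that merges associatively across tiles and
slides — and finalise to means and variances (variance clipped at 0
against catastrophic cancellation). Binary masks are written as {0, 255}
8-bit PNGs; stacked multi-class masks as `(t, t, n_classes)` arrays in
compressed RDS, R's native lossless serialisation, with channel order
following `classes_to_extract`.

## Inference and stitching

Classifier and segmenter inference store predictions only on tiles
passing the filters; asking for evaluation or visualisation before any
prediction exists is a distinct, early error. Where overlapping tiles
disagree, the stitched slide-level value of a pixel is the *arithmetic
mean* of all contributing tile predictions: unbiased, order-invariant
(verified by permutation tests) and exactly equal to a per-pixel
accumulate-and-divide oracle; max-pooling is available as an option for
recall-oriented use. Integer output maps probability to 0–255 by
round-half-up, so certainty is exactly 255. Pixels outside every tile
(dropped edges) are 0 — a value a genuine prediction could also take —
so a coverage plane (contributing-tile count per pixel) is stored
alongside and distinguishes "no tile" from "predicted zero".

## Metrics

Tile-level ground truth for a class is `overlap fraction ≥
overlap_threshold` (default 0.5); predicted positivity is `probability ≥
t`. Sweeps never abort: undefined ratios (precision with no predicted
positives, a sensitivity with no positive tiles) return 0 with a warning,
because a sweep endpoint routinely produces them. Dice is pooled over all
evaluated tiles (micro) by default — it weights pixels, not tiles, which
matches how a stitched mask is consumed — with per-tile macro averaging
as an option; two empty masks score 1. The slide-level AUROC treats the
positive-tile count as a score and uses midpoint ranks for ties,
equivalent to pairwise concordance with ties at ½.

## The synthetic fixtures

The generator emulates exactly the structure the pipeline's logic
depends on: a white background (glass), coloured regions for tissue
(stain-like purple) and pen-mark/bubble-like artefacts (blue), Gaussian
pixel noise (default sd 0.02 on the 0–1 scale, ≈ 5 grey levels), a
factor-2 pyramid built by 2×2 mean pooling (deterministic and adequately
alias-free at test scale), and annotation files in both supported
dialects. Colours are chosen far apart in RGB so a small classifier can
separate the classes quickly. What it deliberately does *not* emulate:
H&E texture, stain variation, focus artefacts, compression artefacts, or
the scale of real slides. Passing tests therefore demonstrate that the
*machinery* — grids, geometry, filters, bookkeeping, merging, metrics —
is correct, not that any particular detector generalises to real tissue;
detector quality on real data is entirely a property of the model plugged
into the `tile_model()` contract.

Oracle models close the loop for end-to-end tests by recovering ground
truth from tile pixels via nearest-reference-colour matching; on
noise-free, integer-aligned fixtures a perfect model provably scores
Dice 1 and balanced accuracy 1, so any deviation localises a defect in
the machinery rather than the model.

## Problem sizes and numerical choices

The test suite and acceptance script run on 768 × 512 (and smaller)
3-level slides with 64 px tiles (~100 tiles per slide), 200 random grid
configurations, 100 random histograms, 4 × 10⁵-point Monte-Carlo
geometry samples, 100 random metric sets, and 200 tiles per class for
detector training — sizes at which every property is measurable in
seconds while exercising the same code paths as gigapixel inputs; no
algorithm in the package has state that grows qualitatively with slide
size beyond the arrays themselves. Other fixed numerics: greyscale luma
weights 0.299/0.587/0.114; Clipper grid 2⁻²⁰ px; threshold tie-breaks to
the lowest bin with 10⁻⁹ relative tolerance; round-half-up for the 0–255
scale; variance clipped at 0.

## Known limitations

* No native reader for vendor WSI formats (SVS/NDPI/MRXS); inputs are
  multi-page TIFF or anything pre-converted to it. Micron units are not
  supported.
* The detection-to-working-grid carry-over is centre lookup; misaligned
  grids quantise probabilities to the detection grid rather than
  interpolating.
* The bundled training harness is colour-feature-based and is not a
  substitute for a real vision model on real tissue.
* Stitching holds the full slide-level array in memory; at true
  gigapixel scale the array (and the float option especially) is large,
  as the integer default exists to mitigate.
* Slide state embeds the source path; moving the image breaks
  `load_state()` by design rather than silently caching stale pixels.
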