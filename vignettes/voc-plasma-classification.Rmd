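---
title: "Classifying VOC plasma images with block-mean RGB features and cosine similarity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying VOC plasma images with block-mean RGB features and cosine similarity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement and the model

A helium dielectric-barrier-discharge photoionization detector ionizes an
injected volatile organic compound (VOC) and the plasma takes on an
analyte-specific color; benzene and benzene-containing mixtures additionally
change the spatial distribution of the emitted light. The classifier's input
is one still RGB frame per injection, captured at peak ionization, with a
category label of the form `analyte-pressure`: six analytes (n-pentane `C`,
benzene `B`, acetone `A`, and the mixtures `BC`, `AC`, `AB`) crossed with
four gas-chromatograph inlet pressures (17, 20, 24, 27 Psi) give 24 VOC
categories; pure helium adds `He-17` … `He-27`.

The model is deliberately minimal:

1. **Crop** the frame to a named region (full plasma band, plasma window
   only, or bottom reflection band).
2. **Segment** the region into an `n_w × n_h` grid of equal blocks and
   replace each block by its mean R, G, B (floating point, no rounding).
   Concatenating the triplets row-major gives a feature vector of length
   `3 · n_w · n_h`.
3. **Train** by averaging each category's training vectors element-wise —
   the category centroid. There are no fitted weights.
4. **Classify** a test vector to the centroid with the largest cosine
   similarity `S_c(x, y) = x·y / (‖x‖‖y‖)`.

The key assumption is that category identity is encoded in the *direction*
of the feature vector — the joint pattern of hue across blocks — not in its
overall magnitude. Cosine similarity discards global intensity scaling,
which buys robustness to exposure differences but has a sharp consequence:
with a single whole-image block (`1x1` grid) the feature is one mean color,
and any two categories whose mean colors are parallel are
indistinguishable in principle. Spatial segmentation is what breaks such
ties; this is the package's central, testable claim, and the reason the
whole-image baseline performs poorly while modest grids classify perfectly.

## Conventions and parameters

* **Sizes are width × height everywhere** a user sees them (region
  `540x400`, grid `27x20`), matching the field's tabulation; pixel arrays
  are indexed `[row, column, channel]` internally. Grid strings parse as
  `n_w x n_h`.
* **Crop rectangles** are 0-based, top-left origin, half-open. Standard
  region *sizes* for real 1080 × 1920 portrait frames are fixed (region 1:
  1080 × 1350; region 2: 360 × 324; region 3: 540 × 400) but their *offsets*
  depend on the camera geometry, so `region_spec()` stores explicit offsets
  and `default_regions()` centers the crops; a YAML config overrides them.
  (Two sizes for the plasma-window crop circulate, 540 × 420 and 360 × 324;
  the package uses 360 × 324, the size consistent with every grid in the
  block-count tables.)
* **Strict divisibility** (default): a grid must divide its region exactly,
  as every standard grid does — e.g. 1080/8 = 1350/10 = 135. The permissive
  `strict = FALSE` mode truncates remainder rows/columns at the right and
  bottom edges instead, for ad-hoc region sizes.
* **Channel values** are the stored 8-bit values (gamma-encoded sRGB), not
  linearized intensities. "Mean RGB" is read literally; block means of
  display-encoded values are what the method is defined on.
* **Tie-breaking** in the argmax is the first category in canonical label
  order (analyte column order `C, B, A, BC, AC, AB, He`, then ascending
  pressure). Ties are measure-zero on real data; determinism matters for
  reproducible tests. Argmax comparisons use exact float comparison.
* **Display normalization** `S_norm = (S_c − S_min)/(1 − S_min)` uses the
  minimum over one classification test's *entire* matrix (all test images ×
  all categories), not per row; it is affine, so similarity rank order — and
  hence classification — is unchanged. It exists purely to make heatmaps
  readable (`autoplot()` additionally clamps at a display floor, 0.90 by
  default); the degenerate all-ones matrix is rejected.
* **Accuracy** is reported both as an exact fraction and rounded to one
  decimal percent (`95.8%` style). Wall times are recorded in sweep tables
  for orientation but are hardware-dependent and never asserted anywhere.
* A test image whose label is absent from the model is classified into the
  closest present category and flagged (`label_in_model = FALSE`) rather
  than rejected, since unseen-category rejection is outside the method's
  scope.

## The synthetic generator

`generate_dataset()` exists so that every pipeline stage is testable
without the original image deposit. It emulates the features the classifier
relies on, and only those:

* a black background;
* one or two vertical Gaussian-profile light columns in the central plasma
  band, colored by an analyte-specific base RGB hue;
* a deterministic additive RGB shift per pressure step, so same-analyte
  categories at different pressures are nearby but separable — the dominant
  real-data confusion type;
* a faint bottom band holding a blurred, intensity-scaled copy of the
  column profile (the "reflection"), so bottom-band crops carry usable
  signal;
* i.i.d. Gaussian pixel noise per replicate, clipped to [0, 255].

The default canvas is 216 × 270, exactly 1/5 of the full-band region, so
the standard grids divide it integrally. Default study conditions: 24
categories × (5 training + 1 test) replicates, noise σ = 2 channel units,
base hues pairwise ≥ 40 channel units apart. These are modest, realistic
choices for a bright, stable plasma photographed by a phone camera, and the
scaled-down canvas keeps the whole suite fast while preserving the
geometry; they are fixed once in `synth_config()` rather than tuned
per test.

One pair is special by design: benzene (`B`, two narrow columns) and the
benzene/pentane mixture (`BC`, one double-width off-center column) share a
base hue and total intensity mass. Their whole-image mean colors are
parallel by construction, so the `1x1` grid cannot separate them — at zero
noise the similarity tie is exact and resolved arbitrarily; with noise the
decision is a coin flip per image — while any finer grid sees the different
column layouts and separates them cleanly. The generator's config enforces
the minimum hue separation between all *other* analyte pairs and exempts
declared mean-color twins. The helium preset (`helium_synth_config()`)
models the opposite regime: one hue family, pressure shifts and noise both
10× smaller, reproducing the much tighter within-category similarity of
pure-helium frames — its per-category (max − mean) cosine spreads come out
1–2 orders of magnitude below the VOC set's.

What the generator does **not** emulate: lens vignetting and exposure
drift, JPEG compression artifacts, frame-to-frame plasma flicker,
saturation clipping of the camera, or any physical emission model. Passing
tests on synthetic data therefore demonstrate the correctness of the
pipeline and the qualitative segmentation-vs-whole-image mechanism, not the
real-data accuracy figures; those require the deposited image set, which
the manifest-driven disk workflow (`read_manifest()` →
`featurize_images()` → `evaluate()`) consumes unchanged.

## Numerical choices

* Block means are computed by grouped column sums in double precision; a
  naive per-pixel double-loop oracle agrees within 1e-9 in the tests.
  Rounding to integers happens only in `reconstruct()`, where block means
  are painted back as flat tiles (at one-pixel blocks the reconstruction is
  pixel-identical to an integer source).
* Block traversal is row-major, top-left to bottom-right, RGB interleaved
  per block. Any fixed consistent ordering gives identical classifications
  (cosine similarity is permutation-invariant when the same permutation is
  applied everywhere — a property test); the order is frozen for file
  compatibility.
* Feature CSVs store one row per image (`v_000` …) with a JSON sidecar for
  grid/region metadata; models serialize to JSON with full-precision
  centroid arrays.
* Dataset generation is a pure function of `(config, seed)`: images are
  rendered noiselessly, then noise is drawn from R's RNG in a fixed
  category-major, replicate-minor order, so datasets are byte-for-byte
  reproducible.

## Problem sizes used by the test suite and acceptance script

Unit tests run on small random images (≤ 32 × 32) against brute-force
oracles and on reduced datasets (2 training replicates). The end-to-end
checks use the full default conditions: the 144-image default dataset on
the 216 × 270 canvas with grids 1×1 / 4×5 / 8×10, and a 28-image helium
dataset for the similarity-spread comparison. `scripts/acceptance.R`
regenerates both datasets from its `--seed` and recomputes every reported
quantity at run time.

## Known limitations

* Nearest-centroid cosine classification has no rejection option: every
  image is assigned some category, however dissimilar.
* The method is defined on RGB; grayscale input is rejected rather than
  promoted.
* Accuracy on the deliberately mean-color-matched pair at the `1x1` grid is
  a stochastic quantity (ties broken by noise); tests assert the direction
  of the effect — whole-image below segmented, errors confined to the
  matched pair — not an exact error count.
* JPEG input is supported for real phone-camera frames but lossy
  compression perturbs block means slightly; PNG is the canonical lossless
  format and the only one the generator writes.
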