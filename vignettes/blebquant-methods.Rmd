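---
title: "Quantifying blebbing cells: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying blebbing cells: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

blebquant measures plasma-membrane blebbing in time-lapse microscopy of
single cells. This vignette is the package's own account of what it
computes, which knobs matter, and where the design was genuinely open.

## The measurement problem

Mechanically confined cells bleb. A confined cell may form one large,
stable *leader bleb* and migrate in its direction (leader mobile, LM), form
the bleb but stay put (leader non-mobile, LNM), or form many small,
short-lived circumferential blebs and no leader (NL). Migration-scale
imaging uses intervals of minutes — at the 8 min reference interval used
throughout this package, five frames span 40 min — which is far too coarse
for curvature-based bleb trackers that need the birth and retraction of
each bleb to be resolved. The workflow here therefore follows the
segmentation-and-subtraction strategy: threshold the cell, let the user
(or a file) say where the cell body is, and treat everything else as
blebs.

## Pipeline

1. **Reduce and calibrate.** A multi-page TIFF is reduced to one channel
   and one Z plane (a fixed slice, mean, or maximum-intensity projection —
   fixed once for the whole movie, since re-choosing per frame would make
   areas incomparable across time). Pixel size (µm/px) and frame interval
   (min/frame) put all outputs in physical units. Uncalibrated stacks fall
   back to 1 µm/px and 8 min/frame with a warning rather than failing, so
   a pipeline can always run end to end; the fallback interval is the one
   at which the 5-frame persistence window equals 40 min.
2. **Edit.** Optional exclusion ROIs blank out debris or neighbouring
   cells by overwriting their interior with the frame's modal intensity
   (the background level of a fluorescence image) before any threshold is
   computed — the headless equivalent of hand-erasing objects from the raw
   movie. Multi-cell fields are handled by looping cells, each with its own
   body ROIs and exclusions.
3. **Binarize.** A global auto-threshold is computed on a 256-bin
   histogram. Data already integer in [0, 255] are binned identically;
   anything else is linearly rescaled onto the 256 bins, which matches the
   behaviour of the common reference implementations and makes the methods
   bit-depth-agnostic. Seven methods are provided (`otsu`, `mean`, `li`,
   `triangle`, `yen`, `isodata`, `minimum`); Otsu maximizes between-class
   variance and is the default. The default mode recomputes the threshold
   per frame, because intensity drifts over hours of imaging
   (photobleaching, focus); `first_frame` mode propagates frame 0's value
   for parity with preview-style workflows, and `preview_all_methods()`
   writes every method's frame-0 mask for offline choice. Bright cells on
   dark background are the default polarity; `dark_cell` inverts first.
4. **Clean.** Interior holes are filled (background regions not
   4-connected to the border become foreground — the complement of the
   8-connected foreground convention), thin attached noise is removed by
   morphological opening with a Euclidean disk (radius 0 disables it), and
   size exclusion keeps the largest connected component (or applies an
   area floor). With the default `keep_largest` policy the whole-cell mask
   has at most one component per frame. Opening runs before size
   exclusion so the single-component guarantee survives any splitting.
5. **Split.** `all_blebs = whole_cell AND NOT body`, and
   `cell_body = whole_cell AND NOT all_blebs`. This is exact set algebra:
   the two compartments are disjoint and their union is the whole-cell
   mask, pixel for pixel, so areas are conserved by construction. Body
   outlines may overlap bleb pixels; the subtraction order, not a second
   thresholding pass, defines the split. Sub-threshold gaps between a bleb
   and the body are not bridged — orphan components simply appear as
   blebs. Frames without their own body polygon inherit the nearest
   earlier one. The largest bleb by area is isolated per frame; area ties
   are broken deterministically by the lowest label id in row-major scan
   order and logged.

Foreground components use 8-connectivity throughout (diagonally touching
pixels are one object).

## Shape descriptors

For a region of area $A$ (pixel count × px²) and perimeter $P$:

* circularity $= 4\pi A / P^2$, clamped at 1 (digitization can push a
  disk slightly above 1);
* ellipse axes $M, m$ from the second-order central moments of the pixel
  centres (plus the 1/12 within-pixel variance, which also keeps
  single-pixel regions finite), rescaled so the fitted ellipse's area
  equals $A$ — with that normalization roundness
  $= 4A/(\pi M^2) = m/M = 1/\text{aspect ratio}$ exactly;
* solidity $= A / A_{hull}$, the convex hull taken over the pixel corner
  points so a filled rectangle scores exactly 1;
* aspect ratio $= M/m \ge 1$.

The perimeter is a corner-corrected chain code on the traced 8-connected
boundary: $P = 0.980\,N_s + 1.406\,N_d - 0.091\,N_c$ for straight steps,
diagonal steps and corners. The naive weights (1 and $\sqrt 2$)
overestimate a circle's perimeter by about 5.5%, which would push a
digital disk's circularity down to ~0.90; the corrected estimator is
accurate to well under 1% on smooth shapes, so a radius-50 disk scores
within 0.02 of 1 on all four descriptors. Regions of three pixels or
fewer use the exposed-edge (crack) length instead, where chain codes are
degenerate. Two caveats are inherent to local estimators: perimeters of
shapes with sharp corners converge more slowly (a rectangle's circularity
still differs by a few percent between a 1× and 2× digitization of the
same shape, while roundness, aspect ratio and solidity are stable to
<1%), and hull-based solidity carries an $O(1/r)$ positive bias on the
hull area for curved outlines (a digital disk's solidity is ~0.98 at
radius 50).

Percent-of-cell-area measures are `100 × Σ bleb areas / whole-cell area`
and `100 × largest-bleb area / whole-cell area`. Per-cell summaries
average each descriptor over the frames that possess it: bleb *counts*
average over all frames (a bleb-free frame contributes 0), but bleb
*size and shape* averages use only frames with at least one bleb — the
shape of nothing cannot be averaged. Whether bleb-free frames should
instead contribute zero area is genuinely ambiguous, so the rule is
togglable (`include_blebfree_frames`) and both denominators
(`n_frames`, `n_frames_with_blebs`) are reported.

## Dynamics and classification

Instantaneous speed is the whole-cell centroid displacement between
consecutive frames divided by the frame interval (µm/min); the
plot-of-origin view translates each cell's first point to (0, 0).

Bleb tracking links components of consecutive frames greedily by pixel
overlap, accepting a link when
`overlap / min(area_t, area_t+1) ≥ link_min_overlap` (default 0.5).
Unmatched components start tracks; a track ends the first frame its bleb
is unmatched. There is no gap closing: at multi-minute sampling a bleb
that disappears for a frame has genuinely retracted, and a later bleb at
the same position is a new object. A track alive `k` frames has lifetime
`k × frame interval` minutes. Curvature-based linking was rejected
because it requires temporal resolution far beyond migration-scale
movies.

Classification operationalizes two field definitions that are stated in
words rather than formulas, so both rules and all their parameters are
exposed:

* **has a leader bleb** — some track persists ≥ `persistence_frames`
  frames (default 5, i.e. 40 min at 8 min/frame) with mean area ≥
  `leader_area_frac` (default 0.10) of the mean whole-cell area over the
  same frames.
* **is mobile** — some window of `persistence_frames` consecutive
  intervals has mean speed ≥ `speed_min` (default 0.25 µm/min) *and*
  directionality ratio (net displacement / path length) ≥ `dir_min`
  (default 0.5). The speed floor is half the ~0.5 µm/min (30 µm/h)
  typical of leader-bleb-based migration — a permissive floor that still
  rejects centroid jitter, which sits an order of magnitude lower.

LM = both, LNM = leader only, NL = neither; fewer than 5 analyzed frames
yields `undetermined`. Thresholds are in physical units, so
classification refuses to run on uncalibrated data.

## The synthetic generator

`scene_params()` / `render_scene()` build movies of an elliptical cell
body with circular blebs attached to its rim (each bleb centre sits half
a radius outside the rim, so most of the disc is bleb and the whole cell
stays one connected component, as in real morphology). Defaults emulate a
confined melanoma-like cell: 0.5 µm/px, 8 min/frame, 10 frames, body
semi-axes 10 × 7 µm, background/cell intensities 20/120 on the 8-bit
scale, additive Gaussian noise of 5 intensity units (5% of contrast).
Truth masks are the noise-free geometry with the same subtraction
convention as the pipeline; truth tracks and phenotype come from the
scene's own bookkeeping (bleb birth/lifetime parameters, motion type),
never from image processing. One integer seed fully determines the
render.

Presets: `LM` moves at 0.5 µm/min with a permanent 6.5 µm-radius leader
bleb (~34% of cell area — comfortably above the 10% floor); `LNM` is the
same cell, static; `NL` is static with six 2 µm blebs living ≤ 2 frames
(~4% of cell area each); `apoptotic_like` has eight 1–2-frame blebs;
`low_confinement_like` has two blebs (5 and 4 µm) spanning the whole
movie. Preset geometry places parameters at least 2× from every
classification threshold, so recovery is expected to be exact there.

What the generator does **not** emulate: cortical mechanics (bleb
pressure, retraction dynamics within a frame), intensity texture inside
the cell, uneven illumination, photobleaching (the noise model is
stationary), cell–cell contact, and focus drift. Passing closed-loop
tests therefore shows the pipeline's logic is correct under clean,
geometry-level conditions; it does not certify segmentation on noisy real
movies, where threshold choice and manual editing still matter.

## Numerical conventions

* Frames and pixel coordinates are 0-based `(row, col)` in all file
  formats; polygon containment is even-odd and boundary-inclusive, so a
  rectangle with corners (1,1)–(6,6) covers exactly 36 pixels.
* Foreground 8-connectivity pairs with 4-connected holes.
* Largest-bleb ties: lowest label id, logged.
* Masks write as 0/255 8-bit TIFF and round-trip losslessly.
* CSV numbers are serialized to 6 significant digits, making repeated
  runs byte-identical; there is no randomness anywhere in the analysis
  path.
* Degenerate inputs: constant frames abort thresholding with the frame
  index; empty frames produce warnings (and empty outputs), never NaN
  rows; an all-body cell is a warning (bleb-free), not an error.

## Test problem sizes

The test-suite and acceptance runs use 96 × 192 px movies of 10 frames,
20 seeds per preset for phenotype recovery and 10 for the lifetime
contrast, 200 random frames for the threshold oracle and 100 for mask
algebra — sizes at which every closed-loop property is exercised while
the whole suite stays quick on a single core.

## Known limitations

* Body definition is an explicit input (ROI files); there is no automatic
  cell-body detector.
* No local/adaptive thresholding, watershed splitting, deconvolution,
  drift correction, or fluorescence-intensity statistics.
* Binary ImageJ `.roi` files are not parsed; convert to the JSON polygon
  format.
* Overlap tracking cannot follow blebs that slide along the rim by more
  than their own width per frame.
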