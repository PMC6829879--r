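---
title: "Methods: line-based quantification of cell elongation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: line-based quantification of cell elongation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(houghcell)
```

## The morphological model

`houghcell` treats elongation as a *linear-pattern* property: a slender,
fibroblast-like cell presents two nearly straight, nearly parallel boundary
edges, while a cobblestone-shaped epithelial cell and a detached floating
cell present only short, curved boundary arcs. The pipeline therefore
reduces an image to the set of straight boundary segments of length at
least 20 px, merges the segments that describe one cell, and reports their
count and lengths. The count tracks how many cells express the elongated
phenotype (and, on a time series, proliferation of those cells); the
length distribution tracks how elongated they are.

The assumptions this rests on:

* adherent cells are darker than the culture medium (the cytoplasm
  transmits less light), so boundaries carry the image's strongest
  gradients after contrast stretching;
* elongated cells are locally straight — curvature is not modeled, a
  strongly bent cell is represented by its merged piecewise line;
* floating cells are bright and rounded, so their longest straight chord
  stays below the 20 px floor and they are never counted;
* magnification is fixed within a study (lengths are reported in pixels,
  not micrometres; at a different magnification the 20/25/30/40 px
  conventions denote different physical lengths).

## Stage 1: preprocessing

Gray conversion uses BT.601 luminance weights; equal-channel pixels are
unaffected by the choice. Normalization is fixed per bit depth (`/255`)
rather than per-image min–max, so frames of one time series stay on a
common intensity scale; per-image rescaling is available as
`normalize = "minmax"` for isolated frames with unusual exposure.

The 3×3 median filter (`median_kernel`, odd pixels) is the smallest window
that removes isolated impulse noise without eroding thin boundaries;
borders are replicated so the frame edge does not acquire an artificial
dark halo. The cube law `F = G³` is applied next: it is strictly monotone
with `F ≤ G` on `[0, 1]`, so it never reorders intensities but stretches
the dark (cell) end of the range away from the brighter medium.

Edges come from a Canny chain: Gaussian smoothing (`canny_sigma`, default
1.5 px — small enough to keep the two sides of a ~10 px wide cell
distinct, large enough to suppress texture), Sobel gradients, non-maximum
suppression with linear interpolation of the magnitude along the gradient
direction, and hysteresis with 8-connected linking. When thresholds are
not given they are derived per image: the high threshold is the Otsu split
of the gradient-magnitude histogram and the low threshold is 0.4× that. A
percentile rule was considered and rejected: under non-uniform
illumination *every* background pixel has a small nonzero gradient, so any
fixed percentile sits inside the background mode of what is in fact a
bimodal distribution; Otsu finds the mode boundary instead. Because any
relative rule adapts downward on a featureless frame, the derived high
threshold is floored at `min_grad = 0.01` intensity units/px — an order of
magnitude below real boundary gradients, an order above noise — so blank
frames give empty edge maps.

## Stage 2: Hough detection

Coordinates are zero-based with `x` = column and `y` = row (top-left
origin); `θ` is restricted to `[0, π)` so each undirected line has one
parameter pair, and `ρ = x·cosθ + y·sinθ` is binned over `[-D, D]` with
`D` the image diagonal. Discretization defaults are 1° × 1 px
(`theta_step`, `rho_step`) — standard granularity; coarser bins blur
nearly parallel cells together, finer bins split votes of slightly curved
boundaries.

Peak finding is greedy non-maximum suppression: take the largest remaining
count, suppress an `11 × 11`-bin window around it (±5°, ±5 px), repeat
while counts reach `min_votes`. Ties break toward the lower θ then ρ bin,
making the peak list deterministic. The window wraps at `θ → π` with `ρ`
negated so both parameter images of a line are suppressed together.
`min_votes` defaults to 20, matching the length floor: a shorter run
cannot reach 20 collinear pixels.

The accumulator describes infinite lines, but per-cell lengths need
endpoints. The bridge is peak-guided tracing: edge pixels within
`lateral_tol` (2 px) of a peak line are projected onto it, sorted, and
split wherever consecutive projections gap by more than `max_gap` (3 px);
each maximal run whose Euclidean endpoint distance reaches `min_length`
(20 px) becomes a segment. The 20 px floor is applied to Euclidean segment
length (and mirrored in `min_votes`); applying it to raw vote counts alone
would keep scattered, non-contiguous pixel sets. The floor is inclusive
(`length ≥ 20`).

## Stage 3: post-processing

Two rule-based corrections, in this order:

1. **Duplicate removal.** If two segments have minimal distance < 15 px
   *and* included angle < 20° (both strict), the shorter one is removed.
   Distance is the minimal point-pair distance between the two *closed
   segments* — infinite-line distance would be zero for any non-parallel
   pair and make the rule vacuous. The angle is the acute angle between
   undirected directions (directions 10° and 170° are 20° apart). With
   more than two mutual conflicts the resolution is greedy: accept
   segments in decreasing length (ties by θ, ρ, x₁, y₁) when they conflict
   with nothing already accepted. This is deterministic, idempotent, and
   provably the length-favoring maximal conflict-free set — the test suite
   checks it against exhaustive enumeration up to 8 segments.
2. **Fragment merging.** Segments that intersect or whose endpoints lie
   within `join_tol = 5 px` are connected; connected components become
   piecewise lines (`cell_id`), and a cell's length is the sum of its
   member lengths. `join_tol` is deliberately below the 15 px duplicate
   radius: anything close enough to merge would otherwise have been a
   duplicate candidate, and distinct neighboring cells stay separate.

## Quantification

Per image: `n_lines`, the raw lengths, mean and sample SD (n−1), and the
percentage of lines in the bins [20, 25), [25, 30), [30, 40), [40, ∞).
Half-open bins partition the line set — every length lands in exactly one
bin and the percentages sum to 100 when any line exists; an empty image
reports zero lines with undefined (NA) moments rather than zeros.
`assemble_timecourse()` binds per-image reports into one table keyed by
(group, day, image), numbering replicates within each stratum;
`tidy()`/`glance()` give the long per-line and wide per-image forms. Group
hypothesis testing (ANOVA with multiplicity correction) is deliberately
exported rather than computed — the tidy tables feed any standard
statistics tool.

## The synthetic scene generator

`generate_scene()` emulates the imaging conditions the pipeline is built
for: a uniform bright medium (0.75) carrying dark adherent cells (0.45) —
elongated cells as capsules of a given centerline length and aspect ratio,
cobblestone cells as low-eccentricity ellipses (15–25 px diameter) — and
bright floating discs (0.95, radius 4–8 px); then a ±5% linear
illumination ramp, Gaussian blur (σ = 1 px), and salt-and-pepper noise
(rate 0.002). The intensity ordering cell < medium < floating is enforced
by `scene_spec()`. Placement is rejection-sampled with a 16 px clearance
between adherent cells so that the duplicate rule cannot delete a true
neighbor's line; exceeding the attempt budget is a placement error, not a
silent overlap. A single mandatory seed drives one RNG, so scenes are
bit-reproducible.

The default study condition — 10 elongated cells of 50–70 px (aspect 6) on
a 320 × 320 px frame — gives object densities at which each cell's two
boundary sides are 8–12 px apart: within the 15 px duplicate radius, so
each cell resolves to one line, exactly the situation the duplicate rule
addresses.

What the generator does *not* emulate: cell-to-cell contact and confluent
sheets, intracellular texture, curved (banana-shaped) cells, focus drift,
and vignetting beyond a linear ramp. Passing the recovery tests therefore
demonstrates the pipeline's correctness and its behavior under the stated
noise model, not performance on confluent or highly textured real
cultures — on such data the thresholds are exposed for tuning
(`pipeline_config()`), and the overlay rendering exists precisely so a
user can audit detections frame by frame.

## Numerical conventions and degenerate inputs

* Vote binning rounds to the nearest ρ bin, half away from zero; with the
  default 1 px bins integer-coordinate ties do not occur in practice.
* An empty edge image is a valid all-zero accumulator; an all-zero
  accumulator yields an empty peak list; an image with no detections
  reports `n_lines = 0`.
* A zero-length segment is treated as a point for distances and is an
  error for angles (no direction).
* Polyline start/end for the overlay (red/yellow) is the spanning-chord
  endpoint with smaller (y, then x) — determinism, since the merged
  polyline itself is undirected.
* All pipeline stages are pure functions of image and configuration, so
  repeated runs are byte-identical; the only RNG in the package is the
  seeded scene generator.

## Test and validation scale

The suite validates voting against a brute-force oracle on random images
up to 32 × 32 px (dozens per run), geometry against dense-sampling and
exhaustive-enumeration oracles (100+ random pairs, all conflict structures
up to 8 segments), and end-to-end recovery on 10-seed batches of the
default 320 × 320 scenes — 30 full pipeline runs — chosen so the whole
suite completes in well under a minute while still exercising every
stage at the study condition. The acceptance script reruns the same
study-scale recovery from scratch and reports recall, precision, count
and length errors, floating-cell robustness, and the
elongated-vs-cobblestone contrast.

## Known limitations

* Lengths are in pixels; cross-study comparison requires equal
  magnification.
* A strongly curved cell is under-measured by its chord segments even
  after merging; dynamic curve models are out of scope.
* In confluent sheets boundary segments of touching cells can merge; the
  count then underestimates cell number.
* The 20 px floor makes cells shorter than 20 px invisible by design; the
  readout is specific to the elongated phenotype, not a general
  segmentation.
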