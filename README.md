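# houghcell

Quantifying cell elongation in brightfield microscopy with the Hough
transform.

## The problem

When epithelial cells (e.g. A549) are driven through an
epithelial–mesenchymal transition — typically by TGF-β — their morphology
changes from a rounded "cobblestone" shape to a slender, fibroblast-like
one. Impedance readouts (RTCA cell index) track the population in real
time but say nothing about shape, and the paper-and-ruler alternative does
not scale. `houghcell` measures the change directly from ordinary 200×
brightfield frames: slender cells present near-straight boundary segments,
and the number and length of those segments per image are a morphology
readout that can be followed over a treatment time series.

## The method

The pipeline has three stages:

1. **Preprocessing.** RGB frames are converted to normalized gray
   (`G ∈ [0, 1]`), salt-and-pepper noise is removed with a 3×3 median
   filter, contrast is stretched with the cube law `F(i,j) = G(i,j)³`
   (adherent cells transmit less light than the medium, so the cube pushes
   them further from the background), and boundaries are extracted with a
   Canny edge detector (Gaussian-derivative gradient, non-maximum
   suppression, hysteresis).
2. **Hough transform.** Every edge pixel `(x, y)` votes, for each angle
   bin `θ ∈ [0, π)`, into the distance bin nearest
   `ρ = x·cosθ + y·sinθ`. Peaks of the accumulator `[H_ij]` are straight
   boundary candidates; edge runs along each peak line are chained into
   segments, and only segments of at least 20 px are kept — short chords
   are noise-level, which also makes bright rounded floating cells
   invisible to the detector.
3. **Post-processing.** Two corrections: nearly parallel duplicate
   markings of one cell (minimal distance < 15 px *and* included angle
   < 20°) keep only the longer line; intersecting or very close segments
   are merged into one piecewise line per cell. Reported per image:
   line count, line lengths, mean ± SD, and the percentage of lines in
   the bins 20–25, 25–30, 30–40 and > 40 px.

Because study images of this kind are rarely deposited, the package ships
a seeded synthetic-scene generator (dark elongated capsules and
cobblestone blobs on a brighter medium, bright floating discs,
illumination gradient, blur, impulse noise) with exact ground truth, so
every stage is testable offline and detection quality is measurable.

## Worked example

```r
library(houghcell)

sc  <- generate_scene(scene_spec(seed = 42, n_elongated = 6,
                                 n_cobblestone = 3, n_floating = 4))
rep <- run_image(sc$image, image_id = "demo", group = "tgfb", day = 2)
glance(rep)
#> # A tibble: 1 × 10
#>   image_id group   day n_lines mean_length sd_length pct_20_25 pct_25_30
#>   <chr>    <chr> <int>   <int>       <dbl>     <dbl>     <dbl>     <dbl>
#> 1 demo     tgfb      2       6        70.5      8.42         0         0
#>   pct_30_40 pct_gt40
#>       <dbl>    <dbl>
#> 1         0      100

evaluate_recovery(attr(rep, "cells"), sc$truth) |>
  dplyr::select(n_detected, n_truth, recall, mean_length_error)
#> # A tibble: 1 × 4
#>   n_detected n_truth recall mean_length_error
#>        <int>   <int>  <dbl>             <dbl>
#> 1          6       6      1             0.115
```

All 6 elongated cells are found as 6 lines (the 3 cobblestone and 4
floating cells are correctly ignored), with mean detected length 70.5 px
and every line in the > 40 px bin — the elongated phenotype. Recall is
1.0 against ground truth with ~11% length error. `autoplot(rep)` shows
the length histogram; `render_overlay(sc$image, attr(rep, "cells"))`
draws each detected cell in green with a red start and yellow end point.

For a treatment time series laid out as `root/<group>/day<N>/*.png`:

```r
tc <- run_batch("root/")   # one row per image
tidy(tc)                   # long form: group, day, replicate, length
autoplot(tc)               # detected lines per day, per group
```

A thin CLI wraps the same functions:
`exec/houghcell <run|batch|synth|eval> [options]`.

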