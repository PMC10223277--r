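# fazmetry

Morphometry of manually segmented foveal avascular zones (FAZ) in OCTA
images.

## The problem

The foveal avascular zone — the capillary-free region at the centre of the
fovea — is a key OCTA biomarker for diabetic retinopathy, but on most
devices it must be delimited by hand: an observer draws a coloured perimeter
line over the en-face image of the superficial (SCP) or deep (DCP) capillary
plexus. Manual delimitation carries substantial inter- and intra-observer
variability, especially in diseased retinas, and the variability depends on
which definition of the FAZ boundary the observer applies: tracing the
enclosing vessels directly ("region without vessels") versus placing the
boundary at the inner edge of the vascular transition zone.

`fazmetry` provides the measurement chain for such segmentations, and a
synthetic-data module that generates FAZ-like contours with known ground
truth so every step can be validated end to end.

## The statistics at its core

Given the $N$ perimeter points $(x_i, y_i)$ of one drawn contour:

1. **Azimuthal ordering.** Points are converted to polar coordinates about
   their centroid and sorted by azimuth (ties broken by radius), closing
   the polygon.
2. **Area** by the shoelace (Gauss) method,
   $A = \tfrac12 \left| \sum_{i=1}^{N} (y_i + y_{i+1})(x_i - x_{i+1}) \right|$
   (indices mod $N$), converted from px² to mm² with the device pixel size
   (by default `width_mm / image_cols` per axis for a 3 mm scan field).
3. **Acircularity** as the radial coefficient of variation about the
   contour centre $(\bar x, \bar y)$:
   $\mathrm{acirc} = \sigma(R) / \bar R$, with
   $\bar R = \tfrac1N \sum_i R_i$ and
   $\sigma(R) = \sqrt{\tfrac1N \sum_i (R_i - \bar R)^2}$,
   where $R_i$ is the distance of point $i$ from the centre. A perfect
   circle scores 0; values above 0.5 flag a very irregular contour.

Per-segmentation metrics are aggregated into group summaries (mean/SD of
area and acircularity per cohort × plexus × criterion), initial-vs-final
criterion contrasts, inter-/intra-observer variability components, and the
paired area–acircularity table.

## Worked example

Render a synthetic annotated image, extract the drawn perimeter and measure
it:

```r
library(fazmetry)
set.seed(1)
shape <- synthetic_shape(30, data.frame(k = c(3, 5), a = c(0.08, 0.05),
                                        phi = c(0.4, 1.1)),
                         centre = c(63.5, 63.5), n_samples = 720)
analytic_area(shape)
#> [1] 2839.98            # ground-truth area in px^2

img <- render_annotated(shape, background = "vessels")
ps  <- extract_overlay(img, overlay_spec(c(255, 0, 0), tolerance = 30))
ps
#> <faz_pointset> 245 points | eye eye HEALTHY SCP | observer A1 | INITIAL

compute_metrics(ps, scale = pixel_scale(3 / 320))
#> <faz_metrics> area 0.2503 mm^2 (2847.5 px^2), acircularity 0.0688, N = 245
```

The measured polygon area (2847.5 px²) recovers the analytic area of the
generating shape (2840.0 px²) to 0.3 %; at the 3 mm / 320 px device scale
that is an FAZ of 0.25 mm² with a mildly irregular boundary
(acircularity 0.069).

A full simulated study — cohorts of eyes, two plexuses, several observers
tracing under both delimitation criteria — runs through the pipeline
drivers:

```r
res <- cmd_all("study_out", spec = cohort_spec(seed = 7))
res$summaries$summary        # mean/SD area and acircularity per cell
res$summaries$contrast       # initial-vs-final deltas and area ratio
```

or from the shell via the thin wrapper
`inst/scripts/fazmetry-cli.R` (subcommands `simulate`, `extract`,
`metrics`, `summarize`, `all`).

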