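---
title: "FAZ morphometry: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{FAZ morphometry: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(fazmetry)
```

# The measurement model

`fazmetry` quantifies manual segmentations of the foveal avascular zone
(FAZ): closed perimeter lines drawn by human observers over en-face OCTA
images of the superficial (SCP) or deep (DCP) capillary plexus. Each
segmentation is reduced to two scalars:

* the **area** enclosed by the drawn polygon, in mm², and
* the **acircularity**, the coefficient of variation of the radial
  distances of the perimeter points from their centroid,
  $\sigma(R)/\bar R$, which is 0 for a perfect circle and grows with
  boundary irregularity.

The chain implemented by `compute_metrics()` is:

1. extract the overlay pixels whose colour matches the drawn line
   (`extract_overlay()`);
2. sort the unordered pixel cloud by azimuth about its centroid
   (`sort_by_azimuth()`);
3. take the perimeter-point centroid, the radial coordinates, and
   $\sigma(R)/\bar R$ (`contour_centre()`, `radial_coordinates()`,
   `acircularity()`);
4. take the absolute shoelace sum for the area (`shoelace_area()`) and
   convert px² to mm² with the device pixel scale (`to_mm2()`).

## Assumptions

**Star-shapedness.** Azimuth sorting reconstructs the drawn curve exactly
when the boundary is star-shaped about its centroid — every boundary point
visible from the centre. Healthy and moderately remodelled FAZs satisfy
this; a boundary that doubles back (a deep notch or crescent) is silently
replaced by a different polygon. Note that the sorted polygon itself is
always simple: after sorting, consecutive azimuth gaps are below $\pi$, so
no two edges can properly cross. The failure mode is therefore *not* a
self-intersecting polygon but a plausible-looking wrong one, which is why a
diagnostic is attached rather than an error raised: `star_shaped` in the
metrics row is `FALSE` when some azimuth sector contains radii spread more
widely than a drawn line of a few pixels' thickness can explain (sector
binning, spread threshold `max(6 px, 0.2 * mean radius)` in at least two
sectors). The flag is a heuristic: it marks records whose area and
acircularity deserve manual review.

**Perimeter-point centre.** The centre used for the radial statistics is
the arithmetic mean of the perimeter points, not the area centroid. For
thick drawn lines kept whole (see below) the two differ slightly; the
perimeter-point mean is the definition implemented throughout.

**Population SD.** $\sigma(R)$ uses the divisor $N$, matching the $1/N$
structure of the mean radius; the contour is a full enumeration of the
drawn points, not a sample from them. The sample form ($N-1$) is available
via `sd_divisor = "n-1"` and matters only for very sparse contours.

# Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `overlay_spec()$tolerance` | 30 | intensity levels (0–255) | Pencil-drawn lines are near-pure colours; 30 absorbs export quantisation while staying far from the greyscale background. Must be < 128. |
| `pixel_scale()` | `width_mm / image_cols` per axis | mm/px | The device exports a 3 mm field; when the manufacturer's pixel size is unknown the scan width over the pixel count is the natural default. Anisotropic scales are supported since exports need not be square. |
| `sd_divisor` | `"n"` | — | See above. |
| `line_thickness` (render) | 1 | px | Matches a single-pixel pencil stroke; thicker lines are kept whole during extraction. |
| `transition_px` (render) | 6 | px | Width of the avascular-to-vascular transition band in synthetic images. |

Lines thicker than 1 px are **not** thinned before measurement: all
matching pixels enter the point set, and the azimuth sort's radius
tie-break keeps ring pixels adjacent, so the measured polygon tracks the
ring's interior envelope closely. Skeletonisation would silently change
areas; keeping the ring whole keeps the measurement transparent, and the
thickness-sensitivity bound (area shift below one perimeter-pixel band per
thickness step) is asserted in the test suite.

# The synthetic-data generator

Clinical OCTA exports with manual overlays are not redistributable, so the
package ships a generator whose defaults define the simulated study
conditions.

**Shapes.** FAZ-like boundaries are finite Fourier radial perturbations of
a circle, $r(\theta) = R_0 (1 + \sum_k a_k \cos(k\theta + \phi_k))$ with
harmonic orders $k \in \{2,\dots,6\}$ and $\sum_k |a_k| < 1$. This is the
lowest-order family that spans realistic FAZ irregularity while keeping a
closed-form area, $\pi R_0^2 (1 + \tfrac12 \sum_k a_k^2)$, available as
ground truth for oracle tests. Orders $k \ge 2$ also keep the
perimeter-point centroid at the construction centre, which makes the
acircularity of a single harmonic analytically $a/\sqrt 2$ in the dense
limit — a second closed form the tests lean on.

**Cohorts.** The default `cohort_spec()` simulates 73 healthy, 40 type-1
and 54 type-2 diabetic eyes (167 eyes, both plexuses, four observers with
one of them tracing two series, two criteria — 3340 tracings). Base radii
are uniform per cohort (18–28 px for healthy, 16–26 px for DM1, 16–30 px
for DM2 on the 320 px / 3 mm grid, i.e. FAZ areas of roughly 0.1–0.3 mm²),
and the DM2 amplitude range (0.05–0.20) is the widest, reflecting the more
disturbed retinas of that group. These are field-realistic choices fixed
once; they are configuration, not claims about any clinical population.

**Observers and criteria.** A tracing perturbs the radial profile
multiplicatively:
$r'(\theta) = r(\theta) \cdot b \cdot (1 + s(\theta) + \varepsilon(\theta))$,
with a radial bias $b$, a high-frequency harmonic spike term $s$ (order
drawn from 15–40 — vessel-following scallops, deliberately not white
noise), and per-point Gaussian jitter $\varepsilon$ (SD 0.01 by default).
The criterion-level templates are $b = 1.12$, spike amplitude 0.06 for the
**initial** criterion (observers hug the enclosing vessels, spikier lines)
and $b = 0.97$, spike 0.02 for the **final** criterion (the boundary
slightly enters the avascular core, smoother lines). On top of the
templates, each default observer carries their own per-criterion bias —
spread widely under the initial criterion (1.06–1.16: a loosely defined
boundary is interpreted differently by each observer) and tightly around
0.97 under the final one (0.96–0.98: the common transition-zone rule pulls
observers together). This observer-level spread is what makes
inter-observer variability drop under the final criterion in the simulated
cohort; with a single shared model per criterion the drop would not be
reproduced, because the spike and jitter terms barely move an area mean.
Under these defaults the final/initial mean-area ratio is about 0.75 in
every cohort × plexus cell (the `mean_final_initial_area_ratio` quantity
recomputed by `scripts/acceptance.R`).

**Reproducibility.** Every record draws from its own RNG stream, derived
from the master seed by a stable hash of the record key
(eye | plexus | observer | series | criterion), so any subset of a cohort
regenerates identically regardless of generation order — asserted by
growing a design and comparing shared records.

**What the generator does not emulate.** Real capillary geometry, OCTA
motion/projection artefacts, signal dropout, observer fatigue or learning,
and non-star-shaped pathological FAZs. Passing tests therefore validate the
*measurement chain* (extraction, ordering, area, acircularity, aggregation)
and the *direction* of the criterion effects under the planted model; they
say nothing about the clinical magnitude of those effects.

# Numerical choices

* **Azimuth ties** (several pixels of a thick line at one angle) break by
  ascending radius: deterministic output, no long chords between ring
  sides.
* **Start convention:** the contour starts at the smallest azimuth in
  $(-\pi, \pi]$, making sorted output unique.
* **Degenerate inputs:** fewer than 3 distinct points or a collinear set
  raise a structured `faz_degenerate_contour_error`; a contour whose points
  all coincide with the centre raises `faz_zero_radius_error`. Overlay
  extraction raises `faz_no_overlay_error` on zero matches and warns (with
  the component count) when matches form more than one 8-connected
  component — 8-connectivity, because a 1 px drawn line steps diagonally.
* **Shoelace sign:** the signed sum's absolute value is returned; drawn
  contours have no meaningful orientation.
* **Coordinates** are real-valued throughout the geometry; integer pixel
  input is promoted. The serialization convention is fixed: x = column,
  y = row, origin top-left, 0-based.

# Test and simulation sizes

The suite validates against independent oracles (a hand-coded
dense-sampling $\sigma/\bar R$, `pracma::polyarea`, convex hulls) at sizes
chosen to make discretisation error negligible relative to the asserted
tolerances: 1000–2000 angular samples for oracle comparisons, 100 random
shapes for round-trip and oracle sweeps, 50 contours for invariance
properties, and cohorts of 100 eyes per group for the parameter-recovery
and ordering checks. The same sizes are used by `scripts/acceptance.R`.

# Known limitations

* Non-star-shaped FAZs are measured as their azimuth-sorted proxy and only
  flagged, not corrected; a genuinely crescent-shaped FAZ needs a different
  ordering (e.g. nearest-neighbour chaining), which is out of scope.
* The acircularity is the only shape index implemented; isoperimetric
  circularity ($4\pi A / P^2$) and solidity are deliberately out of scope.
* No automatic FAZ segmentation: the package measures manual delimitations.
* Summary SDs pool all segmentations within a group by default. Whether to
  pool or to average within eyes first is a genuine analysis choice; both
  are exposed (`eye_average`), pooling is the default because the
  per-segmentation distribution is the object the variability analysis
  describes.
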