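# Synthetic FAZ-like boundaries
#
# Shapes are finite Fourier radial perturbations of a circle,
#   r(theta) = R0 * (1 + sum_k a_k * cos(k * theta + phi_k)),  k >= 2,
# the lowest-order family that spans realistic FAZ irregularity while
# keeping a closed-form area, pi * R0^2 * (1 + sum a_k^2 / 2), available as
# ground truth for oracle tests.

#' Parametric FAZ-like shape
#'
#' A star-shaped boundary defined in polar form as a circle of base radius
#' `R0` modulated by cosine harmonics. Requires `sum(|a_k|) < 1` so the
#' radius stays positive, and harmonic orders `k >= 2` so the perimeter-point
#' centroid coincides with `centre`.
#'
#' @param R0 Base radius in pixels (> 0).
#' @param harmonics Data frame (or 3-column matrix) with columns `k`
#'   (integer order >= 2), `a` (amplitude fraction) and `phi` (phase, rad).
#'   May be empty for a perfect circle.
#' @param centre Numeric `(cx, cy)` in pixel coordinates.
#' @param n_samples Number of uniform angular samples used when the shape is
#'   discretised (default 512).
#' @return Object of class `faz_shape`.
#' @export
synthetic_shape <- function(R0, harmonics = NULL, centre = c(0, 0),
                            n_samples = 512L) {
  if (!is.finite(R0) || R0 <= 0) {
    faz_stop("faz_invalid_spec_error", "R0 must be > 0")
  }
  if (is.null(harmonics) || NROW(harmonics) == 0L) {
    harmonics <- data.frame(k = integer(), a = numeric(), phi = numeric())
  } else {
    harmonics <- as.data.frame(harmonics)
    names(harmonics) <- c("k", "a", "phi")[seq_along(harmonics)]
    if (is.null(harmonics$phi)) harmonics$phi <- 0
    if (any(harmonics$k < 2 | harmonics$k != round(harmonics$k))) {
      faz_stop("faz_invalid_spec_error",
               "harmonic orders k must be integers >= 2")
    }
    if (sum(abs(harmonics$a)) >= 1) {
      faz_stop("faz_invalid_spec_error",
               "sum of |amplitudes| must be < 1 to keep the radius positive")
    }
  }
  structure(list(R0 = as.numeric(R0), harmonics = harmonics,
                 centre = as.numeric(centre),
                 n_samples = as.integer(n_samples)),
            class = "faz_shape")
}

#' @export
print.faz_shape <- function(x, ...) {
  cat(sprintf("<faz_shape> R0 = %.1f px, %d harmonic(s), area %.1f px^2\n",
              x$R0, nrow(x$harmonics), analytic_area(x)))
  invisible(x)
}

#' Radial profile of a synthetic shape
#'
#' @param shape A [synthetic_shape()].
#' @param theta Vector of angles (rad).
#' @return `r(theta)` in pixels.
#' @export
shape_radius <- function(shape, theta) {
  r <- rep(1, length(theta))
  h <- shape$harmonics
  for (i in seq_len(nrow(h))) {
    r <- r + h$a[i] * cos(h$k[i] * theta + h$phi[i])
  }
  shape$R0 * r
}

#' Closed-form area of a synthetic shape
#'
#' `pi * R0^2 * (1 + sum(a_k^2) / 2)`: the polar area integral of the
#' harmonic radial profile (cross terms vanish over a full period).
#'
#' @param shape A [synthetic_shape()].
#' @return Area in px^2.
#' @export
analytic_area <- function(shape) {
  pi * shape$R0^2 * (1 + sum(shape$harmonics$a^2) / 2)
}

#' Discretise a shape to a pixel point set
#'
#' Samples the boundary at `n_samples` uniform angles, rounds to integer
#' pixel coordinates and drops duplicates.
#'
#' @param shape A [synthetic_shape()] with `n_samples >= 3`.
#' @param meta A [faz_meta()] attached to the resulting point set.
#' @param round_px Round to integer pixels (default `TRUE`); `FALSE` keeps
#'   exact real-valued boundary samples.
#' @return A [point_set()].
#' @export
shape_to_points <- function(shape, meta = faz_meta(), round_px = TRUE) {
  stopifnot(inherits(shape, "faz_shape"))
  n <- shape$n_samples
  if (n < 3L) {
    faz_stop("faz_invalid_spec_error", "n_samples must be at least 3")
  }
  theta <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  r <- shape_radius(shape, theta)
  pts <- cbind(x = shape$centre[1] + r * cos(theta),
               y = shape$centre[2] + r * sin(theta))
  if (round_px) pts <- unique(round(pts))
  point_set(pts, meta = meta)
}

#' Cohort-level synthetic study specification
#'
#' Defines the shape-parameter distributions per patient cohort and the
#' factorial design (eyes x plexus x observers x series x criteria) of a
#' simulated segmentation study. Defaults mirror a study of 73 healthy, 40
#' type-1 and 54 type-2 diabetic eyes, both capillary plexuses, four
#' observers (one tracing two series) and two delimitation criteria; the
#' DM2 shape family is configured with the widest irregularity range,
#' reflecting the more disturbed retinas of that group.
#'
#' `R0` ranges are in pixels on the default 320 px / 3 mm grid; amplitudes
#' are uniform per harmonic within `amp_range`, with 2 or 3 harmonics of
#' order 2..6.
#'
#' @param cohorts Named list; one entry per cohort with elements `n_eyes`,
#'   `R0_range` (px) and `amp_range`.
#' @param observers Named list, one entry per observer letter, each with
#'   `series` (number of tracing series) and `bias` (named numeric,
#'   per-criterion radial bias overriding the template model's). The
#'   defaults spread the observer biases widely under `INITIAL` (each
#'   observer interprets the loose "region without vessels" definition
#'   differently, some hugging the enclosing vessels) and tightly around
#'   0.97 under `FINAL` (the common transition-zone criterion pulls
#'   observers together), which is what makes inter-observer variability
#'   drop under the final criterion.
#' @param plexus Character vector of plexus labels to simulate.
#' @param observer_models Named list `INITIAL`/`FINAL` of [observer_model()]
#'   templates supplying spike amplitude and noise per criterion.
#' @param width_mm Physical scan width (mm).
#' @param image_px Nominal image width/height in pixels (sets the pixel
#'   scale `width_mm / image_px`).
#' @param n_samples Angular samples per tracing.
#' @param seed Master seed; every record derives its own stream from it.
#' @return Object of class `faz_cohort_spec`.
#' @export
cohort_spec <- function(
    cohorts = list(
      HEALTHY = list(n_eyes = 73L, R0_range = c(18, 28), amp_range = c(0.02, 0.10)),
      DM1 = list(n_eyes = 40L, R0_range = c(16, 26), amp_range = c(0.03, 0.12)),
      DM2 = list(n_eyes = 54L, R0_range = c(16, 30), amp_range = c(0.05, 0.20))
    ),
    observers = list(
      C = list(series = 1L, bias = c(INITIAL = 1.06, FINAL = 0.96)),
      E = list(series = 1L, bias = c(INITIAL = 1.12, FINAL = 0.97)),
      G = list(series = 2L, bias = c(INITIAL = 1.16, FINAL = 0.98)),
      S = list(series = 1L, bias = c(INITIAL = 1.09, FINAL = 0.97))
    ),
    plexus = c("SCP", "DCP"),
    observer_models = list(INITIAL = observer_model("INITIAL"),
                           FINAL = observer_model("FINAL")),
    width_mm = 3, image_px = 320L, n_samples = 512L, seed = 1L) {
  if (!all(names(cohorts) %in% COHORT_LEVELS)) {
    faz_stop("faz_invalid_spec_error", sprintf(
      "cohort names must be among %s", paste(COHORT_LEVELS, collapse = ", ")))
  }
  for (nm in names(cohorts)) {
    co <- cohorts[[nm]]
    if (co$n_eyes < 1L || any(co$R0_range <= 0) || diff(co$R0_range) < 0 ||
        any(co$amp_range < 0) || diff(co$amp_range) < 0) {
      faz_stop("faz_invalid_spec_error",
               sprintf("invalid parameter ranges for cohort %s", nm))
    }
    # worst case: 3 harmonics at the top of the range must keep r > 0
    if (3 * max(co$amp_range) >= 1) {
      faz_stop("faz_invalid_spec_error", sprintf(
        "amplitude range for cohort %s allows sum(|a|) >= 1", nm))
    }
  }
  if (is.null(names(observers)) || !is.list(observers)) {
    faz_stop("faz_invalid_spec_error",
             "observers must be a named list of observer definitions")
  }
  for (nm in names(observers)) {
    ob <- observers[[nm]]
    if (is.null(ob$series) || ob$series < 1L) {
      faz_stop("faz_invalid_spec_error",
               sprintf("observer %s needs a series count >= 1", nm))
    }
    if (!is.null(ob$bias) && (is.null(names(ob$bias)) || any(ob$bias <= 0))) {
      faz_stop("faz_invalid_spec_error", sprintf(
        "observer %s bias must be a named positive vector", nm))
    }
  }
  if (!all(plexus %in% PLEXUS_LEVELS)) {
    faz_stop("faz_invalid_spec_error", "plexus entries must be SCP or DCP")
  }
  if (!all(c("INITIAL", "FINAL") %in% names(observer_models))) {
    faz_stop("faz_invalid_spec_error",
             "observer_models must contain INITIAL and FINAL entries")
  }
  structure(list(cohorts = cohorts, observers = observers, plexus = plexus,
                 observer_models = observer_models,
                 width_mm = as.numeric(width_mm),
                 image_px = as.integer(image_px),
                 n_samples = as.integer(n_samples),
                 seed = as.integer(seed)),
            class = "faz_cohort_spec")
}

#' Draw one ground-truth shape from a cohort's distribution
#'
#' `R0` is uniform over the cohort's `R0_range`; 2 or 3 harmonics are drawn
#' with orders sampled without replacement from 2..6, amplitudes uniform
#' over `amp_range`, and uniform phases. Deterministic given `seed`.
#'
#' @param spec A [cohort_spec()].
#' @param cohort Cohort name present in `spec$cohorts`.
#' @param seed Integer seed for this draw (default: from the spec master
#'   seed).
#' @return A [synthetic_shape()] centred in the nominal image.
#' @export
sample_shape <- function(spec, cohort, seed = spec$seed) {
  stopifnot(inherits(spec, "faz_cohort_spec"))
  co <- spec$cohorts[[cohort]]
  if (is.null(co)) {
    faz_stop("faz_invalid_spec_error",
             sprintf("cohort %s not present in the spec", cohort))
  }
  with_seed(seed, {
    R0 <- stats::runif(1, co$R0_range[1], co$R0_range[2])
    m <- sample(2:3, 1)
    ks <- sample(2:6, m)
    amps <- stats::runif(m, co$amp_range[1], co$amp_range[2])
    phis <- stats::runif(m, 0, 2 * pi)
    ctr <- (spec$image_px - 1) / 2
    synthetic_shape(R0, data.frame(k = ks, a = amps, phi = phis),
                    centre = c(ctr, ctr), n_samples = spec$n_samples)
  })
}
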