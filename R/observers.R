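# Observer tracing model
#
# A tracing perturbs the ground-truth radial profile multiplicatively:
#   r'(theta) = r(theta) * bias * (1 + spike(theta) + eps(theta)),
# where spike() is a high-frequency harmonic (order 15..40) mimicking the
# vessel-following scallops of tracings that hug the enclosing capillaries,
# and eps() is per-point Gaussian radial jitter. Under the INITIAL
# delimitation ("region without vessels") observers tend to follow the
# enclosing vessels: bias > 1 and a strong spike term. Under the FINAL
# delimitation (inner boundary of the vascular transition zone) tracings
# slightly enter the avascular core and are smoother: bias just below 1 and
# a weak spike term.

#' Observer tracing model
#'
#' @param criterion `"INITIAL"` or `"FINAL"`; sets the defaults below.
#' @param radial_bias Multiplicative radial offset. Default 1.12 for
#'   `INITIAL` (tracing along the enclosing vessels), 0.97 for `FINAL`
#'   (slightly inside the true boundary).
#' @param spike_amp Amplitude of the high-frequency vessel-following
#'   perturbation. Default 0.06 (`INITIAL`, spikier) / 0.02 (`FINAL`,
#'   smoother).
#' @param noise_sd Per-point radial jitter as a fraction of the radius
#'   (default 0.01).
#' @param seed RNG seed making the tracing reproducible.
#' @return Object of class `faz_observer_model`.
#' @export
observer_model <- function(criterion = c("INITIAL", "FINAL"),
                           radial_bias = NULL, spike_amp = NULL,
                           noise_sd = 0.01, seed = 1L) {
  criterion <- match.arg(criterion)
  radial_bias <- radial_bias %||% switch(criterion, INITIAL = 1.12, FINAL = 0.97)
  spike_amp <- spike_amp %||% switch(criterion, INITIAL = 0.06, FINAL = 0.02)
  if (radial_bias <= 0 || spike_amp < 0 || noise_sd < 0) {
    faz_stop("faz_invalid_spec_error",
             "need radial_bias > 0 and spike_amp, noise_sd >= 0")
  }
  structure(list(criterion = criterion, radial_bias = radial_bias,
                 spike_amp = spike_amp, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "faz_observer_model")
}

#' Simulate one observer tracing of a shape
#'
#' Samples the perturbed radial profile at the shape's angular grid, rounds
#' to pixels and returns the tracing as a [point_set()] carrying the model's
#' criterion in its metadata. Fully reproducible given `model$seed`.
#'
#' A model with `radial_bias = 1`, `spike_amp = 0` and `noise_sd = 0` is the
#' identity observer: it reproduces [shape_to_points()] exactly.
#'
#' @param shape A [synthetic_shape()].
#' @param model An [observer_model()].
#' @param meta A [faz_meta()] for the record; its `criterion` is overwritten
#'   with the model's.
#' @param round_px Round to integer pixels (default `TRUE`).
#' @return A [point_set()].
#' @export
simulate_observer_tracing <- function(shape, model, meta = faz_meta(),
                                      round_px = TRUE) {
  stopifnot(inherits(shape, "faz_shape"), inherits(model, "faz_observer_model"))
  n <- shape$n_samples
  theta <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  r <- shape_radius(shape, theta)
  perturb <- with_seed(model$seed, {
    spike <- if (model$spike_amp > 0) {
      k <- sample(15:40, 1)
      phi <- stats::runif(1, 0, 2 * pi)
      model$spike_amp * cos(k * theta + phi)
    } else {
      0
    }
    eps <- if (model$noise_sd > 0) stats::rnorm(n, 0, model$noise_sd) else 0
    spike + eps
  })
  r2 <- r * model$radial_bias * (1 + perturb)
  pts <- cbind(x = shape$centre[1] + r2 * cos(theta),
               y = shape$centre[2] + r2 * sin(theta))
  if (round_px) pts <- unique(round(pts))
  meta$criterion <- model$criterion
  point_set(pts, meta = meta)
}
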