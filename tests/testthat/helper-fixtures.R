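# In-code fixtures shared across test files.

unit_square_ps <- function() {
  point_set(rbind(c(1, 1), c(0, 0), c(1, 0), c(0, 1)))
}

# Grey 64x64 image carrying a contiguous horizontal run of n_overlay pixels
# in the given colour (one connected component).
tiny_overlay_image <- function(colour = c(255, 0, 0), n_overlay = 12L,
                               meta = faz_meta()) {
  px <- array(128, dim = c(64, 64, 3))
  xs <- seq(10, length.out = n_overlay)
  ys <- rep(32L, n_overlay)
  for (ch in 1:3) px[cbind(ys + 1, xs + 1, ch)] <- colour[ch]
  list(image = annotated_image(px, meta = meta), x = xs, y = ys)
}

# A small two-criterion cohort spec used by several tests.
small_spec <- function(seed = 7L, n_eyes = 2L, image_px = 128L) {
  cohort_spec(
    cohorts = list(
      HEALTHY = list(n_eyes = n_eyes, R0_range = c(18, 26),
                     amp_range = c(0.02, 0.10)),
      DM2 = list(n_eyes = n_eyes, R0_range = c(16, 28),
                 amp_range = c(0.05, 0.18))
    ),
    observers = list(
      A = list(series = 1L, bias = c(INITIAL = 1.08, FINAL = 0.96)),
      B = list(series = 2L, bias = c(INITIAL = 1.15, FINAL = 0.98))
    ),
    image_px = image_px, n_samples = 360L, seed = seed
  )
}
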