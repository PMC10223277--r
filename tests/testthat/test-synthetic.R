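test_that("synthetic shapes validate their invariants", {
  expect_error(synthetic_shape(-1), class = "faz_invalid_spec_error")
  expect_error(synthetic_shape(10, data.frame(k = 1, a = 0.1, phi = 0)),
               class = "faz_invalid_spec_error")
  expect_error(
    synthetic_shape(10, data.frame(k = c(2, 3), a = c(0.6, 0.5),
                                   phi = c(0, 0))),
    class = "faz_invalid_spec_error"
  )
  circ <- synthetic_shape(10)
  expect_equal(analytic_area(circ), pi * 100)
  h <- data.frame(k = c(2, 5), a = c(0.1, 0.05), phi = c(0, 1))
  expect_equal(analytic_area(synthetic_shape(10, h)),
               pi * 100 * (1 + (0.01 + 0.0025) / 2))
})

test_that("sample_shape is deterministic and respects degenerate ranges", {
  spec <- cohort_spec(
    cohorts = list(HEALTHY = list(n_eyes = 1L, R0_range = c(20, 20),
                                  amp_range = c(0, 0))),
    seed = 5L
  )
  s1 <- sample_shape(spec, "HEALTHY", seed = 99L)
  s2 <- sample_shape(spec, "HEALTHY", seed = 99L)
  expect_identical(s1, s2)
  expect_equal(s1$R0, 20)
  expect_equal(analytic_area(s1), pi * 400)  # zero amplitudes: a circle
  expect_error(sample_shape(spec, "DM1"), class = "faz_invalid_spec_error")
  expect_error(
    cohort_spec(cohorts = list(HEALTHY = list(
      n_eyes = 1L, R0_range = c(20, 20), amp_range = c(0.3, 0.4)
    ))),
    class = "faz_invalid_spec_error"
  )
})

test_that("sampled analytic areas match their Monte-Carlo expectation", {
  spec <- cohort_spec(seed = 13L)
  co <- spec$cohorts$HEALTHY
  areas <- sapply(1:500, function(i) {
    analytic_area(sample_shape(spec, "HEALTHY", seed = i))
  })
  # closed-form expectation over the uniform draws: R0 ~ U(lo, hi),
  # m ~ U{2,3} harmonics, a_j ~ U(alo, ahi), independent
  ER2 <- (co$R0_range[1]^2 + prod(co$R0_range) + co$R0_range[2]^2) / 3
  Ea2 <- (co$amp_range[1]^2 + prod(co$amp_range) + co$amp_range[2]^2) / 3
  expected <- pi * ER2 * (1 + 0.5 * 2.5 * Ea2)
  se <- sd(areas) / sqrt(length(areas))
  expect_lt(abs(mean(areas) - expected), 4 * se)
})

test_that("shape_to_points recovers analytic ground truth downstream", {
  sh <- synthetic_shape(100, centre = c(160, 160), n_samples = 2000L)
  m <- compute_metrics(shape_to_points(sh), scale = pixel_scale(1))
  expect_equal(m$area_px2, pi * 1e4, tolerance = 0.01)

  harm <- synthetic_shape(100, data.frame(k = 5, a = 0.1, phi = 0.3),
                          centre = c(160, 160), n_samples = 2000L)
  mh <- compute_metrics(shape_to_points(harm), scale = pixel_scale(1))
  expect_lt(abs(mh$acircularity - 0.1 / sqrt(2)), 5e-3)  # absolute band

  tiny <- synthetic_shape(10, centre = c(16, 16), n_samples = 3L)
  expect_equal(nrow(shape_to_points(tiny)$points), 3L)

  set.seed(31)
  for (i in 1:20) {
    sh <- random_shape(n_samples = 2000L)
    m <- compute_metrics(shape_to_points(sh), scale = pixel_scale(1))
    expect_equal(m$area_px2, analytic_area(sh), tolerance = 0.01)
  }
})

test_that("the identity observer reproduces the raw discretised shape", {
  sh <- random_shape(n_samples = 400L)
  id <- observer_model("INITIAL", radial_bias = 1, spike_amp = 0,
                       noise_sd = 0)
  traced <- simulate_observer_tracing(sh, id)
  expect_equal(traced$points, shape_to_points(sh)$points)
  expect_identical(traced$meta$criterion, "INITIAL")
})

test_that("final-criterion tracings are smaller than initial ones", {
  set.seed(17)
  smaller <- logical(200)
  for (i in 1:200) {
    sh <- random_shape(n_samples = 360L)
    mi <- observer_model("INITIAL", seed = 1000L + i)
    mf <- observer_model("FINAL", seed = 2000L + i)
    ai <- shoelace_area(sort_by_azimuth(simulate_observer_tracing(sh, mi)))
    af <- shoelace_area(sort_by_azimuth(simulate_observer_tracing(sh, mf)))
    smaller[i] <- af < ai
  }
  expect_gte(sum(smaller), 195L)
})

test_that("observers with the same model are exchangeable", {
  set.seed(29)
  d <- numeric(200)
  for (i in 1:200) {
    sh <- random_shape(n_samples = 360L)
    m1 <- observer_model("FINAL", seed = 3000L + i)
    m2 <- observer_model("FINAL", seed = 4000L + i)
    p1 <- simulate_observer_tracing(sh, m1)
    p2 <- simulate_observer_tracing(sh, m2)
    expect_false(identical(p1$points, p2$points))  # seeds change the line
    d[i] <- shoelace_area(sort_by_azimuth(p1)) -
      shoelace_area(sort_by_azimuth(p2))
  }
  expect_gt(t.test(d)$p.value, 0.01)  # but no systematic area difference
})

test_that("generate_cohort expands the factorial design deterministically", {
  spec <- cohort_spec(
    cohorts = list(HEALTHY = list(n_eyes = 2L, R0_range = c(18, 24),
                                  amp_range = c(0.02, 0.08))),
    observers = list(A = list(series = 1L), B = list(series = 1L)),
    image_px = 128L, n_samples = 180L, seed = 21L
  )
  co <- generate_cohort(spec)
  expect_length(co$records, 2L * 2L * 2L * 1L * 2L)  # eyes x plexus x obs x series x crit
  co2 <- generate_cohort(spec)
  expect_identical(co$records, co2$records)
  expect_identical(co$ground_truth, co2$ground_truth)

  # growing the design leaves shared records untouched (per-record streams)
  spec4 <- spec
  spec4$cohorts$HEALTHY$n_eyes <- 4L
  co4 <- generate_cohort(spec4)
  for (key in names(co$records)) {
    expect_identical(co4$records[[key]]$points, co$records[[key]]$points)
  }
})

test_that("rendering options behave and bound the extracted area", {
  sh <- synthetic_shape(25, data.frame(k = 3, a = 0.08, phi = 0.5),
                        centre = c(47.5, 47.5), n_samples = 720L)
  expect_error(
    extract_overlay(render_annotated(sh, line_thickness = 0, size = 96)),
    class = "faz_no_overlay_error"
  )
  a1 <- compute_metrics(extract_overlay(render_annotated(sh, size = 96)),
                        scale = pixel_scale(1))
  a3 <- compute_metrics(
    extract_overlay(render_annotated(sh, line_thickness = 3, size = 96)),
    scale = pixel_scale(1)
  )
  # thickening the ring by 1 px on each side moves the measured polygon by
  # at most a one-pixel band around the perimeter
  perim <- 2 * pi * a1$mean_radius_px
  expect_lt(abs(a3$area_px2 - a1$area_px2), perim * 2)
  expect_error(render_annotated(synthetic_shape(30, centre = c(5, 5))),
               class = "faz_out_of_bounds_error")
})
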