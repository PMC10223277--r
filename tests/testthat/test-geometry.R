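test_that("azimuth sort orders a convex quadrilateral and is stable", {
  ct <- sort_by_azimuth(unit_square_ps())
  expect_equal(unname(ct$points),
               rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)))
  # already-sorted input comes back in the same cyclic order
  ct2 <- sort_by_azimuth(point_set(ct$points))
  expect_equal(ct2$points, ct$points)
})

test_that("azimuth sort rejects degenerate inputs", {
  expect_error(sort_by_azimuth(point_set(rbind(c(0, 0), c(1, 1)))),
               class = "faz_degenerate_contour_error")
  expect_error(sort_by_azimuth(point_set(cbind(0:5, 0:5))),
               class = "faz_degenerate_contour_error")
})

test_that("shoelace area matches closed forms and the polyarea oracle", {
  expect_equal(shoelace_area(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))), 1)
  expect_equal(shoelace_area(rbind(c(0, 0), c(1, 1), c(2, 2))), 0)
  for (n in c(3, 8, 60, 360)) {
    th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
    poly <- cbind(100 * cos(th), 100 * sin(th))
    closed_form <- 0.5 * n * 100^2 * sin(2 * pi / n)
    expect_equal(shoelace_area(poly), closed_form, tolerance = 1e-12)
    expect_equal(shoelace_area(poly), polyarea_oracle(poly),
                 tolerance = 1e-12)
  }
  expect_error(shoelace_area(rbind(c(0, 0), c(1, 0))),
               class = "faz_degenerate_contour_error")
})

test_that("azimuth sort + shoelace equals convex-hull area on convex inputs", {
  set.seed(11)
  for (i in 1:20) {
    a <- runif(1, 10, 60)
    b <- runif(1, 10, 60)
    phi <- runif(1, 0, pi)
    th <- sort(runif(200, 0, 2 * pi))
    pts <- cbind(a * cos(th) * cos(phi) - b * sin(th) * sin(phi) + 80,
                 a * cos(th) * sin(phi) + b * sin(th) * cos(phi) + 80)
    area <- shoelace_area(sort_by_azimuth(point_set(pts)))
    expect_equal(area, hull_area_oracle(pts), tolerance = 1e-9)
  }
})

test_that("pixel scale conversion is plain multiplication", {
  sc <- pixel_scale(3 / 320)
  expect_equal(to_mm2(10000, sc), 10000 * (3 / 320)^2)
  expect_equal(to_mm2(0, sc), 0)
  expect_equal(to_mm2(123.4, pixel_scale(1)), 123.4)
  aniso <- pixel_scale(3 / 320, 3 / 240)
  expect_equal(to_mm2(100, aniso), 100 * (3 / 320) * (3 / 240))
  expect_error(pixel_scale(0), class = "faz_invalid_spec_error")
  meta <- faz_meta(image_cols = 320L, image_rows = 240L, width_mm = 3)
  sc2 <- scale_from_meta(meta)
  expect_equal(sc2$mm_per_px_x, 3 / 320)
  expect_equal(sc2$mm_per_px_y, 3 / 240)
})

test_that("centre and radial coordinates follow their definitions", {
  ct <- sort_by_azimuth(unit_square_ps())
  expect_equal(contour_centre(ct), c(x = 0.5, y = 0.5))
  expect_equal(radial_coordinates(ct), rep(sqrt(0.5), 4))
  expect_equal(contour_centre(rbind(c(0, 0), c(3, 0), c(0, 3))),
               c(x = 1, y = 1))
  expect_equal(radial_coordinates(rbind(c(0, 0), c(4, 0)), centre = c(0, 0)),
               c(0, 4))
  th <- seq(0, 2 * pi, length.out = 1001)[-1001]
  circ <- cbind(7 + 3 * cos(th), -2 + 3 * sin(th))
  expect_equal(contour_centre(circ), c(x = 7, y = -2), tolerance = 1e-9)
  expect_equal(radial_coordinates(circ, c(7, -2)), rep(3, 1000),
               tolerance = 1e-9)
})

test_that("acircularity is zero for a circle and matches the dense oracle", {
  th <- seq(0, 2 * pi, length.out = 361)[-361]
  circ <- point_set(cbind(50 * cos(th), 50 * sin(th)))
  expect_lt(acircularity(sort_by_azimuth(circ)), 1e-12)

  # single harmonic: continuum value a / sqrt(2)
  h <- data.frame(k = 5, a = 0.1, phi = 0)
  sh <- synthetic_shape(100, h, n_samples = 2000L)
  ac <- acircularity(sort_by_azimuth(shape_to_points(sh, round_px = FALSE)))
  expect_equal(ac, 0.1 / sqrt(2), tolerance = 1e-3)

  # ellipse versus the independent point-cloud oracle
  th <- seq(0, 2 * pi, length.out = 2001)[-2001]
  ell <- cbind(2 * cos(th), sin(th))
  ac_main <- acircularity(sort_by_azimuth(point_set(ell)))
  expect_equal(ac_main, acirc_points_oracle(ell), tolerance = 1e-6)
})

test_that("acircularity SD divisor options agree with stats::sd", {
  pts <- random_contour_points(n_samples = 100L)
  ct <- sort_by_azimuth(point_set(pts))
  r <- radial_coordinates(ct)
  expect_equal(acircularity(ct, sd_divisor = "n-1"), sd(r) / mean(r))
  n <- length(r)
  expect_equal(acircularity(ct), sd(r) * sqrt((n - 1) / n) / mean(r))
  same <- matrix(rep(c(2, 3), each = 4), ncol = 2)
  expect_error(acircularity(same), class = "faz_zero_radius_error")
})

test_that("area and acircularity are invariant under rigid motions and scale covariant", {
  set.seed(23)
  for (i in 1:50) {
    pts <- random_contour_points(n_samples = sample(60:300, 1))
    ct <- sort_by_azimuth(point_set(pts))
    a0 <- shoelace_area(ct)
    c0 <- acircularity(ct)
    # translation
    tr <- sort_by_azimuth(point_set(sweep(pts, 2, runif(2, -500, 500), "+")))
    expect_equal(shoelace_area(tr), a0, tolerance = 1e-9)
    expect_equal(acircularity(tr), c0, tolerance = 1e-9)
    # rotation
    ang <- runif(1, 0, 2 * pi)
    rot <- pts %*% rbind(c(cos(ang), sin(ang)), c(-sin(ang), cos(ang)))
    rot <- sort_by_azimuth(point_set(rot))
    expect_equal(shoelace_area(rot), a0, tolerance = 1e-9)
    expect_equal(acircularity(rot), c0, tolerance = 1e-9)
    # uniform scaling
    s <- runif(1, 0.2, 5)
    sc <- sort_by_azimuth(point_set(pts * s))
    expect_equal(shoelace_area(sc), a0 * s^2, tolerance = 1e-9)
    expect_equal(acircularity(sc), c0, tolerance = 1e-9)
  }
})

test_that("inscribed polygon area converges to pi r^2 at second order", {
  r <- 50
  err <- sapply(c(90, 360, 1440), function(n) {
    th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
    abs(shoelace_area(cbind(r * cos(th), r * sin(th))) - pi * r^2)
  })
  expect_lt(err[2], err[1] / 2)
  expect_lt(err[3], err[2] / 2)
})

test_that("acircularity increases with harmonic amplitude", {
  vals <- sapply(c(0.02, 0.05, 0.1, 0.2), function(a) {
    sh <- synthetic_shape(100, data.frame(k = 4, a = a, phi = 0),
                          n_samples = 2000L)
    acircularity(sort_by_azimuth(shape_to_points(sh, round_px = FALSE)))
  })
  expect_true(all(diff(vals) > 0))
})

test_that("compute_metrics ties the chain together consistently", {
  m <- compute_metrics(unit_square_ps(), scale = pixel_scale(1))
  expect_equal(m$area_mm2, 1)
  expect_equal(m$acircularity, 0)
  expect_true(m$star_shaped)
  expect_equal(m$acircularity, m$radial_sd_px / m$mean_radius_px)

  # rendered circle of radius 50 px at the 3 mm / 320 px device scale
  sh <- synthetic_shape(50, centre = c(80, 80), n_samples = 2000L)
  ps <- shape_to_points(sh)
  mc <- compute_metrics(ps, scale = pixel_scale(3 / 320))
  expect_equal(mc$area_mm2, pi * 50^2 * (3 / 320)^2, tolerance = 0.02)

  # integer translation leaves every metric unchanged
  ps2 <- point_set(sweep(ps$points, 2, c(17, -9), "+"), meta = ps$meta)
  m2 <- compute_metrics(ps2, scale = pixel_scale(3 / 320))
  expect_equal(m2$area_mm2, mc$area_mm2)
  expect_equal(m2$acircularity, mc$acircularity)
})

test_that("the star-shapedness diagnostic flags boundaries that double back", {
  # a thick ring is still star-shaped
  sh <- synthetic_shape(30, centre = c(47.5, 47.5), n_samples = 720L)
  img <- render_annotated(sh, background = "flat", line_thickness = 3,
                          size = 96)
  m <- compute_metrics(extract_overlay(img), scale = pixel_scale(1))
  expect_true(m$star_shaped)

  # a crescent doubles back: widely separated radii share an azimuth
  th_out <- seq(-2.2, 2.2, length.out = 200)
  th_in <- seq(-2, 2, length.out = 160)
  cres <- rbind(cbind(30 * cos(th_out), 30 * sin(th_out)),
                cbind(14 * cos(rev(th_in)), 14 * sin(rev(th_in))))
  mc <- compute_metrics(point_set(unique(round(cres))),
                        scale = pixel_scale(1))
  expect_false(mc$star_shaped)
})

test_that("metrics_table emits one tidy row per segmentation", {
  ps <- shape_to_points(random_shape(), meta = faz_meta(eye_id = "E1"))
  tab <- metrics_table(list(ps, ps), scale = pixel_scale(1))
  expect_equal(nrow(tab), 2L)
  expect_true(all(c("eye_id", "plexus", "cohort", "observer", "series",
                    "criterion", "n_points", "centre_x", "centre_y",
                    "mean_radius_px", "radial_sd_px", "acircularity",
                    "area_px2", "area_mm2", "star_shaped") %in% names(tab)))
})
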