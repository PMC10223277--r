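#' Render a synthetic annotated OCTA-like image
#'
#' Produces an 8-bit RGB image emulating an en-face OCTA slab with a drawn
#' FAZ perimeter: a dark avascular core inside the boundary, a bright
#' filamentary vessel texture outside, a smooth transition band between them
#' (vascular signal fades rather than switching abruptly), and the perimeter
#' line stamped in `line_colour` at the requested thickness.
#'
#' @param x A [synthetic_shape()] or a [point_set()]. For a point set the
#'   radial profile used by the vessel background is interpolated from the
#'   azimuth-sorted points.
#' @param background `"vessels"` (procedural texture, default) or `"flat"`
#'   (uniform grey).
#' @param line_colour RGB triple in 0..255 for the perimeter (default pure
#'   red).
#' @param line_thickness Odd stamp width in pixels; `0` draws no line.
#' @param size Image rows = cols in pixels; default chosen to contain the
#'   shape plus an 8 px margin (or taken from the point-set metadata).
#' @param transition_px Width of the avascular-to-vascular transition band.
#' @param meta A [faz_meta()] for the image (point-set input carries its
#'   own).
#' @param seed Seed for the background texture noise.
#' @return A [annotated_image()].
#' @export
render_annotated <- function(x, background = c("vessels", "flat"),
                             line_colour = c(255, 0, 0), line_thickness = 1L,
                             size = NULL, transition_px = 6,
                             meta = NULL, seed = 1L) {
  background <- match.arg(background)
  line_thickness <- as.integer(line_thickness)
  if (line_thickness < 0L) {
    faz_stop("faz_invalid_spec_error", "line_thickness must be >= 0")
  }

  if (inherits(x, "faz_shape")) {
    meta <- meta %||% faz_meta()
    rmax <- x$R0 * (1 + sum(abs(x$harmonics$a)))
    if (is.null(size)) size <- ceiling(max(x$centre) + rmax + 8) + 1
    if (any(x$centre - rmax < 1) || any(x$centre + rmax > size - 2)) {
      faz_stop("faz_out_of_bounds_error",
               "shape does not fit in the image with a 1 px margin")
    }
    prof <- function(theta) shape_radius(x, theta)
    ctr <- x$centre
    m <- max(2048L, 4L * x$n_samples)
    theta <- seq(0, 2 * pi, length.out = m + 1L)[-(m + 1L)]
    line_pts <- unique(round(cbind(ctr[1] + prof(theta) * cos(theta),
                                   ctr[2] + prof(theta) * sin(theta))))
  } else if (inherits(x, "faz_pointset")) {
    meta <- meta %||% x$meta
    contour <- sort_by_azimuth(x)
    ctr <- contour_centre(contour)
    az <- atan2(contour$points[, "y"] - ctr[2], contour$points[, "x"] - ctr[1])
    rr <- radial_coordinates(contour, ctr)
    o <- order(az)
    az_s <- az[o]
    rr_s <- rr[o]
    prof <- function(theta) {
      th <- ((theta + pi) %% (2 * pi)) - pi
      stats::approx(c(az_s - 2 * pi, az_s, az_s + 2 * pi), rep(rr_s, 3),
                    xout = th, rule = 2, ties = mean)$y
    }
    rmax <- max(rr)
    if (is.null(size)) size <- ceiling(max(x$points) + 8) + 1
    if (min(x$points) < 0 || max(x$points) > size - 1) {
      faz_stop("faz_out_of_bounds_error", "points do not fit in the image")
    }
    line_pts <- unique(round(x$points))
  } else {
    faz_stop("faz_invalid_spec_error",
             "x must be a faz_shape or a faz_pointset")
  }
  size <- as.integer(size)
  if (size < 8L) {
    faz_stop("faz_invalid_spec_error", "image must be at least 8 x 8")
  }

  # background intensity field (row-major grids; x = col - 1, y = row - 1)
  X <- matrix(rep(0:(size - 1L), each = size), nrow = size)
  Y <- matrix(rep(0:(size - 1L), times = size), nrow = size)
  if (background == "vessels") {
    dx <- X - ctr[1]
    dy <- Y - ctr[2]
    rho <- sqrt(dx^2 + dy^2)
    rb <- matrix(prof(atan2(dy, dx)), nrow = size)
    mix <- 1 / (1 + exp(-(rho - rb) / pmax(transition_px / 4, 0.5)))
    tex <- with_seed(seed, {
      fil <- sin(0.9 * X + 2.6 * sin(0.11 * Y + 1.3)) *
        sin(0.9 * Y + 2.6 * sin(0.13 * X))
      0.45 + 0.28 * fil + matrix(stats::rnorm(size^2, 0, 0.04), nrow = size)
    })
    grey <- (1 - mix) * 0.05 + mix * pmin(pmax(tex, 0.05), 0.95)
  } else {
    grey <- matrix(0.5, size, size)
  }
  px <- array(pmin(pmax(round(grey * 255), 0), 255), dim = c(size, size, 3))

  # stamp the perimeter line
  if (line_thickness > 0L) {
    half <- (line_thickness - 1L) %/% 2L
    offs <- expand.grid(dx = -half:half, dy = -half:half)
    for (i in seq_len(nrow(offs))) {
      cx <- line_pts[, 1] + offs$dx[i]
      cy <- line_pts[, 2] + offs$dy[i]
      keep <- cx >= 0 & cx < size & cy >= 0 & cy < size
      rows <- cy[keep] + 1L
      cols <- cx[keep] + 1L
      for (ch in 1:3) {
        px[cbind(rows, cols, ch)] <- line_colour[ch]
      }
    }
  }
  annotated_image(px, meta = meta)
}
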