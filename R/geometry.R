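#' Azimuth-ordered closed contour
#'
#' An ordered boundary: the point list is sorted by azimuth about the
#' centroid of the input points and treated as closed (last vertex connects
#' back to the first). Built by [sort_by_azimuth()].
#'
#' @name faz_contour
#' @keywords internal
NULL

new_contour <- function(pts, meta) {
  structure(list(points = pts, meta = meta), class = "faz_contour")
}

#' @export
print.faz_contour <- function(x, ...) {
  cat(sprintf("<faz_contour> %d ordered points | eye %s %s %s\n",
              nrow(x$points), x$meta$eye_id, x$meta$cohort, x$meta$plexus))
  invisible(x)
}

#' Order contour points by azimuth about their centroid
#'
#' Converts the Cartesian point locations to polar coordinates about the
#' centroid of the input and sorts by azimuth, yielding a closed polygon.
#' Ties in azimuth (frequent for lines thicker than 1 px, where several
#' pixels share an angle) are broken by ascending radius, which keeps
#' near-duplicate ring pixels adjacent instead of creating long chords. The
#' first vertex is the one with the smallest azimuth in (-pi, pi].
#'
#' The ordering reconstructs the drawn curve exactly when the boundary is
#' star-shaped about its centroid (every boundary point visible from the
#' centre); for other inputs it silently measures a different polygon, so
#' [compute_metrics()] attaches a diagnostic flag for point sets that look
#' non-star-shaped.
#'
#' @param points A [point_set()] (or anything [point_set()] accepts) with at
#'   least 3 distinct, non-collinear points.
#' @return A `faz_contour` with the same multiset of points, ordered.
#' @export
sort_by_azimuth <- function(points) {
  if (!inherits(points, "faz_pointset")) points <- point_set(points)
  pts <- points$points
  if (nrow(unique(pts)) < 3L) {
    faz_stop("faz_degenerate_contour_error",
             "need at least 3 distinct points to form a contour")
  }
  ctr <- colMeans(pts)
  dx <- pts[, "x"] - ctr[1]
  dy <- pts[, "y"] - ctr[2]
  ref <- which.max(dx^2 + dy^2)
  cross <- dx * dy[ref] - dy * dx[ref]
  if (all(abs(cross) < 1e-9 * max(1, dx[ref]^2 + dy[ref]^2))) {
    faz_stop("faz_degenerate_contour_error", "all points are collinear")
  }
  az <- atan2(dy, dx)
  r <- sqrt(dx^2 + dy^2)
  new_contour(pts[order(az, r), , drop = FALSE], points$meta)
}

#' Polygon area by the shoelace (Gauss) method
#'
#' Absolute value of the signed shoelace sum over the closed vertex cycle,
#' in squared pixel units; orientation-independent.
#'
#' @param contour A `faz_contour` from [sort_by_azimuth()] (a plain ordered
#'   two-column matrix is also accepted and used as-is).
#' @return Area in px^2.
#' @export
shoelace_area <- function(contour) {
  pts <- if (inherits(contour, "faz_contour")) contour$points else
    as.matrix(contour)
  n <- nrow(pts)
  if (is.null(n) || n < 3L) {
    faz_stop("faz_degenerate_contour_error",
             "need at least 3 points for a polygon area")
  }
  x <- pts[, 1]
  y <- pts[, 2]
  nxt <- c(2:n, 1L)
  abs(sum((y + y[nxt]) * (x - x[nxt]))) / 2
}

#' Pixel scale of an OCTA scan
#'
#' Physical length per pixel step along columns and rows. The default
#' construction divides the scan width by the pixel count per axis (3 mm
#' field over the image width); anisotropic scales are supported because
#' exported images need not be square.
#'
#' @param mm_per_px_x,mm_per_px_y Length (mm) per column / row step.
#' @return Object of class `faz_scale`.
#' @export
pixel_scale <- function(mm_per_px_x, mm_per_px_y = mm_per_px_x) {
  if (!is.finite(mm_per_px_x) || !is.finite(mm_per_px_y) ||
      mm_per_px_x <= 0 || mm_per_px_y <= 0) {
    faz_stop("faz_invalid_spec_error", "pixel scale must be strictly positive")
  }
  structure(list(mm_per_px_x = as.numeric(mm_per_px_x),
                 mm_per_px_y = as.numeric(mm_per_px_y)),
            class = "faz_scale")
}

#' Default pixel scale from image metadata
#'
#' `width_mm / image_cols` per column step and `width_mm / image_rows` per
#' row step.
#'
#' @param meta A [faz_meta()] with `image_cols`/`image_rows` set.
#' @return A [pixel_scale()].
#' @export
scale_from_meta <- function(meta) {
  if (is.na(meta$image_cols) || is.na(meta$image_rows)) {
    faz_stop("faz_metadata_error",
             "image dimensions unknown; cannot derive a pixel scale")
  }
  pixel_scale(meta$width_mm / meta$image_cols, meta$width_mm / meta$image_rows)
}

#' Convert a pixel area to square millimetres
#'
#' @param area_px2 Area in px^2 (>= 0).
#' @param scale A [pixel_scale()].
#' @return Area in mm^2: `area_px2 * mm_per_px_x * mm_per_px_y`.
#' @export
to_mm2 <- function(area_px2, scale) {
  stopifnot(inherits(scale, "faz_scale"))
  if (any(area_px2 < 0)) {
    faz_stop("faz_invalid_spec_error", "area_px2 must be >= 0")
  }
  area_px2 * scale$mm_per_px_x * scale$mm_per_px_y
}

#' Geometric centre of a contour
#'
#' Arithmetic mean of the x and y coordinates of all perimeter points (the
#' perimeter-point centroid, not the area centroid).
#'
#' @param contour A `faz_contour` (or two-column matrix).
#' @return Named numeric vector `c(x, y)`.
#' @export
contour_centre <- function(contour) {
  pts <- if (inherits(contour, "faz_contour")) contour$points else
    as.matrix(contour)
  c(x = mean(pts[, 1]), y = mean(pts[, 2]))
}

#' Radial coordinates of contour points
#'
#' Euclidean distance from `centre` to every contour point, in contour
#' order.
#'
#' @param contour A `faz_contour` (or two-column matrix).
#' @param centre Numeric `(x, y)`; default the [contour_centre()].
#' @return Numeric vector of radii, same length and order as the contour.
#' @export
radial_coordinates <- function(contour, centre = contour_centre(contour)) {
  pts <- if (inherits(contour, "faz_contour")) contour$points else
    as.matrix(contour)
  if (anyNA(centre) || any(!is.finite(centre))) {
    faz_stop("faz_invalid_spec_error", "centre must be finite")
  }
  sqrt((pts[, 1] - centre[1])^2 + (pts[, 2] - centre[2])^2)
}

#' Acircularity of a closed contour
#'
#' The coefficient of variation of the radial coordinates about the contour
#' centre: `sigma(R) / Rbar`, where `Rbar` is the mean distance from the
#' perimeter-point centroid to the N contour points and `sigma(R)` their
#' standard deviation. A perfect circle has acircularity 0 (every point sits
#' at the constant radius); irregular contours score higher, and values
#' above 0.5 indicate a very irregular boundary. Dimensionless, and
#' invariant to translation, rotation and uniform scaling.
#'
#' `sigma(R)` uses the population divisor N by default, matching the 1/N
#' structure of the mean; the sample (N-1) form is available via
#' `sd_divisor = "n-1"`.
#'
#' @param contour A `faz_contour` (or two-column matrix of ordered points).
#' @param sd_divisor `"n"` (population, default) or `"n-1"` (sample).
#' @return Non-negative scalar.
#' @export
acircularity <- function(contour, sd_divisor = c("n", "n-1")) {
  sd_divisor <- match.arg(sd_divisor)
  r <- radial_coordinates(contour)
  rbar <- mean(r)
  if (rbar <= 0 || all(r == 0)) {
    faz_stop("faz_zero_radius_error",
             "all points coincide with the centre; acircularity undefined")
  }
  n <- length(r)
  sig <- if (sd_divisor == "n") {
    sqrt(sum((r - rbar)^2) / n)
  } else {
    stats::sd(r)
  }
  sig / rbar
}

# TRUE when the point set is consistent with a star-shaped boundary about
# its centroid, the condition under which the azimuth sort reconstructs the
# drawn curve. Azimuth is binned into sectors and the radial spread within
# each sector is compared with what a drawn line of a few pixels' thickness
# can produce: a boundary that doubles back (non-star-shaped, e.g. a
# crescent) puts widely separated radii at the same azimuth. Heuristic; the
# flag marks metrics to be read with care rather than failing the record.
star_shaped <- function(contour, thickness_allow = 6) {
  pts <- contour$points
  n <- nrow(pts)
  if (n < 24L) return(TRUE)
  ctr <- contour_centre(contour)
  az <- atan2(pts[, 2] - ctr[2], pts[, 1] - ctr[1])
  r <- radial_coordinates(contour, ctr)
  nbins <- max(8L, min(64L, n %/% 8L))
  bin <- findInterval(az, seq(-pi, pi, length.out = nbins + 1L),
                      all.inside = TRUE)
  spread <- tapply(r, bin, function(v) diff(range(v)))
  tol <- max(thickness_allow, 0.2 * mean(r))
  sum(spread > tol, na.rm = TRUE) < 2L
}

#' Full morphometry of one segmentation
#'
#' Runs the measurement chain on a raw point set: azimuthal ordering,
#' perimeter-point centre, radial coordinates, acircularity, shoelace area,
#' and physical-unit conversion.
#'
#' @param points A [point_set()].
#' @param scale A [pixel_scale()]; default derived from the point set's
#'   metadata via [scale_from_meta()].
#' @param sd_divisor Passed to [acircularity()].
#' @return Object of class `faz_metrics`: list with `centre`,
#'   `mean_radius_px`, `radial_sd_px`, `acircularity`, `area_px2`,
#'   `area_mm2`, `n_points`, `star_shaped` and the input `meta`.
#'   `as.data.frame()` turns it (or a list of them) into the tidy one-row
#'   per-segmentation table.
#' @export
compute_metrics <- function(points, scale = NULL,
                            sd_divisor = c("n", "n-1")) {
  sd_divisor <- match.arg(sd_divisor)
  if (!inherits(points, "faz_pointset")) points <- point_set(points)
  if (is.null(scale)) scale <- scale_from_meta(points$meta)
  contour <- sort_by_azimuth(points)
  ctr <- contour_centre(contour)
  r <- radial_coordinates(contour, ctr)
  rbar <- mean(r)
  acirc <- acircularity(contour, sd_divisor = sd_divisor)
  sig <- acirc * rbar
  a_px2 <- shoelace_area(contour)
  structure(list(
    centre = ctr,
    mean_radius_px = rbar,
    radial_sd_px = sig,
    acircularity = acirc,
    area_px2 = a_px2,
    area_mm2 = to_mm2(a_px2, scale),
    n_points = nrow(contour$points),
    star_shaped = star_shaped(contour),
    meta = points$meta
  ), class = "faz_metrics")
}

#' @export
print.faz_metrics <- function(x, ...) {
  cat(sprintf(
    "<faz_metrics> area %.4f mm^2 (%.1f px^2), acircularity %.4f, N = %d%s\n",
    x$area_mm2, x$area_px2, x$acircularity, x$n_points,
    if (x$star_shaped) "" else " [non-star-shaped]"
  ))
  invisible(x)
}

#' @export
as.data.frame.faz_metrics <- function(x, ...) {
  cbind(
    meta_as_row(x$meta),
    data.frame(
      n_points = x$n_points, centre_x = unname(x$centre["x"]),
      centre_y = unname(x$centre["y"]), mean_radius_px = x$mean_radius_px,
      radial_sd_px = x$radial_sd_px, acircularity = x$acircularity,
      area_px2 = x$area_px2, area_mm2 = x$area_mm2,
      star_shaped = x$star_shaped
    )
  )
}

#' Tidy metrics table for a batch of segmentations
#'
#' @param pointsets List of [point_set()] objects.
#' @param scale A [pixel_scale()], or `NULL` to derive per record from its
#'   metadata.
#' @param sd_divisor Passed to [acircularity()].
#' @return Data frame, one row per segmentation, with the metadata columns
#'   followed by `n_points`, `centre_x`, `centre_y`, `mean_radius_px`,
#'   `radial_sd_px`, `acircularity`, `area_px2`, `area_mm2`, `star_shaped`.
#' @export
metrics_table <- function(pointsets, scale = NULL,
                          sd_divisor = c("n", "n-1")) {
  sd_divisor <- match.arg(sd_divisor)
  rows <- lapply(pointsets, function(p) {
    as.data.frame(compute_metrics(p, scale = scale, sd_divisor = sd_divisor))
  })
  do.call(rbind, rows)
}
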