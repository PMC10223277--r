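#' Unordered contour point set
#'
#' The raw pixel coordinates of a drawn FAZ perimeter, before azimuthal
#' ordering. Coordinates follow the package convention: `x` = column,
#' `y` = row, origin `(0, 0)` top-left, `y` increasing downward.
#'
#' @param points Two-column matrix or data frame of `(x, y)` coordinates.
#'   Duplicate coordinate pairs are rejected.
#' @param meta A [faz_meta()] metadata record.
#' @return Object of class `faz_pointset`: list with elements `points`
#'   (numeric matrix, columns `x`, `y`) and `meta`.
#' @export
point_set <- function(points, meta = faz_meta()) {
  pts <- as.matrix(points)
  if (ncol(pts) != 2L) {
    faz_stop("faz_parse_error", "points must have two columns (x, y)")
  }
  storage.mode(pts) <- "double"
  dimnames(pts) <- list(NULL, c("x", "y"))
  if (nrow(pts) == 0L) {
    faz_stop("faz_parse_error", "point set must be non-empty")
  }
  if (anyNA(pts) || any(!is.finite(pts))) {
    faz_stop("faz_parse_error", "points contain non-finite coordinates")
  }
  if (anyDuplicated(pts)) {
    faz_stop("faz_parse_error", "point set contains duplicate coordinate pairs")
  }
  if (!inherits(meta, "faz_meta")) meta <- do.call(faz_meta, meta)
  if (!is.na(meta$image_cols) && !is.na(meta$image_rows)) {
    out <- pts[, "x"] < 0 | pts[, "x"] >= meta$image_cols |
      pts[, "y"] < 0 | pts[, "y"] >= meta$image_rows
    if (any(out)) {
      faz_stop("faz_parse_error",
               sprintf("%d point(s) fall outside the %d x %d image bounds",
                       sum(out), meta$image_rows, meta$image_cols))
    }
  }
  structure(list(points = pts, meta = meta), class = "faz_pointset")
}

#' @export
print.faz_pointset <- function(x, ...) {
  cat(sprintf(
    "<faz_pointset> %d points | eye %s %s %s | observer %s%d | %s\n",
    nrow(x$points), x$meta$eye_id, x$meta$cohort, x$meta$plexus,
    x$meta$observer, x$meta$series, x$meta$criterion
  ))
  invisible(x)
}

#' @export
length.faz_pointset <- function(x) nrow(x$points)
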