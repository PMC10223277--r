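#' Annotated OCTA image
#'
#' An en-face OCTA plexus image carrying a hand-drawn FAZ perimeter line,
#' stored as an 8-bit RGB pixel array plus study metadata. Greyscale input
#' is promoted to RGB.
#'
#' @param pixels Numeric array `rows x cols x 3` with values in 0..255, or a
#'   `rows x cols` greyscale matrix (promoted to RGB).
#' @param meta A [faz_meta()] record; `image_cols`/`image_rows` are filled in
#'   from the array.
#' @param width_mm Physical scan width in mm (stored in `meta`).
#' @return Object of class `faz_image`.
#' @export
annotated_image <- function(pixels, meta = faz_meta(), width_mm = NULL) {
  if (is.matrix(pixels)) {
    pixels <- array(rep(pixels, 3L), dim = c(dim(pixels), 3L))
  }
  if (length(dim(pixels)) != 3L || dim(pixels)[3] < 3L) {
    faz_stop("faz_parse_error", "pixels must be rows x cols x 3 (RGB)")
  }
  pixels <- pixels[, , 1:3, drop = FALSE]
  if (dim(pixels)[1] < 8L || dim(pixels)[2] < 8L) {
    faz_stop("faz_parse_error", "image must be at least 8 x 8 pixels")
  }
  storage.mode(pixels) <- "double"
  if (min(pixels) < 0 || max(pixels) > 255) {
    faz_stop("faz_parse_error", "pixel values must lie in 0..255")
  }
  if (!inherits(meta, "faz_meta")) meta <- do.call(faz_meta, meta)
  if (!is.null(width_mm)) meta$width_mm <- as.numeric(width_mm)
  if (meta$width_mm <= 0) faz_stop("faz_metadata_error", "width_mm must be > 0")
  meta$image_rows <- dim(pixels)[1]
  meta$image_cols <- dim(pixels)[2]
  structure(list(pixels = pixels, meta = meta), class = "faz_image")
}

#' @export
print.faz_image <- function(x, ...) {
  cat(sprintf("<faz_image> %d x %d px, %.3g mm wide | eye %s %s\n",
              x$meta$image_rows, x$meta$image_cols, x$meta$width_mm,
              x$meta$eye_id, x$meta$plexus))
  invisible(x)
}

#' Read an annotated image from TIFF or PNG
#'
#' 8-bit RGB is assumed; greyscale is promoted, an alpha channel is dropped.
#'
#' @param path Path to a `.tif`/`.tiff` or `.png` file.
#' @param meta A [faz_meta()] record for the segmentation the image carries.
#' @param width_mm Physical scan width in mm (default from `meta`, usually 3).
#' @return A [annotated_image()].
#' @export
read_annotated_image <- function(path, meta = faz_meta(), width_mm = NULL) {
  if (!file.exists(path)) {
    faz_stop("faz_parse_error", sprintf("image file not found: %s", path))
  }
  ext <- tolower(sub(".*\\.", "", path))
  arr <- switch(ext,
    tif = ,
    tiff = tiff::readTIFF(path),
    png = png::readPNG(path),
    faz_stop("faz_parse_error",
             sprintf("unsupported image format '.%s' (%s)", ext, path))
  )
  annotated_image(round(arr * 255), meta = meta, width_mm = width_mm)
}

#' Write an annotated image to TIFF or PNG
#'
#' @param image A [annotated_image()].
#' @param path Output path; format chosen from the extension.
#' @return `path`, invisibly.
#' @export
write_annotated_image <- function(image, path) {
  stopifnot(inherits(image, "faz_image"))
  arr <- image$pixels / 255
  ext <- tolower(sub(".*\\.", "", path))
  switch(ext,
    tif = ,
    tiff = tiff::writeTIFF(arr, path, bits.per.sample = 8L),
    png = png::writePNG(arr, path),
    faz_stop("faz_parse_error",
             sprintf("unsupported image format '.%s' (%s)", ext, path))
  )
  invisible(path)
}

#' Overlay colour specification
#'
#' How to recognise the drawn perimeter line: a target RGB colour and a
#' per-channel absolute tolerance. Lines drawn with a pencil tool are
#' near-pure colours, so per-channel distance suffices; the tolerance must
#' stay below 128 so the overlay remains distinguishable from the greyscale
#' vessel background.
#'
#' @param colour RGB triple in 0..255 (default pure red).
#' @param tolerance Per-channel maximum absolute difference, integer in
#'   0..127 (default 30).
#' @return Object of class `faz_overlay_spec`.
#' @export
overlay_spec <- function(colour = c(255, 0, 0), tolerance = 30L) {
  colour <- as.numeric(colour)
  if (length(colour) != 3L || any(colour < 0) || any(colour > 255)) {
    faz_stop("faz_invalid_spec_error", "colour must be an RGB triple in 0..255")
  }
  tolerance <- as.integer(tolerance)
  if (is.na(tolerance) || tolerance < 0L || tolerance >= 128L) {
    faz_stop("faz_invalid_spec_error", "tolerance must be an integer in 0..127")
  }
  structure(list(colour = colour, tolerance = tolerance),
            class = "faz_overlay_spec")
}

#' Extract the drawn perimeter overlay from an annotated image
#'
#' Returns every pixel whose colour lies within the per-channel tolerance of
#' the target colour, as a [point_set()] with the image metadata propagated.
#' One call extracts one observer's line; images carrying several observers'
#' lines in different colours are processed by calling this once per
#' [overlay_spec()].
#'
#' @param image A [annotated_image()].
#' @param spec An [overlay_spec()].
#' @return A [point_set()] of matching pixel coordinates.
#' @section Errors and warnings: Raises a `faz_no_overlay_error` if no pixel
#'   matches. Emits a `faz_ambiguous_overlay_warning` (carrying
#'   `n_components`) if the matching pixels form more than one 8-connected
#'   component — usually a sign that two overlays share a colour or the
#'   tolerance also captures background.
#' @export
extract_overlay <- function(image, spec = overlay_spec()) {
  stopifnot(inherits(image, "faz_image"), inherits(spec, "faz_overlay_spec"))
  px <- image$pixels
  hit <- abs(px[, , 1] - spec$colour[1]) <= spec$tolerance &
    abs(px[, , 2] - spec$colour[2]) <= spec$tolerance &
    abs(px[, , 3] - spec$colour[3]) <= spec$tolerance
  idx <- which(hit, arr.ind = TRUE)
  if (nrow(idx) == 0L) {
    faz_stop("faz_no_overlay_error", sprintf(
      "no pixel within tolerance %d of colour (%s)",
      spec$tolerance, paste(spec$colour, collapse = ", ")
    ))
  }
  pts <- cbind(x = idx[, "col"] - 1, y = idx[, "row"] - 1)
  ncomp <- count_components8(pts)
  if (ncomp > 1L) {
    faz_warn("faz_ambiguous_overlay_warning", sprintf(
      "matched overlay pixels form %d connected components", ncomp
    ), n_components = ncomp)
  }
  point_set(pts, meta = image$meta)
}

# 8-connectivity component count on an integer point set (BFS over a keyed
# lookup). A 1 px drawn line steps diagonally, so 4-connectivity would split
# it into spurious pieces.
count_components8 <- function(pts) {
  pts <- round(pts)
  key <- paste(pts[, 1], pts[, 2], sep = ",")
  n <- nrow(pts)
  seen <- logical(n)
  comp <- 0L
  offs <- expand.grid(dx = -1:1, dy = -1:1)
  offs <- offs[!(offs$dx == 0 & offs$dy == 0), ]
  while (any(!seen)) {
    comp <- comp + 1L
    queue <- which(!seen)[1]
    seen[queue] <- TRUE
    while (length(queue) > 0L) {
      i <- queue[[1]]
      queue <- queue[-1]
      nb_keys <- paste(pts[i, 1] + offs$dx, pts[i, 2] + offs$dy, sep = ",")
      hits <- match(nb_keys, key)
      hits <- hits[!is.na(hits)]
      hits <- hits[!seen[hits]]
      if (length(hits)) {
        seen[hits] <- TRUE
        queue <- c(queue, hits)
      }
    }
  }
  comp
}
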