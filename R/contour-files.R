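# Contour file formats
#
# Two equivalent on-disk forms:
#   * CSV with header "x,y" (integer pixel coordinates) plus a JSON sidecar
#     "<stem>.json" holding the metadata;
#   * a single combined JSON file with "points" and "meta" members.
# Coordinates are 0-based (x = column, y = row, origin top-left).

meta_to_list <- function(meta) {
  list(
    eye_id = meta$eye_id, plexus = meta$plexus, cohort = meta$cohort,
    observer = meta$observer, series = meta$series,
    criterion = meta$criterion, width_mm = meta$width_mm,
    image_cols = meta$image_cols, image_rows = meta$image_rows
  )
}

meta_from_list <- function(lst, path = "") {
  required <- c("plexus", "cohort", "criterion")
  missing <- setdiff(required, names(lst))
  if (length(missing)) {
    faz_stop("faz_metadata_error", sprintf(
      "metadata for %s is missing field(s): %s",
      path, paste(missing, collapse = ", ")
    ))
  }
  faz_meta(
    eye_id = lst$eye_id %||% "eye", plexus = lst$plexus,
    cohort = lst$cohort, observer = lst$observer %||% "A",
    series = lst$series %||% 1L, criterion = lst$criterion,
    width_mm = lst$width_mm %||% 3,
    image_cols = lst$image_cols %||% NA_integer_,
    image_rows = lst$image_rows %||% NA_integer_
  )
}

sidecar_path <- function(path) sub("\\.[Cc][Ss][Vv]$", ".json", path)

#' Write a contour point set to disk
#'
#' `format = "csv"` writes an `x,y` CSV plus a JSON metadata sidecar with the
#' same stem; `format = "json"` writes one combined JSON file.
#'
#' @param points A [point_set()].
#' @param path Output path (`.csv` or `.json`).
#' @param format `"csv"` or `"json"`; default guessed from the extension.
#' @return `path`, invisibly.
#' @export
write_contour_file <- function(points, path,
                               format = c("auto", "csv", "json")) {
  stopifnot(inherits(points, "faz_pointset"))
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  meta <- meta_to_list(points$meta)
  ok <- tryCatch({
    if (format == "csv") {
      df <- data.frame(x = as.integer(round(points$points[, "x"])),
                       y = as.integer(round(points$points[, "y"])))
      utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
      jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                           digits = NA, null = "null", na = "null")
    } else {
      jsonlite::write_json(
        list(points = data.frame(x = as.integer(round(points$points[, "x"])),
                                 y = as.integer(round(points$points[, "y"]))),
             meta = meta),
        path, auto_unbox = TRUE, digits = NA, null = "null", na = "null"
      )
    }
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) {
    faz_stop("faz_io_error",
             sprintf("failed writing contour file %s: %s",
                     path, conditionMessage(ok)))
  }
  invisible(path)
}

#' Read a contour point set from disk
#'
#' Accepts the CSV + JSON-sidecar pair or the combined JSON form written by
#' [write_contour_file()].
#'
#' @param path Path to the `.csv` or `.json` file.
#' @return A [point_set()].
#' @export
read_contour_file <- function(path) {
  if (!file.exists(path)) {
    faz_stop("faz_parse_error", sprintf("contour file not found: %s", path))
  }
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    obj <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                    error = function(e) {
                      faz_stop("faz_parse_error", sprintf(
                        "malformed JSON in %s: %s", path, conditionMessage(e)))
                    })
    if (is.null(obj$points) || is.null(obj$meta)) {
      faz_stop("faz_parse_error",
               sprintf("%s lacks 'points' and/or 'meta' members", path))
    }
    pts <- as.data.frame(obj$points)
    meta <- meta_from_list(as.list(obj$meta), path)
  } else {
    df <- tryCatch(utils::read.csv(path), error = function(e) {
      faz_stop("faz_parse_error",
               sprintf("malformed CSV in %s: %s", path, conditionMessage(e)))
    })
    if (!all(c("x", "y") %in% names(df))) {
      faz_stop("faz_parse_error",
               sprintf("%s must have header columns x,y", path))
    }
    if (!nrow(df) || !is.numeric(df$x) || !is.numeric(df$y) || anyNA(df)) {
      faz_stop("faz_parse_error",
               sprintf("%s contains malformed coordinate rows", path))
    }
    side <- sidecar_path(path)
    if (!file.exists(side)) {
      faz_stop("faz_metadata_error",
               sprintf("metadata sidecar %s not found", side))
    }
    meta <- meta_from_list(
      as.list(jsonlite::read_json(side, simplifyVector = TRUE)), side
    )
    pts <- df[, c("x", "y")]
  }
  point_set(pts, meta = meta)
}
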