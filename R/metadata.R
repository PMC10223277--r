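# Segmentation metadata: which eye, which capillary plexus, which patient
# cohort, which observer/series, and which delimitation criterion (the
# "region without vessels" INITIAL definition vs the "inner boundary of the
# transition zone" FINAL definition).

PLEXUS_LEVELS <- c("SCP", "DCP")
COHORT_LEVELS <- c("DM1", "DM2", "HEALTHY")
CRITERION_LEVELS <- c("INITIAL", "FINAL")

#' Segmentation metadata record
#'
#' Bundles the study metadata attached to every annotated image, point set
#' and contour: eye identifier, capillary plexus (`SCP` or `DCP`), patient
#' cohort (`DM1`, `DM2` or `HEALTHY`), observer label (a single letter),
#' measurement series index, and delimitation criterion (`INITIAL` or
#' `FINAL`).
#'
#' @param eye_id Character scalar identifying the eye.
#' @param plexus `"SCP"` (superficial) or `"DCP"` (deep capillary plexus).
#' @param cohort `"DM1"`, `"DM2"` or `"HEALTHY"`.
#' @param observer Single-letter observer label.
#' @param series Measurement series index (integer >= 1); two series by the
#'   same observer are labelled e.g. `G1`, `G2`.
#' @param criterion `"INITIAL"` or `"FINAL"`.
#' @param width_mm Physical width of the scanned field in mm (default 3).
#' @param image_cols,image_rows Pixel dimensions of the source image, if
#'   known; used to derive the default pixel scale.
#' @return A named list of class `faz_meta`.
#' @export
faz_meta <- function(eye_id = "eye", plexus = "SCP", cohort = "HEALTHY",
                     observer = "A", series = 1L, criterion = "INITIAL",
                     width_mm = 3, image_cols = NA_integer_,
                     image_rows = NA_integer_) {
  meta <- list(
    eye_id = as.character(eye_id),
    plexus = as.character(plexus),
    cohort = as.character(cohort),
    observer = as.character(observer),
    series = as.integer(series),
    criterion = as.character(criterion),
    width_mm = as.numeric(width_mm),
    image_cols = as.integer(image_cols),
    image_rows = as.integer(image_rows)
  )
  validate_meta(meta)
  structure(meta, class = "faz_meta")
}

validate_meta <- function(meta) {
  check_enum <- function(value, levels, field) {
    if (length(value) != 1L || is.na(value) || !value %in% levels) {
      faz_stop("faz_metadata_error", sprintf(
        "invalid %s %s: must be one of %s", field,
        deparse(as.character(value)), paste(levels, collapse = ", ")
      ), field = field, value = value)
    }
  }
  check_enum(meta$plexus, PLEXUS_LEVELS, "plexus")
  check_enum(meta$cohort, COHORT_LEVELS, "cohort")
  check_enum(meta$criterion, CRITERION_LEVELS, "criterion")
  if (length(meta$observer) != 1L || !grepl("^[A-Za-z]$", meta$observer)) {
    faz_stop("faz_metadata_error",
             sprintf("observer must be a single letter, got %s",
                     deparse(meta$observer)))
  }
  if (is.na(meta$series) || meta$series < 1L) {
    faz_stop("faz_metadata_error", "series must be an integer >= 1")
  }
  if (!is.finite(meta$width_mm) || meta$width_mm <= 0) {
    faz_stop("faz_metadata_error", "width_mm must be > 0")
  }
  invisible(meta)
}

meta_as_row <- function(meta) {
  data.frame(
    eye_id = meta$eye_id, plexus = meta$plexus, cohort = meta$cohort,
    observer = meta$observer, series = meta$series,
    criterion = meta$criterion, stringsAsFactors = FALSE
  )
}
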