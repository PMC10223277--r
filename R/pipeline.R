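# Pipeline drivers. Each cmd_* function is a plain R function usable
# programmatically; inst/scripts/fazmetry-cli.R wraps them for the shell.
# Per-record failures are logged in the returned manifest and never abort a
# batch silently.

log_line <- function(verbose, fmt, ...) {
  if (verbose) message(sprintf(fmt, ...))
  invisible(NULL)
}

write_run_log <- function(output_dir, command, config) {
  jsonlite::write_json(
    list(command = command,
         package_version = as.character(utils::packageVersion("fazmetry")),
         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
         config = config),
    file.path(output_dir, paste0("run_log_", command, ".json")),
    auto_unbox = TRUE, digits = NA, null = "null", na = "null", pretty = TRUE
  )
}

#' Simulate a synthetic segmentation dataset on disk
#'
#' Generates a cohort from a [cohort_spec()] and writes one contour file per
#' tracing (CSV + JSON sidecar under `contours/`), optionally one rendered
#' annotated PNG per tracing (under `images/`), plus `ground_truth.csv` and
#' a JSON run log recording the resolved configuration.
#'
#' @param output_dir Output directory (created if needed).
#' @param spec A [cohort_spec()]; `seed` overrides its master seed.
#' @param write_images Also render annotated PNGs (slow for large specs).
#' @param line_colour,line_thickness Rendering options for the overlay.
#' @param seed Optional master-seed override.
#' @param verbose Emit per-stage messages.
#' @return The generated `faz_cohort`, invisibly.
#' @export
cmd_simulate <- function(output_dir, spec = cohort_spec(),
                         write_images = FALSE, line_colour = c(255, 0, 0),
                         line_thickness = 1L, seed = NULL, verbose = FALSE) {
  if (!is.null(seed)) spec$seed <- as.integer(seed)
  dir.create(file.path(output_dir, "contours"), recursive = TRUE,
             showWarnings = FALSE)
  cohort <- generate_cohort(spec)
  log_line(verbose, "simulated %d tracings (%d shapes)",
           length(cohort$records), length(cohort$shapes))
  for (key in names(cohort$records)) {
    stem <- gsub("\\|", "_", key)
    write_contour_file(cohort$records[[key]],
                       file.path(output_dir, "contours",
                                 paste0(stem, ".csv")))
  }
  if (write_images) {
    dir.create(file.path(output_dir, "images"), showWarnings = FALSE)
    for (key in names(cohort$records)) {
      stem <- gsub("\\|", "_", key)
      img <- render_annotated(cohort$records[[key]],
                              line_colour = line_colour,
                              line_thickness = line_thickness,
                              size = spec$image_px)
      write_annotated_image(img, file.path(output_dir, "images",
                                           paste0(stem, ".png")))
      jsonlite::write_json(meta_to_list(cohort$records[[key]]$meta),
                           file.path(output_dir, "images",
                                     paste0(stem, ".json")),
                           auto_unbox = TRUE, digits = NA, na = "null")
    }
  }
  utils::write.csv(cohort$ground_truth,
                   file.path(output_dir, "ground_truth.csv"),
                   row.names = FALSE)
  write_run_log(output_dir, "simulate",
                list(seed = spec$seed, image_px = spec$image_px,
                     width_mm = spec$width_mm, n_samples = spec$n_samples,
                     n_records = length(cohort$records),
                     write_images = write_images))
  invisible(cohort)
}

#' Extract overlay contours from a directory of annotated images
#'
#' Processes every `.png`/`.tif`/`.tiff` in `input_dir`. Metadata comes
#' from a JSON sidecar named after the image stem. One contour file is
#' written per (image, overlay colour); failures are recorded in the
#' manifest and the run continues.
#'
#' @param input_dir Directory of annotated images (+ JSON metadata
#'   sidecars).
#' @param output_dir Where contour files and `manifest.csv` go.
#' @param overlays List of [overlay_spec()]s, one per observer line colour.
#' @param width_mm Physical scan width (mm) if the sidecar does not state
#'   it.
#' @param verbose Emit per-file messages.
#' @return The manifest data frame (`file`, `overlay`, `status`,
#'   `n_points`, `output`), invisibly. Raises an error only if every image
#'   fails.
#' @export
cmd_extract <- function(input_dir, output_dir,
                        overlays = list(overlay_spec()), width_mm = 3,
                        verbose = FALSE) {
  files <- list.files(input_dir, pattern = "\\.(png|tif|tiff)$",
                      ignore.case = TRUE, full.names = TRUE)
  if (!length(files)) {
    faz_stop("faz_empty_input_error",
             sprintf("no images found in %s", input_dir))
  }
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (f in files) {
    stem <- sub("\\.[^.]+$", "", basename(f))
    side <- file.path(input_dir, paste0(stem, ".json"))
    meta <- tryCatch({
      if (file.exists(side)) {
        meta_from_list(as.list(jsonlite::read_json(side,
                                                   simplifyVector = TRUE)),
                       side)
      } else {
        faz_meta(eye_id = stem, width_mm = width_mm)
      }
    }, faz_error = function(e) e)
    for (i in seq_along(overlays)) {
      tag <- paste(overlays[[i]]$colour, collapse = "-")
      status <- "ok"
      npts <- NA_integer_
      out_path <- NA_character_
      if (inherits(meta, "condition")) {
        status <- class(meta)[1]
      } else {
        res <- tryCatch({
          img <- read_annotated_image(f, meta = meta,
                                      width_mm = meta$width_mm)
          withCallingHandlers(
            extract_overlay(img, overlays[[i]]),
            faz_ambiguous_overlay_warning = function(w) {
              log_line(verbose, "%s: %s", basename(f), conditionMessage(w))
              invokeRestart("muffleWarning")
            }
          )
        }, faz_error = function(e) e)
        if (inherits(res, "condition")) {
          status <- class(res)[1]
        } else {
          npts <- length(res)
          out_path <- file.path(output_dir,
                                sprintf("%s_overlay%d.csv", stem, i))
          write_contour_file(res, out_path)
        }
      }
      log_line(verbose, "%s [overlay %s]: %s", basename(f), tag, status)
      rows[[paste(f, i)]] <- data.frame(
        file = basename(f), overlay = tag, status = status,
        n_points = npts, output = basename(out_path),
        stringsAsFactors = FALSE
      )
    }
  }
  manifest <- do.call(rbind, rows)
  rownames(manifest) <- NULL
  utils::write.csv(manifest, file.path(output_dir, "manifest.csv"),
                   row.names = FALSE)
  write_run_log(output_dir, "extract",
                list(input_dir = input_dir, n_images = length(files),
                     n_overlays = length(overlays), width_mm = width_mm))
  if (all(manifest$status != "ok")) {
    faz_stop("faz_empty_input_error",
             "overlay extraction failed for every image (see manifest)")
  }
  invisible(manifest)
}

#' Compute the tidy metrics table for a directory of contour files
#'
#' Reads every contour file in `input_dir` (CSV + sidecar or combined
#' JSON), runs [compute_metrics()] on each, and writes one tidy CSV row per
#' contour. Files that fail to parse are logged and skipped.
#'
#' @param input_dir Directory of contour files.
#' @param output_csv Path of the metrics CSV to write.
#' @param scale Optional [pixel_scale()]; default derived per record from
#'   its metadata.
#' @param sd_divisor Passed to [acircularity()].
#' @param verbose Emit per-file messages.
#' @return The metrics data frame, invisibly.
#' @export
cmd_metrics <- function(input_dir, output_csv, scale = NULL,
                        sd_divisor = c("n", "n-1"), verbose = FALSE) {
  sd_divisor <- match.arg(sd_divisor)
  csvs <- list.files(input_dir, pattern = "\\.csv$", full.names = TRUE)
  csvs <- csvs[basename(csvs) != "manifest.csv"]
  jsons <- list.files(input_dir, pattern = "\\.json$", full.names = TRUE)
  jsons <- jsons[!file.exists(sub("\\.json$", ".csv", jsons)) &
                   !grepl("^run_log", basename(jsons))]
  files <- c(csvs, jsons)
  if (!length(files)) {
    faz_stop("faz_empty_input_error",
             sprintf("no contour files found in %s", input_dir))
  }
  rows <- list()
  for (f in files) {
    if (grepl("\\.csv$", f)) {
      header <- names(utils::read.csv(f, nrows = 1))
      if ("area_mm2" %in% header) {
        faz_stop("faz_parse_error", sprintf(
          "%s has the metrics-table schema, not contour coordinates; refusing to re-measure it",
          f))
      }
    }
    res <- tryCatch(
      as.data.frame(compute_metrics(read_contour_file(f), scale = scale,
                                    sd_divisor = sd_divisor)),
      faz_error = function(e) e
    )
    if (inherits(res, "condition")) {
      log_line(TRUE, "skipping %s: %s", basename(f), conditionMessage(res))
    } else {
      log_line(verbose, "%s: area %.4f mm^2", basename(f), res$area_mm2)
      rows[[f]] <- res
    }
  }
  if (!length(rows)) {
    faz_stop("faz_empty_input_error", "no contour file could be processed")
  }
  metrics <- do.call(rbind, rows)
  rownames(metrics) <- NULL
  dir.create(dirname(output_csv), recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(metrics, output_csv, row.names = FALSE)
  invisible(metrics)
}

#' Summarise a metrics table into the study's output tables
#'
#' Writes `summary.csv` (mean/SD per cohort x plexus x criterion),
#' `summary_by_observer.csv`, `contrast.csv` (initial vs final; skipped
#' with a note when only one criterion is present), `variability_eye.csv`,
#' `variability_cohort.csv`, `pairs.csv` and `pair_correlations.csv`, plus
#' an optional area-acircularity scatter PNG.
#'
#' @param metrics_csv Path to the tidy metrics CSV from [cmd_metrics()].
#' @param output_dir Output directory.
#' @param eye_average Passed to [summarize_records()].
#' @param plots Write the scatter plot PNG.
#' @param verbose Emit messages.
#' @return Named list of the computed tables, invisibly.
#' @export
cmd_summarize <- function(metrics_csv, output_dir, eye_average = FALSE,
                          plots = FALSE, verbose = FALSE) {
  if (!file.exists(metrics_csv)) {
    faz_stop("faz_empty_input_error",
             sprintf("metrics file not found: %s", metrics_csv))
  }
  records <- utils::read.csv(metrics_csv)
  check_records(records)
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  out <- list()
  out$summary <- summarize_records(records, eye_average = eye_average)
  utils::write.csv(out$summary, file.path(output_dir, "summary.csv"),
                   row.names = FALSE)
  out$summary_by_observer <- summarize_records(
    records, by = c("cohort", "plexus", "criterion", "observer"),
    eye_average = eye_average
  )
  utils::write.csv(out$summary_by_observer,
                   file.path(output_dir, "summary_by_observer.csv"),
                   row.names = FALSE)
  if (length(unique(records$criterion)) == 2L) {
    out$contrast <- criterion_contrast(out$summary)
    utils::write.csv(out$contrast, file.path(output_dir, "contrast.csv"),
                     row.names = FALSE)
  } else {
    log_line(TRUE, "single criterion present; contrast table skipped")
  }
  vab <- observer_variability(records)
  out$variability_eye <- vab$per_eye
  out$variability_cohort <- vab$by_cohort
  utils::write.csv(vab$per_eye, file.path(output_dir, "variability_eye.csv"),
                   row.names = FALSE)
  utils::write.csv(vab$by_cohort,
                   file.path(output_dir, "variability_cohort.csv"),
                   row.names = FALSE)
  pa <- area_acircularity_pairs(records)
  out$pairs <- pa$pairs
  out$pair_correlations <- pa$correlations
  utils::write.csv(pa$pairs, file.path(output_dir, "pairs.csv"),
                   row.names = FALSE)
  utils::write.csv(pa$correlations,
                   file.path(output_dir, "pair_correlations.csv"),
                   row.names = FALSE)
  if (plots) {
    grDevices::png(file.path(output_dir, "area_vs_acircularity.png"),
                   width = 900, height = 700, res = 120)
    plot_area_acircularity(records)
    grDevices::dev.off()
  }
  write_run_log(output_dir, "summarize",
                list(metrics_csv = metrics_csv, eye_average = eye_average,
                     n_records = nrow(records)))
  log_line(verbose, "summaries written to %s", output_dir)
  invisible(out)
}

#' Run the full synthetic pipeline end to end
#'
#' Simulate, render, extract, measure and summarise in one call:
#' [cmd_simulate()] with images, [cmd_extract()] on the rendered images,
#' [cmd_metrics()] on the extracted contours, [cmd_summarize()] on the
#' metrics table.
#'
#' @param output_dir Root output directory.
#' @param spec A [cohort_spec()] (use a small one; every tracing is
#'   rendered).
#' @param seed Optional master-seed override.
#' @param plots Passed to [cmd_summarize()].
#' @param verbose Emit per-stage messages.
#' @return Named list with the cohort, manifest, metrics and summary
#'   tables, invisibly.
#' @export
cmd_all <- function(output_dir, spec = cohort_spec(), seed = NULL,
                    plots = FALSE, verbose = FALSE) {
  cohort <- cmd_simulate(output_dir, spec = spec, write_images = TRUE,
                         seed = seed, verbose = verbose)
  manifest <- cmd_extract(file.path(output_dir, "images"),
                          file.path(output_dir, "extracted"),
                          width_mm = spec$width_mm, verbose = verbose)
  metrics <- cmd_metrics(file.path(output_dir, "extracted"),
                         file.path(output_dir, "metrics.csv"),
                         verbose = verbose)
  summaries <- cmd_summarize(file.path(output_dir, "metrics.csv"),
                             file.path(output_dir, "summaries"),
                             plots = plots, verbose = verbose)
  invisible(list(cohort = cohort, manifest = manifest, metrics = metrics,
                 summaries = summaries))
}
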