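#' Generate a full synthetic segmentation cohort
#'
#' Expands a [cohort_spec()] into its full factorial design: for every eye a
#' ground-truth shape per plexus, then one tracing per (observer, series,
#' criterion) cell. Each record draws from its own RNG stream, derived from
#' the master seed by a stable hash of the record key, so any subset of the
#' cohort regenerates identically regardless of generation order.
#'
#' @param spec A [cohort_spec()].
#' @return Object of class `faz_cohort`: list with
#'   \describe{
#'     \item{records}{named list of [point_set()] tracings, keyed
#'       `eye|plexus|observer|series|criterion`.}
#'     \item{shapes}{named list of ground-truth [synthetic_shape()]s, keyed
#'       `eye|plexus`.}
#'     \item{ground_truth}{data frame: one row per (eye, plexus) with the
#'       generating parameters and the analytic area in px^2 and mm^2.}
#'     \item{spec}{the input spec.}
#'   }
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "faz_cohort_spec"))
  scale <- pixel_scale(spec$width_mm / spec$image_px)
  records <- list()
  shapes <- list()
  gt_rows <- list()
  for (cohort in names(spec$cohorts)) {
    n_eyes <- spec$cohorts[[cohort]]$n_eyes
    for (e in seq_len(n_eyes)) {
      eye_id <- sprintf("%s_%03d", cohort, e)
      for (plexus in spec$plexus) {
        shape_key <- paste(eye_id, plexus, sep = "|")
        shape <- sample_shape(spec, cohort,
                              seed = hash_seed(spec$seed,
                                               paste0("shape|", shape_key)))
        shapes[[shape_key]] <- shape
        a_px2 <- analytic_area(shape)
        gt_rows[[shape_key]] <- data.frame(
          shape_id = shape_key, eye_id = eye_id, cohort = cohort,
          plexus = plexus, R0 = shape$R0,
          n_harmonics = nrow(shape$harmonics),
          analytic_area_px2 = a_px2,
          analytic_area_mm2 = to_mm2(a_px2, scale),
          stringsAsFactors = FALSE
        )
        for (obs in names(spec$observers)) {
          for (series in seq_len(spec$observers[[obs]]$series)) {
            for (criterion in names(spec$observer_models)) {
              rec_key <- paste(eye_id, plexus, obs, series, criterion,
                               sep = "|")
              model <- spec$observer_models[[criterion]]
              obs_bias <- spec$observers[[obs]]$bias
              if (!is.null(obs_bias) && criterion %in% names(obs_bias)) {
                model$radial_bias <- unname(obs_bias[[criterion]])
              }
              model$seed <- hash_seed(spec$seed, paste0("trace|", rec_key))
              meta <- faz_meta(
                eye_id = eye_id, plexus = plexus, cohort = cohort,
                observer = obs, series = series, criterion = criterion,
                width_mm = spec$width_mm, image_cols = spec$image_px,
                image_rows = spec$image_px
              )
              records[[rec_key]] <-
                simulate_observer_tracing(shape, model, meta = meta)
            }
          }
        }
      }
    }
  }
  structure(list(records = records, shapes = shapes,
                 ground_truth = do.call(rbind, unname(gt_rows)),
                 spec = spec),
            class = "faz_cohort")
}

#' @export
print.faz_cohort <- function(x, ...) {
  cat(sprintf("<faz_cohort> %d tracings of %d ground-truth shapes\n",
              length(x$records), length(x$shapes)))
  invisible(x)
}

#' Per-segmentation metrics for a synthetic cohort
#'
#' Runs [compute_metrics()] on every tracing of a generated cohort, at the
#' pixel scale implied by the spec.
#'
#' @param cohort A [generate_cohort()] result.
#' @param sd_divisor Passed to [acircularity()].
#' @return Tidy data frame, one row per tracing (see [metrics_table()]).
#' @export
cohort_metrics <- function(cohort, sd_divisor = c("n", "n-1")) {
  stopifnot(inherits(cohort, "faz_cohort"))
  sd_divisor <- match.arg(sd_divisor)
  scale <- pixel_scale(cohort$spec$width_mm / cohort$spec$image_px)
  metrics_table(cohort$records, scale = scale, sd_divisor = sd_divisor)
}
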