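# Cohort-level aggregation of per-segmentation metrics.
#
# Input throughout is the tidy metrics table (one row per segmentation,
# see metrics_table()): metadata columns eye_id, plexus, cohort, observer,
# series, criterion plus area_mm2 and acircularity.

metric_cols <- c("area_mm2", "acircularity")

check_records <- function(records) {
  if (!is.data.frame(records) || nrow(records) == 0L) {
    faz_stop("faz_empty_input_error", "records must be a non-empty data frame")
  }
  need <- c("cohort", "plexus", "criterion", metric_cols)
  missing <- setdiff(need, names(records))
  if (length(missing)) {
    faz_stop("faz_parse_error", sprintf(
      "records table lacks column(s): %s (is this a metrics table?)",
      paste(missing, collapse = ", ")))
  }
  invisible(records)
}

#' Group means and SDs of area and acircularity
#'
#' Aggregates per-segmentation metrics into the study's summary structure:
#' per group, the count and the mean and standard deviation of the FAZ area
#' (mm^2) and of the acircularity. Cross-record SDs use the sample (N-1)
#' divisor; single-record groups report SD 0. All segmentations are pooled
#' within a group by default; average over eyes first (`eye_average = TRUE`)
#' to summarise eye-level means instead.
#'
#' @param records Tidy metrics data frame (from [metrics_table()] /
#'   [cohort_metrics()] or read back from the pipeline CSV).
#' @param by Grouping columns, a subset of
#'   `c("cohort", "plexus", "criterion", "observer")`.
#' @param eye_average Average records within each eye (and grouping cell)
#'   before summarising.
#' @return Data frame with the grouping columns plus `n`, `mean_area_mm2`,
#'   `sd_area_mm2`, `mean_acircularity`, `sd_acircularity`.
#' @export
summarize_records <- function(records,
                              by = c("cohort", "plexus", "criterion"),
                              eye_average = FALSE) {
  check_records(records)
  allowed <- c("cohort", "plexus", "criterion", "observer")
  if (length(by) == 0L || !all(by %in% allowed)) {
    faz_stop("faz_invalid_spec_error", sprintf(
      "grouping keys must be a non-empty subset of %s",
      paste(allowed, collapse = ", ")))
  }
  if (eye_average) {
    pre <- stats::aggregate(records[metric_cols],
                            records[unique(c("eye_id", by))], mean)
    records <- pre
  }
  sd0 <- function(v) if (length(v) < 2L) 0 else stats::sd(v)
  groups <- records[by]
  agg_mean <- stats::aggregate(records[metric_cols], groups, mean)
  agg_sd <- stats::aggregate(records[metric_cols], groups, sd0)
  agg_n <- stats::aggregate(list(n = records[[metric_cols[1]]]), groups,
                            length)
  out <- agg_n
  out$mean_area_mm2 <- agg_mean$area_mm2
  out$sd_area_mm2 <- agg_sd$area_mm2
  out$mean_acircularity <- agg_mean$acircularity
  out$sd_acircularity <- agg_sd$acircularity
  out <- out[do.call(order, out[by]), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Initial-versus-final criterion contrast
#'
#' For every (cohort, plexus) cell of a summary that contains both
#' delimitation criteria, reports the change in mean and SD when moving
#' from the initial to the final criterion, and the mean ratio
#' `FINAL / INITIAL`. Signs only; no hypothesis test is performed.
#'
#' @param summary Output of [summarize_records()] grouped by (at least)
#'   `cohort`, `plexus`, `criterion`.
#' @return Data frame with columns `cohort`, `plexus`,
#'   `delta_mean_area_mm2` (initial minus final), `delta_sd_area_mm2`,
#'   `area_ratio` (final over initial), `delta_mean_acircularity`,
#'   `delta_sd_acircularity`.
#' @export
criterion_contrast <- function(summary) {
  need <- c("cohort", "plexus", "criterion", "mean_area_mm2", "sd_area_mm2",
            "mean_acircularity", "sd_acircularity")
  if (!all(need %in% names(summary))) {
    faz_stop("faz_parse_error",
             "summary must come from summarize_records() with cohort, plexus and criterion grouping")
  }
  cells <- unique(summary[c("cohort", "plexus")])
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    sub <- summary[summary$cohort == cells$cohort[i] &
                     summary$plexus == cells$plexus[i], ]
    ini <- sub[sub$criterion == "INITIAL", ]
    fin <- sub[sub$criterion == "FINAL", ]
    if (nrow(ini) != 1L || nrow(fin) != 1L) {
      faz_stop("faz_missing_criterion_error", sprintf(
        "cell (%s, %s) lacks one of the two criteria",
        cells$cohort[i], cells$plexus[i]))
    }
    data.frame(
      cohort = cells$cohort[i], plexus = cells$plexus[i],
      delta_mean_area_mm2 = ini$mean_area_mm2 - fin$mean_area_mm2,
      delta_sd_area_mm2 = ini$sd_area_mm2 - fin$sd_area_mm2,
      area_ratio = fin$mean_area_mm2 / ini$mean_area_mm2,
      delta_mean_acircularity = ini$mean_acircularity - fin$mean_acircularity,
      delta_sd_acircularity = ini$sd_acircularity - fin$sd_acircularity,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out[order(out$cohort, out$plexus), , drop = FALSE]
}

#' Inter- and intra-observer variability of the FAZ area
#'
#' For every (eye, plexus, criterion): the inter-observer SD of the area
#' (SD across observers of each observer's series-averaged area) and the
#' intra-observer SD (mean over observers of the SD across that observer's
#' series). A component that lacks replication (one observer, or no
#' repeated series) is reported as `NA`, not an error. Cohort-level means
#' of both components are returned alongside.
#'
#' @param records Tidy metrics data frame; needs `eye_id`, `observer` and
#'   `series` columns.
#' @return List with two data frames: `per_eye` (eye_id, cohort, plexus,
#'   criterion, n_observers, inter_sd_area_mm2, intra_sd_area_mm2) and
#'   `by_cohort` (cohort, plexus, criterion, mean_inter_sd, mean_intra_sd).
#' @export
observer_variability <- function(records) {
  check_records(records)
  if (!all(c("eye_id", "observer", "series") %in% names(records))) {
    faz_stop("faz_parse_error",
             "records must carry eye_id, observer and series columns")
  }
  cells <- unique(records[c("eye_id", "cohort", "plexus", "criterion")])
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    sub <- records[records$eye_id == cells$eye_id[i] &
                     records$plexus == cells$plexus[i] &
                     records$criterion == cells$criterion[i], ]
    per_obs_mean <- tapply(sub$area_mm2, sub$observer, mean)
    inter <- if (length(per_obs_mean) >= 2L) stats::sd(per_obs_mean) else
      NA_real_
    within <- tapply(sub$area_mm2, sub$observer,
                     function(v) if (length(v) >= 2L) stats::sd(v) else
                       NA_real_)
    intra <- if (all(is.na(within))) NA_real_ else
      mean(within, na.rm = TRUE)
    data.frame(
      eye_id = cells$eye_id[i], cohort = cells$cohort[i],
      plexus = cells$plexus[i], criterion = cells$criterion[i],
      n_observers = length(per_obs_mean),
      inter_sd_area_mm2 = unname(inter),
      intra_sd_area_mm2 = unname(intra),
      stringsAsFactors = FALSE
    )
  })
  per_eye <- do.call(rbind, rows)
  mean_na <- function(v) if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  by_cohort <- stats::aggregate(
    per_eye[c("inter_sd_area_mm2", "intra_sd_area_mm2")],
    per_eye[c("cohort", "plexus", "criterion")], mean_na
  )
  names(by_cohort)[4:5] <- c("mean_inter_sd", "mean_intra_sd")
  by_cohort <- by_cohort[order(by_cohort$cohort, by_cohort$plexus,
                               by_cohort$criterion), , drop = FALSE]
  rownames(by_cohort) <- NULL
  list(per_eye = per_eye, by_cohort = by_cohort)
}

#' Paired area-acircularity table
#'
#' One row per segmentation pairing the FAZ area with its acircularity,
#' flagging very irregular contours (acircularity above 0.5), plus the
#' Spearman rank correlation between area and acircularity within each
#' (plexus, criterion) cell. The correlation is descriptive; no p-value is
#' attached.
#'
#' @param records Tidy metrics data frame.
#' @return List with `pairs` (area_mm2, acircularity, plexus, criterion,
#'   cohort, irregular_flag) and `correlations` (plexus, criterion, n,
#'   spearman_rho).
#' @export
area_acircularity_pairs <- function(records) {
  check_records(records)
  pairs <- records[c("area_mm2", "acircularity", "plexus", "criterion")]
  if ("cohort" %in% names(records)) pairs$cohort <- records$cohort
  pairs$irregular_flag <- pairs$acircularity > 0.5
  cells <- unique(pairs[c("plexus", "criterion")])
  cors <- lapply(seq_len(nrow(cells)), function(i) {
    sub <- pairs[pairs$plexus == cells$plexus[i] &
                   pairs$criterion == cells$criterion[i], ]
    rho <- if (nrow(sub) >= 3L) {
      stats::cor(sub$area_mm2, sub$acircularity, method = "spearman")
    } else NA_real_
    data.frame(plexus = cells$plexus[i], criterion = cells$criterion[i],
               n = nrow(sub), spearman_rho = rho, stringsAsFactors = FALSE)
  })
  list(pairs = pairs, correlations = do.call(rbind, cors))
}

#' Scatter plot of area against acircularity
#'
#' Base-graphics scatter of the paired table, coloured by criterion, with
#' the very-irregular threshold (acircularity 0.5) marked.
#'
#' @param records Tidy metrics data frame.
#' @param ... Passed to [graphics::plot()].
#' @return The paired table, invisibly.
#' @export
plot_area_acircularity <- function(records, ...) {
  pa <- area_acircularity_pairs(records)
  cols <- ifelse(pa$pairs$criterion == "FINAL", "#1f77b4", "#ff7f0e")
  graphics::plot(pa$pairs$area_mm2, pa$pairs$acircularity, col = cols,
                 pch = 16, cex = 0.6, xlab = "FAZ area (mm^2)",
                 ylab = "Acircularity", ...)
  graphics::abline(h = 0.5, lty = 2, col = "grey40")
  graphics::legend("topright", legend = c("initial", "final"), pch = 16,
                   col = c("#ff7f0e", "#1f77b4"), bty = "n")
  invisible(pa)
}
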