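#' End-to-end dFC analysis
#'
#' Runs the full assessment pipeline on a cohort for every requested
#' (metric, window) combination: optional high-pass preprocessing,
#' per-subject surrogate null construction, observed group-mean dFC
#' strengths, critical values and hypothesis tests, and per-metric
#' minimum-detecting-window profiles.  Fully deterministic for a fixed
#' surrogate seed.
#'
#' @param cohort a [as_cohort()] cohort (or single [roi_ts()]).
#' @param metrics character vector of [metric_ids()] entries.
#' @param grid a [window_grid()] (or single [window_spec()]).
#' @param surrogate a [surrogate_spec()].
#' @param test a [test_config()].
#' @param metric_cfg a [metric_config()].
#' @param highpass_hz optional high-pass cutoff applied to every subject
#'   before analysis (`NULL` = no filtering).
#' @param out_dir optional directory; when given, long-format TSV tables
#'   and a JSON run manifest are written there.
#' @return Object of class `dfc_analysis`: `tests` (list indexed
#'   `[[metric]][[window]]`), `profiles` (per metric, from
#'   [detection_profile()]), `grid_seconds`, `manifest`.
#' @export
run_full_analysis <- function(cohort, metrics = c("pearson", "mutual_information"),
                              grid = NULL, surrogate = surrogate_spec(),
                              test = test_config(),
                              metric_cfg = metric_config(),
                              highpass_hz = NULL, out_dir = NULL) {
  if (inherits(cohort, "roi_ts")) cohort <- as_cohort(cohort)
  stopifnot(inherits(cohort, "dfc_cohort"))
  unknown <- setdiff(metrics, metric_ids())
  if (length(unknown))
    stop_swdfc(sprintf("unknown metric(s): %s", paste(unknown, collapse = ", ")),
               "swdfc_validation_error")
  tr <- cohort$subjects[[1L]]$tr_seconds
  if (is.null(grid)) grid <- window_grid(tr_seconds = tr)
  if (inherits(grid, "window_spec"))
    grid <- structure(list(specs = list(grid), seconds = grid$length_seconds),
                      class = "window_grid")
  if (!is.null(highpass_hz))
    cohort <- as_cohort(lapply(cohort$subjects, highpass_filter,
                               cutoff_hz = highpass_hz))
  tests <- lapply(metrics, function(m) vector("list", length(grid$specs)))
  names(tests) <- metrics
  for (wi in seq_along(grid$specs)) {
    w <- grid$specs[[wi]]
    nulls <- null_strengths(cohort, surrogate, metrics, w, metric_cfg)
    for (m in metrics) {
      gm <- cohort_mean_dfc(cohort, m, w, metric_cfg)
      tests[[m]][[wi]] <- test_dfc(gm, nulls[[m]], test)
    }
  }
  profiles <- lapply(tests, detection_profile)
  manifest <- list(metrics = metrics, window_grid_s = grid$seconds,
                   n_subjects = length(cohort$subjects),
                   n_regions = nrow(cohort$subjects[[1L]]$data),
                   T = ncol(cohort$subjects[[1L]]$data), tr_seconds = tr,
                   surrogate_method = surrogate$method,
                   n_surrogates = surrogate$n_surrogates,
                   surrogate_seed = surrogate$seed,
                   alpha = test$alpha, correction = test$correction,
                   null_mode = test$null_mode,
                   highpass_hz = highpass_hz)
  out <- structure(list(tests = tests, profiles = profiles,
                        grid_seconds = grid$seconds, manifest = manifest),
                   class = "dfc_analysis")
  if (!is.null(out_dir)) write_analysis(out, out_dir)
  out
}

#' @export
print.dfc_analysis <- function(x, ...) {
  m <- x$manifest
  cat(sprintf("<dfc_analysis> %d subjects, %d regions, %d metrics x %d windows (%s surrogates, n = %d)\n",
              m$n_subjects, m$n_regions, length(m$metrics),
              length(x$grid_seconds), toupper(m$surrogate_method),
              m$n_surrogates))
  for (met in names(x$tests)) {
    nr <- vapply(x$tests[[met]], `[[`, 0L, "n_reject")
    cat(sprintf("  %-26s dynamic pairs by window: %s\n", met,
                paste(nr, collapse = " ")))
  }
  invisible(x)
}

#' @export
summary.dfc_analysis <- function(object, ...) {
  rows <- do.call(rbind, lapply(names(object$tests), function(met) {
    do.call(rbind, lapply(object$tests[[met]], function(tt) {
      data.frame(metric = met, window_s = tt$window$length_seconds,
                 n_reject = tt$n_reject,
                 tstar = if (length(tt$critical_value_Tstar) == 1L)
                   tt$critical_value_Tstar else NA_real_,
                 stringsAsFactors = FALSE)
    }))
  }))
  class(rows) <- c("summary.dfc_analysis", "data.frame")
  rows
}

# TSV + JSON manifest export of an analysis bundle.
write_analysis <- function(x, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  for (met in names(x$tests)) {
    for (tt in x$tests[[met]]) {
      d <- strength_long(tt$group_mean_strength)
      d$tstar <- if (length(tt$critical_value_Tstar) == 1L)
        tt$critical_value_Tstar else tt$critical_value_Tstar
      d$reject <- ut_vec(tt$reject)
      rows[[length(rows) + 1L]] <- d
    }
  }
  tab <- do.call(rbind, rows)
  utils::write.table(tab, file.path(out_dir, "dfc_tests.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  prof <- do.call(rbind, lapply(names(x$profiles), function(met) {
    p <- x$profiles[[met]]
    data.frame(metric = met, region_i = p$region_i, region_j = p$region_j,
               min_window_s = p$min_window_s, contiguous = p$contiguous,
               detected_windows = vapply(p$detected_windows, paste,
                                         "", collapse = ","),
               stringsAsFactors = FALSE)
  }))
  utils::write.table(prof, file.path(out_dir, "detection_profiles.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(x$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' Test-retest reproducibility experiment
#'
#' Correlates the pairwise group-mean dFC strengths of two analyses (one
#' per cohort, e.g. disjoint halves of a study) for every shared
#' (metric, window) cell.
#'
#' @param analysisA,analysisB `dfc_analysis` objects sharing metrics and
#'   window grid.
#' @return `data.frame` of class `reproducibility_report` with columns
#'   `metric`, `window_s`, `r`.
#' @export
reproducibility_experiment <- function(analysisA, analysisB) {
  stopifnot(inherits(analysisA, "dfc_analysis"),
            inherits(analysisB, "dfc_analysis"))
  if (!identical(names(analysisA$tests), names(analysisB$tests)) ||
      !identical(analysisA$grid_seconds, analysisB$grid_seconds))
    stop_swdfc("analyses disagree on metrics or window grid",
               "swdfc_validation_error")
  rows <- do.call(rbind, lapply(names(analysisA$tests), function(met) {
    do.call(rbind, lapply(seq_along(analysisA$tests[[met]]), function(wi) {
      data.frame(metric = met,
                 window_s = analysisA$grid_seconds[wi],
                 r = test_retest(analysisA$tests[[met]][[wi]]$group_mean_strength,
                                 analysisB$tests[[met]][[wi]]$group_mean_strength),
                 stringsAsFactors = FALSE)
    }))
  }))
  class(rows) <- c("reproducibility_report", "data.frame")
  rows
}
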