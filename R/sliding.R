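#' Convert a window length from seconds to samples
#'
#' `floor(length_seconds / tr_seconds)`; errors if the result is below 2
#' samples.
#'
#' @param length_seconds window length in seconds.
#' @param tr_seconds sampling interval in seconds.
#' @return Integer number of samples.
#' @examples
#' seconds_to_samples(120, 0.72)  # 166
#' @export
seconds_to_samples <- function(length_seconds, tr_seconds) {
  stopifnot(length_seconds > 0, tr_seconds > 0)
  w <- as.integer(floor(length_seconds / tr_seconds))
  if (w < 2L)
    stop_swdfc(sprintf("window of %g s is under 2 samples at TR %g s",
                       length_seconds, tr_seconds),
               "swdfc_window_error")
  w
}

#' Sliding-window specification
#'
#' Rectangular window of a given length in seconds, shifted by
#' `step_samples` (default one TR).
#'
#' @param length_seconds window length in seconds.
#' @param tr_seconds sampling interval, used to derive the length in
#'   samples.
#' @param step_samples positive shift between consecutive windows (default 1).
#' @return List of class `window_spec` with `length_seconds`,
#'   `length_samples`, `step_samples`, `shape = "rectangular"`.
#' @export
window_spec <- function(length_seconds, tr_seconds, step_samples = 1L) {
  stopifnot(step_samples >= 1L)
  structure(list(length_seconds = length_seconds,
                 length_samples = seconds_to_samples(length_seconds, tr_seconds),
                 step_samples = as.integer(step_samples),
                 shape = "rectangular"),
            class = "window_spec")
}

#' Window-length grid
#'
#' The default grid spans 20 to 150 s in steps of 10 s (14 lengths).
#'
#' @param from,to,by grid limits and step, in seconds.
#' @param tr_seconds sampling interval.
#' @param step_samples window shift in samples.
#' @return List of class `window_grid`: `window_spec`s with strictly
#'   increasing lengths.
#' @export
window_grid <- function(from = 20, to = 150, by = 10, tr_seconds = 0.72,
                        step_samples = 1L) {
  secs <- seq(from, to, by = by)
  if (any(diff(secs) <= 0))
    stop_swdfc("window lengths must be strictly increasing", "swdfc_validation_error")
  structure(list(specs = lapply(secs, window_spec, tr_seconds = tr_seconds,
                                step_samples = step_samples),
                 seconds = secs),
            class = "window_grid")
}

#' Windowed metric series for one region pair
#'
#' Slides a rectangular window of `window$length_samples` columns across the
#' series (half-open segments `[k, k + w)`, advancing by
#' `window$step_samples`) and evaluates the metric in each segment.  The
#' MTD metric is handled natively through its own centered formulation with
#' inner half-window equal to the sliding-window length (valid region only).
#'
#' @param set a [roi_ts()] object.
#' @param metric one of [metric_ids()].
#' @param window a [window_spec()].
#' @param pair integer pair `c(i, j)` of region indices.
#' @param config a [metric_config()].
#' @return List of class `windowed_series` with `values` (one value per
#'   window position), `pair`, `metric`, `window`.
#' @export
windowed_metric <- function(set, metric, window, pair,
                            config = metric_config()) {
  stopifnot(inherits(set, "roi_ts"), inherits(window, "window_spec"))
  metric <- match.arg(metric, metric_ids())
  X <- set$data
  w <- window$length_samples
  T <- ncol(X)
  if (w > T)
    stop_swdfc("window does not fit the series", "swdfc_window_error")
  i <- pair[1L]; j <- pair[2L]
  if (metric == "mtd") {
    wi <- config$mtd_inner_w %||% w
    vals <- mtd_series(X[c(i, j), , drop = FALSE], wi, config)[1L, ]
    vals <- vals[seq(1L, length(vals), by = window$step_samples)]
  } else {
    starts <- seq(1L, T - w + 1L, by = window$step_samples)
    vals <- numeric(length(starts))
    for (k in seq_along(starts)) {
      seg <- X[, starts[k]:(starts[k] + w - 1L), drop = FALSE]
      vals[k] <- tryCatch(metric_value(metric, seg, i, j, config),
        swdfc_degenerate_error = function(e)
          stop_swdfc(sprintf("window %d: %s", k, conditionMessage(e)),
                     "swdfc_degenerate_error"))
    }
  }
  structure(list(values = vals, pair = c(i, j), metric = metric,
                 window = window),
            class = "windowed_series")
}

#' dFC strength: variance of a windowed metric series
#'
#' The dynamic-connectivity test statistic: the sample variance (divisor
#' `count - 1`) of the windowed metric values of a pair.
#'
#' @param series a `windowed_series` from [windowed_metric()], or a bare
#'   numeric vector of windowed values.
#' @return Nonnegative variance.
#' @export
dfc_strength <- function(series) {
  v <- if (inherits(series, "windowed_series")) series$values else series
  if (length(v) < 2L)
    stop_swdfc("need at least 2 window positions for a variance",
               "swdfc_insufficient_windows_error")
  var(v)
}

#' Pairwise dFC strength matrix
#'
#' Evaluates [dfc_strength()] for every unordered region pair of a subject
#' at one metric and window, returning a symmetric matrix (diagonal `NA`).
#' Pearson, mutual information and variation of information use compiled
#' step-1 kernels (identical, to numerical precision, to the generic path);
#' the inverse-covariance metric computes one penalized precision matrix per
#' window for all pairs at once.
#'
#' @inheritParams windowed_metric
#' @param engine `"auto"` (compiled fast paths where available),
#'   `"reference"` (force the generic per-pair R path).
#' @return Object of class `dfc_strength_matrix`: fields `values` (n x n),
#'   `metric`, `window`, `region_labels`.
#' @export
dfc_matrix <- function(set, metric, window, config = metric_config(),
                       engine = c("auto", "reference")) {
  stopifnot(inherits(set, "roi_ts"), inherits(window, "window_spec"))
  metric <- match.arg(metric, metric_ids())
  engine <- match.arg(engine)
  n <- nrow(set$data)
  v <- strength_vector(set$data, metric, window, config, engine)
  structure(list(values = sym_from_pairs(v, n),
                 metric = metric, window = window,
                 region_labels = set$region_labels),
            class = "dfc_strength_matrix")
}

# Pair-ordered vector of dFC strengths for one data matrix.  Fast paths are
# used when engine == "auto", the window shape is step-1 rectangular, and
# the metric configuration is the default binning rule.
strength_vector <- function(X, metric, window, config = metric_config(),
                            engine = "auto") {
  w <- window$length_samples
  fast_ok <- engine == "auto" && window$step_samples == 1L &&
    identical(config$bin_rule, "segment_length")
  if (fast_ok && metric == "pearson") {
    series <- cpp_windowed_pearson(X, w)
    return(row_vars(series))
  }
  if (fast_ok && metric %in% c("mutual_information", "variation_of_information")) {
    res <- cpp_windowed_mivi(X, w)
    m <- if (metric == "mutual_information") res$mi else res$vi
    return(row_vars(m))
  }
  if (metric == "icov") {
    # one precision matrix per window covers all pairs
    T <- ncol(X)
    starts <- seq(1L, T - w + 1L, by = window$step_samples)
    pi <- pair_index(nrow(X))
    series <- matrix(NA_real_, nrow(pi), length(starts))
    for (k in seq_along(starts)) {
      P <- sparse_precision(X[, starts[k]:(starts[k] + w - 1L), drop = FALSE],
                            lambda = config$icov_lambda,
                            lw_shrinkage = config$icov_lw_shrinkage)
      series[, k] <- P[cbind(pi[, 1L], pi[, 2L])]
    }
    return(row_vars(series))
  }
  set <- roi_ts(X, 1)  # labels/TR irrelevant for the per-pair loop
  pi <- pair_index(nrow(X))
  vapply(seq_len(nrow(pi)), function(p) {
    dfc_strength(windowed_metric(set, metric, window, pi[p, ], config))
  }, 0.0)
}

# rowwise sample variance without apply() overhead
row_vars <- function(m) {
  k <- ncol(m)
  if (k < 2L)
    stop_swdfc("need at least 2 window positions for a variance",
               "swdfc_insufficient_windows_error")
  mu <- rowMeans(m)
  (rowSums(m * m) - k * mu * mu) / (k - 1)
}

#' Group-mean dFC strength matrix
#'
#' Elementwise mean of the per-subject strength matrices of a cohort, the
#' group-level observed statistic compared against the null critical value.
#'
#' @param cohort a [as_cohort()] cohort.
#' @inheritParams dfc_matrix
#' @export
cohort_mean_dfc <- function(cohort, metric, window, config = metric_config(),
                            engine = c("auto", "reference")) {
  stopifnot(inherits(cohort, "dfc_cohort"))
  mats <- lapply(cohort$subjects, dfc_matrix, metric = metric,
                 window = window, config = config, engine = match.arg(engine))
  values <- Reduce(`+`, lapply(mats, `[[`, "values")) / length(mats)
  out <- mats[[1L]]
  out$values <- values
  out
}

#' @export
print.dfc_strength_matrix <- function(x, ...) {
  v <- ut_vec(x$values)
  cat(sprintf("<dfc_strength_matrix> metric '%s', window %g s (%d samples): %d pairs\n",
              x$metric, x$window$length_seconds, x$window$length_samples,
              length(v)))
  cat(sprintf("  strength range [%.4g, %.4g], median %.4g\n",
              min(v), max(v), median(v)))
  invisible(x)
}

#' Export a strength matrix in long format
#'
#' @param x a `dfc_strength_matrix`.
#' @param subject subject or group label for the output column.
#' @return `data.frame` with columns subject, metric, window_s, region_i,
#'   region_j, value (one row per unordered pair).
#' @export
strength_long <- function(x, subject = "group") {
  stopifnot(inherits(x, "dfc_strength_matrix"))
  pi <- pair_index(nrow(x$values))
  data.frame(subject = subject, metric = x$metric,
             window_s = x$window$length_seconds,
             region_i = x$region_labels[pi[, 1L]],
             region_j = x$region_labels[pi[, 2L]],
             value = ut_vec(x$values),
             stringsAsFactors = FALSE)
}
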