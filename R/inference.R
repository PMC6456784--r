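#' Hypothesis-test configuration
#'
#' @param alpha significance level in (0, 1); default 0.05.
#' @param correction `"bonferroni"` (divide alpha by the number of tested
#'   pairs) or `"none"`.
#' @param null_mode `"aggregated"` (one pooled null distribution for all
#'   pairs, the default) or `"per_pair"`.
#' @return List of class `test_config`.
#' @export
test_config <- function(alpha = 0.05, correction = c("bonferroni", "none"),
                        null_mode = c("aggregated", "per_pair")) {
  stopifnot(alpha > 0, alpha < 1)
  structure(list(alpha = alpha, correction = match.arg(correction),
                 null_mode = match.arg(null_mode)),
            class = "test_config")
}

#' Build the null distribution of dFC strength from surrogate data
#'
#' For every surrogate index `s` and region pair, computes the dFC strength
#' on each subject's `s`-th surrogate copy and averages across subjects,
#' yielding one subject-averaged null sample per surrogate per pair
#' (`n_surrogates` samples per pair).  In aggregated mode all pairs' samples
#' are additionally pooled into one distribution
#' (`n_surrogates x n_pairs` samples).
#'
#' @param cohort a [as_cohort()] cohort.
#' @param surrogates either a list of per-subject [generate_ensemble()]
#'   results (all the same size, aligned with the cohort), or a
#'   [surrogate_spec()] from which per-subject ensembles are generated on
#'   the fly (streaming; copies are not retained).
#' @param metric one of [metric_ids()].
#' @param window a [window_spec()].
#' @param config a [metric_config()].
#' @return Object of class `dfc_null`: `per_pair` (`n_pairs x n_surrogates`
#'   matrix), `pooled`, `metric`, `window`, `n_surrogates`,
#'   `region_labels`.
#' @export
build_null <- function(cohort, surrogates, metric, window,
                       config = metric_config()) {
  res <- null_strengths(cohort, surrogates, metric, window, config)
  res[[metric]]
}

# Workhorse shared by build_null and the experiment drivers: computes the
# subject-averaged surrogate strength matrix for SEVERAL metrics from a
# single pass over the surrogate copies (the copies dominate the cost, so
# metrics sharing them is the practical way to run multi-metric studies).
null_strengths <- function(cohort, surrogates, metrics, window,
                           config = metric_config()) {
  stopifnot(inherits(cohort, "dfc_cohort"))
  metrics <- vapply(metrics, match.arg, "", choices = metric_ids())
  ns <- length(cohort$subjects)
  n <- nrow(cohort$subjects[[1L]]$data)
  np <- n_pairs(n)

  prebuilt <- !inherits(surrogates, "surrogate_spec")
  if (prebuilt) {
    stopifnot(length(surrogates) == ns)
    sizes <- vapply(surrogates, function(e) length(e$copies), 0L)
    if (length(unique(sizes)) != 1L)
      stop_swdfc("surrogate ensembles differ in size across subjects",
                 "swdfc_validation_error")
    S <- sizes[1L]
  } else {
    S <- surrogates$n_surrogates
  }

  acc <- lapply(metrics, function(m) matrix(0, np, S))
  names(acc) <- metrics
  for (si in seq_len(ns)) {
    subj <- cohort$subjects[[si]]
    if (prebuilt) {
      ens <- surrogates[[si]]
      model <- ens$model
    } else {
      subj_seed <- derive_seed(surrogates$seed, si)
      model <- if (surrogates$method == "mvar") fit_mvar(subj, surrogates$p_max)
    }
    for (k in seq_len(S)) {
      if (prebuilt) {
        copy <- ens$copies[[k]]
      } else {
        old <- local_seed(derive_seed(subj_seed, k))
        copy <- if (surrogates$method == "mvpr") mvpr_surrogate(subj)
                else mvar_surrogate(model, subj)
        restore_seed(old)
      }
      for (m in metrics)
        acc[[m]][, k] <- acc[[m]][, k] +
          strength_vector(copy$data, m, window, config)
    }
  }
  out <- lapply(metrics, function(m) {
    a <- acc[[m]] / ns
    structure(list(per_pair = a, pooled = as.vector(a),
                   metric = m, window = window, n_surrogates = S,
                   region_labels = cohort$subjects[[1L]]$region_labels),
              class = "dfc_null")
  })
  names(out) <- metrics
  out
}

#' @export
print.dfc_null <- function(x, ...) {
  cat(sprintf("<dfc_null> metric '%s', window %g s: %d pairs x %d surrogate samples (pooled %d)\n",
              x$metric, x$window$length_seconds, nrow(x$per_pair),
              x$n_surrogates, length(x$pooled)))
  invisible(x)
}

#' Empirical critical value T*
#'
#' One-sided upper critical value of the null distribution: the
#' nearest-rank empirical quantile at level `1 - alpha'`, where `alpha'` is
#' `alpha / n_pairs` under Bonferroni correction and `alpha` otherwise.
#' The upper tail is forced by the one-sided alternative (strength > 0).
#' In per-pair mode one T* per pair is computed from that pair's own
#' samples; in aggregated mode a single T* from the pooled samples.  If the
#' corrected level is finer than the sample resolution the maximum sample
#' is returned with a warning.
#'
#' @param null a [build_null()] result.
#' @param config a [test_config()].
#' @return Single value (aggregated) or vector of per-pair values.
#' @export
critical_value <- function(null, config = test_config()) {
  stopifnot(inherits(null, "dfc_null"), inherits(config, "test_config"))
  m_pairs <- nrow(null$per_pair)
  alpha_eff <- if (config$correction == "bonferroni")
    config$alpha / m_pairs else config$alpha
  if (config$null_mode == "aggregated")
    nearest_rank_upper(null$pooled, alpha_eff)
  else
    apply(null$per_pair, 1L, nearest_rank_upper, alpha = alpha_eff)
}

# nearest-rank upper quantile: the ceil((1 - alpha) * m)-th order statistic
nearest_rank_upper <- function(samples, alpha) {
  m <- length(samples)
  idx <- ceiling((1 - alpha) * m)
  if (idx >= m) {
    if (alpha < 1 / m)
      warning(sprintf("corrected level %.3g below the resolution of %d null samples; using the maximum",
                      alpha, m))
    idx <- m
  }
  sort(samples, partial = idx)[idx]
}

#' Test for dynamic functional connectivity
#'
#' Compares the group-mean observed dFC strength of every pair against the
#' null critical value T*; the null (stationary connectivity, zero strength
#' beyond sampling fluctuation) is rejected where the observed strength is
#' strictly greater than T*.
#'
#' @param group_mean a [cohort_mean_dfc()] strength matrix.
#' @param null a [build_null()] result with matching metric and window.
#' @param config a [test_config()].
#' @return Object of class `dfc_test`: `reject` (symmetric logical matrix),
#'   `critical_value_Tstar`, `group_mean_strength`, `metric`, `window`,
#'   `config`, `n_reject`.
#' @export
test_dfc <- function(group_mean, null, config = test_config()) {
  stopifnot(inherits(group_mean, "dfc_strength_matrix"),
            inherits(null, "dfc_null"))
  if (!identical(group_mean$metric, null$metric) ||
      group_mean$window$length_samples != null$window$length_samples)
    stop_swdfc("strength matrix and null distribution disagree on metric/window",
               "swdfc_validation_error")
  tstar <- critical_value(null, config)
  n <- nrow(group_mean$values)
  obs <- ut_vec(group_mean$values)
  rej <- obs > tstar       # strict: equality is not rejected
  structure(list(reject = sym_from_pairs(rej, n, diag_value = FALSE),
                 critical_value_Tstar = tstar,
                 group_mean_strength = group_mean,
                 metric = group_mean$metric, window = group_mean$window,
                 config = config, n_reject = sum(rej)),
            class = "dfc_test")
}

#' @export
print.dfc_test <- function(x, ...) {
  np <- n_pairs(nrow(x$reject))
  cat(sprintf("<dfc_test> metric '%s', window %g s: %d of %d pairs dynamic (alpha %g, %s, %s null)\n",
              x$metric, x$window$length_seconds, x$n_reject, np,
              x$config$alpha, x$config$correction, x$config$null_mode))
  if (length(x$critical_value_Tstar) == 1L)
    cat(sprintf("  T* = %.6g\n", x$critical_value_Tstar))
  invisible(x)
}

#' Minimum detecting window per pair
#'
#' Summarizes a list of [test_dfc()] results over a window grid (same
#' metric, one result per grid window): for each pair, the smallest window
#' length at which the pair is detected, and whether the detected set is
#' contiguous, i.e. exactly all grid windows at or above that minimum.
#' Non-contiguous detection patterns are flagged (the dagger convention)
#' and the explicit detected list retained.
#'
#' @param results list of `dfc_test` objects covering the full grid (any
#'   order).
#' @return `data.frame` with columns `region_i`, `region_j`,
#'   `min_window_s` (NA when never detected), `contiguous`, and a list
#'   column `detected_windows` of detected lengths in seconds.
#' @export
detection_profile <- function(results) {
  stopifnot(length(results) >= 1L,
            all(vapply(results, inherits, TRUE, "dfc_test")))
  metric <- unique(vapply(results, `[[`, "", "metric"))
  if (length(metric) != 1L)
    stop_swdfc("results mix metrics", "swdfc_validation_error")
  secs <- vapply(results, function(r) r$window$length_seconds, 0.0)
  if (anyDuplicated(secs))
    stop_swdfc("duplicate window lengths in results", "swdfc_validation_error")
  ord <- order(secs)
  secs <- secs[ord]; results <- results[ord]
  n <- nrow(results[[1L]]$reject)
  pi <- pair_index(n)
  det <- vapply(results, function(r) ut_vec(r$reject), logical(n_pairs(n)))
  if (is.null(dim(det))) det <- matrix(det, nrow = 1L)
  labels <- results[[1L]]$group_mean_strength$region_labels
  rows <- lapply(seq_len(nrow(pi)), function(p) {
    d <- which(det[p, ])
    if (!length(d))
      return(list(min_window_s = NA_real_, contiguous = NA,
                  detected_windows = numeric(0)))
    suffix <- seq.int(min(d), length(secs))
    list(min_window_s = secs[min(d)],
         contiguous = identical(d, suffix),
         detected_windows = secs[d])
  })
  out <- data.frame(region_i = labels[pi[, 1L]], region_j = labels[pi[, 2L]],
                    min_window_s = vapply(rows, `[[`, 0.0, "min_window_s"),
                    contiguous = vapply(rows, `[[`, NA, "contiguous"),
                    stringsAsFactors = FALSE)
  out$detected_windows <- lapply(rows, `[[`, "detected_windows")
  attr(out, "metric") <- metric
  attr(out, "grid_seconds") <- secs
  out
}

#' Test-retest reproducibility of dFC estimates
#'
#' Pearson correlation between the vectorized pairwise strengths (upper
#' triangles) of two group-mean strength matrices, e.g. the test and retest
#' halves of a study.
#'
#' @param groupA_mean,groupB_mean `dfc_strength_matrix` objects with the
#'   same regions, metric and window.
#' @return Correlation in `[-1, 1]`.
#' @export
test_retest <- function(groupA_mean, groupB_mean) {
  stopifnot(inherits(groupA_mean, "dfc_strength_matrix"),
            inherits(groupB_mean, "dfc_strength_matrix"))
  if (!identical(groupA_mean$metric, groupB_mean$metric) ||
      !identical(groupA_mean$region_labels, groupB_mean$region_labels) ||
      groupA_mean$window$length_samples != groupB_mean$window$length_samples)
    stop_swdfc("strength matrices disagree on regions/metric/window",
               "swdfc_validation_error")
  pearson_corr(ut_vec(groupA_mean$values), ut_vec(groupB_mean$values))
}
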