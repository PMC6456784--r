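# Simulation experiments with known ground truth.  These are the package's
# calibration studies: type-I error on stationary cohorts, power on cohorts
# with a designed dynamic pair, and test-retest structure.  The parameter
# defaults are the study conditions documented in the methods vignette.

#' One type-I-error replicate on a stationary synthetic cohort
#'
#' Generates a stationary cohort (no dynamic pairs), builds the aggregated
#' MVPR null and the observed group-mean strengths for each requested
#' metric, and tests every pair at `alpha` with Bonferroni correction.
#' Under the null every rejection is a false positive, so the rejection
#' fraction across replicates estimates the realized family-wise-corrected
#' per-pair type-I error.
#'
#' @param seed replicate seed (drives cohort and surrogates).
#' @param n_regions,n_subjects,T,tr_seconds cohort dimensions
#'   (defaults 8 regions, 10 subjects, 800 points at TR 0.72 s).
#' @param n_surrogates MVPR copies per subject (default 100).
#' @param window_seconds window length (default 60 s).
#' @param metrics metrics to test (default Pearson and mutual information).
#' @param alpha significance level (default 0.05, Bonferroni-corrected).
#' @return Named list per metric: logical vector of per-pair rejections.
#' @export
experiment_type_i <- function(seed, n_regions = 8L, n_subjects = 10L,
                              T = 800L, tr_seconds = 0.72,
                              n_surrogates = 100L, window_seconds = 60,
                              metrics = c("pearson", "mutual_information"),
                              alpha = 0.05) {
  spec <- sim_spec(n_regions = n_regions, T = T, tr_seconds = tr_seconds,
                   n_subjects = n_subjects, seed = seed)
  cohort <- gen_cohort(spec)
  window <- window_spec(window_seconds, tr_seconds)
  sspec <- surrogate_spec("mvpr", n_surrogates = n_surrogates,
                          seed = derive_seed(seed, 777L))
  nulls <- null_strengths(cohort, sspec, metrics, window)
  cfg <- test_config(alpha = alpha, correction = "bonferroni",
                     null_mode = "aggregated")
  out <- lapply(metrics, function(m) {
    gm <- cohort_mean_dfc(cohort, m, window)
    ut_vec(test_dfc(gm, nulls[[m]], cfg)$reject)
  })
  names(out) <- metrics
  out
}

#' One power-study run with a designed dynamic pair
#'
#' Generates a cohort whose pair (1, 2) carries gain-modulated shared
#' coupling (modulation frequency `f_mod_hz`), runs the aggregated-null
#' MVPR test for the given metric and window, and reports whether the
#' designed pair is detected.
#'
#' @param seed run seed.
#' @param gain coupling amplitude `a` (0 = stationary control).
#' @param f_mod_hz modulation frequency (default 0.016 Hz).
#' @param n_regions,n_subjects,T,tr_seconds cohort dimensions (defaults
#'   6 regions, 10 subjects, 1200 points at TR 0.72 s).
#' @param n_surrogates MVPR copies per subject (default 100).
#' @param window_seconds window length (default 150 s, the top of the
#'   standard grid).
#' @param metric metric under study (default mutual information).
#' @param alpha significance level (default 0.05, Bonferroni-corrected).
#' @return List with `detected` (logical, the designed pair), `n_reject`
#'   (total rejections) and `tstar`.
#' @export
experiment_power <- function(seed, gain, f_mod_hz = 0.016, n_regions = 6L,
                             n_subjects = 10L, T = 1200L, tr_seconds = 0.72,
                             n_surrogates = 100L, window_seconds = 150,
                             metric = "mutual_information", alpha = 0.05) {
  dyn <- if (gain > 0)
    list(list(i = 1L, j = 2L, amplitude = gain, f_mod_hz = f_mod_hz))
  else list()
  spec <- sim_spec(n_regions = n_regions, T = T, tr_seconds = tr_seconds,
                   n_subjects = n_subjects, dynamic_pairs = dyn, seed = seed)
  cohort <- gen_cohort(spec)
  window <- window_spec(window_seconds, tr_seconds)
  sspec <- surrogate_spec("mvpr", n_surrogates = n_surrogates,
                          seed = derive_seed(seed, 888L))
  null <- build_null(cohort, sspec, metric, window)
  cfg <- test_config(alpha = alpha, correction = "bonferroni",
                     null_mode = "aggregated")
  res <- test_dfc(cohort_mean_dfc(cohort, metric, window), null, cfg)
  list(detected = res$reject[1L, 2L], n_reject = res$n_reject,
       tstar = res$critical_value_Tstar)
}
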