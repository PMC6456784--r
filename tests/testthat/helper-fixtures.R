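# Fixtures are generated in code; nothing is read from disk.

make_ts <- function(n = 4, T = 120, tr = 0.72, seed = 1, id = "s1") {
  set.seed(seed)
  roi_ts(matrix(rnorm(n * T), n, T), tr, subject_id = id)
}

make_cohort <- function(n_subjects = 3, n = 4, T = 120, tr = 0.72, seed = 1) {
  as_cohort(lapply(seq_len(n_subjects), function(k)
    make_ts(n, T, tr, seed = seed + k, id = sprintf("s%d", k))))
}

# Minimal dfc_test construction for detection-profile logic tests: a fake
# rejection pattern at one window, wrapped in the classes the profiling
# code expects.
fake_test <- function(reject_pairs, window_s, n = 4, metric = "pearson",
                      tr = 1) {
  np <- n * (n - 1) / 2
  rej <- rep(FALSE, np)
  rej[reject_pairs] <- TRUE
  w <- window_spec(window_s, tr)
  gm <- structure(list(values = swdfc:::sym_from_pairs(runif(np), n),
                       metric = metric, window = w,
                       region_labels = sprintf("R%02d", seq_len(n))),
                  class = "dfc_strength_matrix")
  structure(list(reject = swdfc:::sym_from_pairs(rej, n, diag_value = FALSE),
                 critical_value_Tstar = 0.5, group_mean_strength = gm,
                 metric = metric, window = w, config = test_config(),
                 n_reject = sum(rej)),
            class = "dfc_test")
}
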