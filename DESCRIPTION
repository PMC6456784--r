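Package: swdfc
Title: Sliding-Window Assessment of Dynamic Functional Connectivity
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Statistical assessment of dynamic functional connectivity (dFC)
    in multivariate BOLD-like time series with the sliding-window technique.
    Implements ten windowed pairwise connectivity metrics (Pearson full and
    partial correlation, L1-penalized inverse covariance, Spearman full and
    partial correlation, Kendall correlation, mutual information, variation
    of information, symmetrized Kullback-Leibler divergence, and
    multiplication of temporal derivatives), a variance-of-windowed-metric
    dFC statistic, surrogate null data generation by multivariate phase
    randomization (MVPR) and multivariate autoregressive (MVAR) residual
    resampling with SBC order selection, per-pair and aggregated empirical
    null distributions with Bonferroni-corrected hypothesis testing,
    minimum-detecting-window profiling, test-retest reproducibility of dFC
    estimates, and a synthetic multi-subject cohort generator with known
    ground truth for power and type-I-error studies.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    signal,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
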