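# swdfc — sliding-window assessment of dynamic functional connectivity

`swdfc` decides, from multivariate resting-state BOLD-like time series,
which region pairs exhibit statistically significant *time-varying*
functional connectivity (dFC), as opposed to the spurious fluctuations
that sliding-window estimates show even on perfectly stationary signals.
It is aimed at neuroimaging methodologists who want the complete
surrogate-based decision pipeline — not just windowed correlation
matrices — with every estimator choice explicit, configurable and tested.

## The statistic and the test

For regions *i*, *j*, a connectivity metric *m*, and a rectangular window
of length *w* samples shifted by one TR, the windowed metric series is

&nbsp;&nbsp;&nbsp;&nbsp;v<sub>ij</sub>(k) = m( X[i, k..k+w), X[j, k..k+w) ), k = 1 … T − w + 1,

and the dFC statistic is its variance across window positions,
σ²<sub>ij</sub> = Var<sub>k</sub>[v<sub>ij</sub>(k)], averaged over
subjects at the group level.  The hypotheses are

&nbsp;&nbsp;&nbsp;&nbsp;H₀: σ² = 0 (stationary FC) &nbsp; vs &nbsp; H₁: σ² > 0 (dFC),

tested against an empirical null built from surrogate data that preserve
stationary structure but destroy time-locked dynamics:

* **MVPR** — multivariate phase randomization: every region's Fourier
  transform is multiplied by one *common* random phase vector (Hermitian
  symmetry imposed), preserving all amplitude spectra and cross-spectra
  exactly;
* **MVAR** — a least-squares vector autoregression with SBC-selected
  order, surrogates built by propagating uniformly resampled residual
  columns through the fitted recursion from a random seed block.

Per surrogate index the subject-averaged σ² gives one null sample per
pair; pooling all pairs (default) gives a single high-resolution null
(e.g. 250 × 78 = 19,500 samples for 13 regions).  The critical value T\*
is the nearest-rank upper quantile at level 1 − α/m (Bonferroni over m
pairs, α = 0.05 default); a pair is dynamic when its observed statistic
strictly exceeds T\*.

Ten metrics are provided: `pearson`, `pearson_partial`, `icov`
(L1-penalized inverse covariance, λ = 0.1), `spearman`,
`spearman_partial`, `kendall`, `mutual_information`,
`variation_of_information`, `kl_symmetrized`, `mtd` (multiplication of
temporal derivatives).  Windowed Pearson and MI/VI run through compiled
sliding kernels; every metric also has a plain R reference path and the
two are tested for equality.

## Worked example

Simulate a 10-subject cohort in which exactly one pair (regions 1–2)
carries genuine dynamic coupling — a shared latent signal whose gain on
region 2 oscillates at 0.016 Hz — and run the full pipeline:

```r
library(swdfc)
spec <- sim_spec(n_regions = 6, T = 1200, tr_seconds = 0.72, n_subjects = 10,
                 dynamic_pairs = list(list(i = 1L, j = 2L, amplitude = 0.6,
                                           f_mod_hz = 0.016)),
                 seed = 1)
cohort <- gen_cohort(spec)
res <- run_full_analysis(
  cohort,
  metrics = c("pearson", "mutual_information"),
  grid = window_grid(from = 40, to = 80, by = 20, tr_seconds = 0.72),
  surrogate = surrogate_spec("mvpr", n_surrogates = 100, seed = 2))
res
```

```
<dfc_analysis> 10 subjects, 6 regions, 2 metrics x 3 windows (MVPR surrogates, n = 100)
  pearson                    dynamic pairs by window: 1 1 1
  mutual_information         dynamic pairs by window: 0 0 0
```

`summary(res)` lists one row per metric–window cell with the rejection
count and critical value:

```
              metric window_s n_reject      tstar
1            pearson       40        1 0.03243123
2            pearson       60        1 0.02187605
3            pearson       80        1 0.01697321
4 mutual_information       40        0 0.04230264
5 mutual_information       60        0 0.03562073
6 mutual_information       80        0 0.03092657
```

and the detection profile confirms the single detected pair is the
designed one, found at every probed window:

```r
subset(res$profiles$pearson, !is.na(min_window_s))
#   region_i region_j min_window_s contiguous detected_windows
# 1      R01      R02           40       TRUE       40, 60, 80
```

Windowed Pearson finds the pair (the oscillating gain makes the windowed
correlation swing); windowed MI does not at these settings — a measured
property of sinusoidally sign-modulated coupling discussed in the methods
vignette (`vignettes/sliding-window-dfc.Rmd`), together with every
estimator convention, the synthetic generator's design, and the
calibration studies.

A thin command-line driver for shell use lives at `inst/cli/swdfc`
(subcommands `simulate`, `analyze`, `reproducibility`).

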