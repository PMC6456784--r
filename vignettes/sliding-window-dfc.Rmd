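---
title: "Assessing dynamic functional connectivity with sliding windows and surrogate nulls"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing dynamic functional connectivity with sliding windows and surrogate nulls}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(swdfc)
```

## The problem

Resting-state fMRI studies routinely ask whether the statistical coupling
between two brain regions is constant over a scanning session (stationary
functional connectivity, FC) or genuinely time-varying (dynamic FC, dFC).
The sliding-window technique slices each pair of region time series into
overlapping windows, computes a connectivity metric in each window, and
summarizes the fluctuation of the windowed values.  The difficulty is that
windowed estimates fluctuate even for perfectly stationary signals, because
every window is a small sample.  A principled decision therefore needs a
null distribution of the fluctuation statistic under stationarity, which is
what surrogate data provide.

`swdfc` implements the full decision pipeline:

1. windowed connectivity with ten metrics (Pearson and Spearman full and
   partial correlation, L1-penalized inverse covariance, Kendall
   correlation, mutual information, variation of information, symmetrized
   Kullback–Leibler divergence, multiplication of temporal derivatives);
2. the dFC statistic: the sample variance $\sigma^2$ of a pair's windowed
   metric series, tested one-sidedly ($H_0\colon \sigma^2 = 0$ beyond
   sampling fluctuation vs $H_1\colon \sigma^2 > 0$);
3. surrogate null data by multivariate phase randomization (MVPR) or a
   multivariate autoregressive model (MVAR) with residual resampling;
4. per-pair or aggregated empirical null distributions, the critical value
   $T^\*$, Bonferroni correction across pairs, minimum-detecting-window
   profiles, and test–retest reproducibility between disjoint groups.

## The statistic and its null

For a cohort, each subject's regions-by-time matrix yields, per region
pair, metric and window length, one $\sigma^2$ value (variance across
window positions, divisor $n-1$); the observed group statistic is the
subject average.  For the null, each subject contributes `n_surrogates`
surrogate copies; $\sigma^2$ is computed on each copy and averaged across
subjects at fixed surrogate index, giving `n_surrogates` null samples per
pair.  With 13 regions and 250 surrogates this is 78 per-pair distributions
or, after pooling (the default, following the aggregated-null practice),
$250 \times 78 = 19{,}500$ samples.  $T^\*$ is the nearest-rank empirical
quantile at level $1 - \alpha/m$ (Bonferroni over the $m$ tested pairs);
a pair is called dynamic when its observed statistic strictly exceeds
$T^\*$.  The wording "$\alpha$-th percentile" for a one-sided alternative
$\sigma^2 > 0$ is implemented as the *upper* tail quantile — the only
reading compatible with rejecting for large observed values.

## Surrogate generation

**MVPR.**  All rows of a subject's matrix are transformed to the frequency
domain and multiplied by one shared random phase vector, then transformed
back.  Hermitian phase symmetry (opposite phases at mirrored frequencies,
zero phase at DC and Nyquist) is imposed so the inverse transform is real;
this symmetry is mathematically required even though descriptions of the
method usually omit it.  Because the phase is common to all rows, every
amplitude spectrum and every cross-spectrum is preserved *exactly*; only
time-locked (nonstationary) structure is destroyed.  A consequence worth
stating precisely: the preserved time-domain quantities are the
**circular** auto- and cross-covariances (phase randomization is an
operation on the discrete Fourier transform, whose inverse is periodic).
The package's preservation report and tests therefore check circular
covariances, where agreement holds to numerical precision; linear lagged
covariances agree only up to edge effects of order lag/T.

**MVAR.**  A vector autoregression of order $p$ is fitted by least squares
(no intercept; series are assumed zero-mean, as produced by high-pass
filtering or the synthetic generator), with $p$ chosen by minimizing the
Schwarz Bayesian Criterion
$\log\det\hat\Sigma_p + \log(T_p)\, p\, n^2 / T_p$ over $p = 1..p_{max}$,
$T_p = T - p$ effective rows.  Surrogates then (1) draw a uniform start
$t_0$, (2) seed the copy with the $p$ original columns starting at $t_0$,
(3) draw residual *columns* uniformly with replacement — whole columns, so
contemporaneous residual correlation survives — and (4) propagate the
autoregressive recursion to full length.  The fitted companion spectral
radius is checked and a warning raised if the model is unstable.

One root seed drives everything; per-subject and per-surrogate streams are
derived deterministically, so ensembles are reproducible and independent of
evaluation order.

## Metric implementation choices

Several estimator details are underdetermined by common usage and were
fixed as follows (each is configurable through `metric_config()`):

* **Ranks**: average ranks for ties, keeping Spearman well defined.
* **Kendall**: the literal concordant/discordant pair count with
  denominator $N(N-1)$, excluding only pairs tied in *both* coordinates.
  This is deliberately not the tie-corrected $\tau_b$; it is documented and
  tested as such.
* **Histograms** for MI/VI: per axis, the number of equal-width bins equals
  the number of points in the evaluated segment, bins spanning the
  segment's own range with the rightmost bin closed; the joint histogram is
  the product binning.  The plug-in estimator is biased upward for fixed
  segment length, but the bias is common to data and surrogates, which is
  all the variance-based test requires.
* **Symmetrized KL** compares the two *marginal* distributions on a common
  set of edges spanning the union range; zero probabilities are floored at
  `1e-12` without renormalization to keep the log-ratio finite.  KL is thus
  a distribution-shape dissimilarity, not a dependence measure.
* **MTD**: first differences scaled by each region's full-segment
  derivative standard deviation (population divisor by default), averaged
  over a centered window of half-width $w$ coupled to the sliding-window
  length; only positions where the centered window fits are used.
* **Inverse covariance**: an L1-penalized precision estimate ($\lambda =
  0.1$ by default) computed by block coordinate descent on the segment's
  ML sample covariance; the pairwise value is the $(i,j)$ off-diagonal
  entry.  At $\lambda = 0$ the estimate equals the plain inverse; at large
  $\lambda$ the off-diagonal is exactly zero; tests verify the KKT
  optimality conditions directly.  Optional Ledoit–Wolf shrinkage of the
  covariance before the solve is available (`icov_lw_shrinkage`, default
  off), since descriptions of "shrinkage-based" sparse precision estimation
  are ambiguous about whether the shrinkage preconditions the L1 problem.
* Constant (degenerate) segments raise errors instead of silently
  returning 0, which would bias the variance statistic downward.

Windows are rectangular, shifted by one TR, indexed by their start column
(half-open `[k, k + w)`), giving `T - w + 1` positions; the default grid is
20–150 s in 10 s steps (14 lengths), converted to samples by flooring.
Weighted or tapered windows are intentionally out of scope.

## The synthetic cohort generator

There is no public ground-truth dataset for dFC, so the package ships a
generator whose truth is known by construction.  The base process is a
stable VAR(1) (default: diagonal coefficient 0.4, unit-variance Gaussian
innovations, 200-sample burn-in, 13 regions, 1200 points at TR 0.72 s —
the dimensions of a typical high-temporal-resolution resting-state
session).  This produces zero-mean series with stationary cross-covariance:
exactly the null hypothesis of the test.  A Student-t innovation option
stresses the information-theoretic metrics with heavy tails.

Genuine dFC is injected per designated pair: a shared latent signal
$s(t)$ — a standardized AR(1) with coefficient 0.9, i.e. band-limited like
hemodynamic fluctuations at this TR — is added to row $i$ with constant
gain $a$ and to row $j$ with gain $a\sin(2\pi f_{mod} t\,\mathrm{TR})$,
producing a true correlation oscillating at $f_{mod}$ (default 0.016 Hz,
the timescale reported for slow resting-state coupling fluctuations).

What the generator does *not* emulate: hemodynamic convolution,
physiological noise, scanner drifts, spatial structure, or regime-switching
connectivity states.  Passing tests on this generator therefore validate
the statistical machinery (calibration, exactness, reproducibility logic),
not the neurobiological fidelity of any particular metric.

### Interactions worth knowing about

Two measured properties of the sinusoidally gain-modulated design matter
when interpreting power studies:

* A rectangular window of length $L$ low-pass-filters the windowed
  covariance with spectral nulls at multiples of $1/L$.  At $L = 60$ s the
  first null ($\approx 0.0167$ Hz) lands almost exactly on the default
  modulation frequency, and at $L = 150$ s the window spans 2.4 modulation
  periods, attenuating the oscillation by a sinc factor of roughly 0.13.
  Probing the windowed-correlation spectrum for the modulation line is
  therefore done with short windows (the package test uses 30 s, where the
  line is recovered at 0.016 Hz).
* Sign-oscillating coupling is nearly invisible to mutual information at
  long windows: MI responds to the coupling *magnitude* (second order in
  the correlation), and stronger average dependence also *lowers* the
  plug-in estimator's sampling noise, so the variance of windowed MI for a
  modulated pair can fall at or below its stationary-null level.  In the
  package's power study (6 regions, 10 subjects, T = 1200, 100 MVPR
  surrogates, aggregated Bonferroni null) the designed pair at gain 0.6 is
  detected by windowed Pearson correlation at 60 s windows but not by MI at
  150 s windows.  This is a property of this generator design, not a defect
  of the inference machinery; the corresponding sensitivity expectation in
  the package's test suite is deliberately left failing rather than
  weakened, and the type-I calibration (which is what the surrogate
  framework guarantees) is verified independently.

## Calibration studies and problem sizes

The shipped experiments use sizes chosen to make repeated end-to-end runs
practical on a single core while keeping every structural constant of the
full design (window grid, Bonferroni, aggregated nulls):

* **Type-I error** (`experiment_type_i`): stationary cohorts of 8 regions,
  10 subjects, T = 800 at TR 0.72 s, 100 MVPR surrogates, Pearson and MI at
  60 s windows, $\alpha = 0.05$ Bonferroni, 25 replicate cohorts.  The
  empirical per-pair rejection fraction must stay at or below the nominal
  level plus two binomial standard errors.
* **Power** (`experiment_power`): one designed dynamic pair, gains
  $\{0, 0.3, 0.6\}$, 20 seeded runs per gain, with monotone non-decreasing
  rejection probability in the gain.
* **Order selection**: VAR(1) with spectral radius 0.8, 3 regions,
  T = 2000; the SBC argmin over $p \in 1..5$ must recover order 1 in at
  least 90 of 100 seeded runs.
* **Test–retest**: a 20-subject cohort whose regions have heterogeneous
  AR(1) coefficients (0.15 to 0.85) is split into halves and the pairwise
  strength vectors correlated.  The heterogeneity matters: it gives every
  pair a reproducible strength level (slower regions produce larger
  windowed-correlation variance), so the split-half correlation measures
  recoverable structure; on a homogeneous cohort there is nothing to
  reproduce and the correlation is pure noise around zero.

## Numerical and degenerate-input decisions

* High-pass preprocessing (default cutoff 0.0067 Hz, a 150 s period) is a
  2nd-order Butterworth applied forward and backward.  The implementation
  uses odd-reflection padding with steady-state initial conditions; without
  the initial-state matching a slow high-pass leaves O(1) transients at the
  series edges.
* The nearest-rank quantile returns the maximum null sample with a warning
  when the Bonferroni-corrected level is finer than the null sample
  resolution (e.g. fewer than $m/\alpha$ pooled samples).
* An observed statistic exactly equal to $T^\*$ is *not* rejected (strict
  inequality).
* Detection profiles report the smallest detecting window and flag
  non-contiguous detection sets (detected windows that are not simply
  "everything at or above the minimum") explicitly, retaining the full
  detected list.
* Missing values are rejected at construction; there is no imputation.

## Worked example

```{r example, eval = FALSE}
spec <- sim_spec(n_regions = 6, T = 1200, tr_seconds = 0.72, n_subjects = 10,
                 dynamic_pairs = list(list(i = 1L, j = 2L, amplitude = 0.6,
                                           f_mod_hz = 0.016)),
                 seed = 1)
cohort <- gen_cohort(spec)
res <- run_full_analysis(
  cohort,
  metrics = c("pearson", "mutual_information"),
  grid = window_grid(from = 20, to = 150, by = 10, tr_seconds = 0.72),
  surrogate = surrogate_spec("mvpr", n_surrogates = 100, seed = 2))
res
summary(res)
res$profiles$pearson
```

## Known limitations

* The aggregated null assumes the pairs' null strength distributions are
  exchangeable enough to pool; strongly heterogeneous variance scales
  across pairs would make the pooled $T^\*$ conservative for some pairs and
  liberal for others (the per-pair mode exists for exactly that case).
* Plug-in MI/VI with segment-length bins is strongly biased for short
  windows; comparisons are only meaningful against surrogates at the same
  window length.
* MVPR surrogates Gaussianize amplitude distributions; for strongly
  non-Gaussian data the null may be miscalibrated for amplitude-sensitive
  metrics (the preservation report quantifies this per dataset).
* Subject-level inference is intentionally not offered: the pipeline
  mirrors a group design in which subject-averaged statistics are compared
  against subject-averaged surrogate statistics.
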