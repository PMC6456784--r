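#' Synthetic cohort specification
#'
#' Defines a multi-subject generator of zero-mean, BOLD-like multivariate
#' time series with known ground truth.  The base process is a stable
#' VAR(1) (stationary cross-covariance, the null condition of the dFC
#' test).  Optional "dynamic pairs" inject genuine time-varying coupling:
#' a shared standardized latent signal `s(t)` (an AR(1) with coefficient
#' 0.9, band-limited like hemodynamic fluctuations) is added to row `i`
#' with constant gain `a` and to row `j` with slowly oscillating gain
#' `c(t) = a sin(2 pi f_mod t TR)`, so the pair's true correlation
#' oscillates at `f_mod` (default 0.016 Hz, the timescale at which slow
#' resting-state coupling fluctuations have been reported).
#'
#' @param n_regions number of regions (default 13).
#' @param T time points per subject (default 1200).
#' @param tr_seconds repetition time (default 0.72 s).
#' @param n_subjects subjects in the cohort.
#' @param base_coeff VAR(1) coefficient matrix (default diagonal 0.4);
#'   spectral radius must be below 1.
#' @param innovation_sd innovation standard deviation (default 1).
#' @param dynamic_pairs list of `list(i, j, amplitude, f_mod_hz)` entries;
#'   amplitudes in `[0, 1)`.
#' @param innovation_df if finite, Student-t degrees of freedom for
#'   heavy-tailed innovations (default `Inf` = Gaussian).
#' @param latent_ar AR(1) coefficient of the shared latent signal
#'   (default 0.9).
#' @param burn_in initial samples discarded to remove transients
#'   (default 200).
#' @param seed root seed; subject `k` uses an independent derived stream.
#' @return List of class `sim_spec`.
#' @export
sim_spec <- function(n_regions = 13L, T = 1200L, tr_seconds = 0.72,
                     n_subjects = 1L, base_coeff = NULL, innovation_sd = 1,
                     dynamic_pairs = list(), innovation_df = Inf,
                     latent_ar = 0.9, burn_in = 200L, seed = 1L) {
  stopifnot(n_regions >= 2L, T >= 2L, tr_seconds > 0, n_subjects >= 1L,
            innovation_sd > 0, burn_in >= 0L, abs(latent_ar) < 1)
  if (is.null(base_coeff)) base_coeff <- diag(0.4, n_regions)
  stopifnot(nrow(base_coeff) == n_regions, ncol(base_coeff) == n_regions)
  rho <- max(Mod(eigen(base_coeff, only.values = TRUE)$values))
  if (rho >= 1)
    stop_swdfc(sprintf("base VAR(1) is unstable (spectral radius %.3f)", rho),
               "swdfc_validation_error")
  nyquist <- 1 / (2 * tr_seconds)
  for (dp in dynamic_pairs) {
    stopifnot(dp$i >= 1L, dp$j >= 1L, dp$i != dp$j,
              dp$i <= n_regions, dp$j <= n_regions,
              dp$amplitude >= 0, dp$amplitude < 1,
              dp$f_mod_hz > 0, dp$f_mod_hz < nyquist)
  }
  structure(list(n_regions = as.integer(n_regions), T = as.integer(T),
                 tr_seconds = tr_seconds, n_subjects = as.integer(n_subjects),
                 base_coeff = base_coeff, innovation_sd = innovation_sd,
                 dynamic_pairs = dynamic_pairs, innovation_df = innovation_df,
                 latent_ar = latent_ar, burn_in = as.integer(burn_in),
                 seed = as.integer(seed)),
            class = "sim_spec")
}

#' Generate one synthetic subject
#'
#' Deterministic for a fixed `(spec$seed, subject_index)`.  The VAR(1)
#' innovations and the latent dynamic-pair signals are always drawn in the
#' same order, so setting all dynamic-pair amplitudes to zero reproduces
#' the pure stationary draw exactly.
#'
#' @param spec a [sim_spec()].
#' @param subject_index positive subject number within the cohort.
#' @return A [roi_ts()] object.
#' @export
gen_subject <- function(spec, subject_index = 1L) {
  stopifnot(inherits(spec, "sim_spec"), subject_index >= 1L)
  old <- local_seed(derive_seed(spec$seed, subject_index))
  on.exit(restore_seed(old))
  n <- spec$n_regions
  total <- spec$T + spec$burn_in
  innov <- if (is.finite(spec$innovation_df)) {
    df <- spec$innovation_df
    matrix(stats::rt(n * total, df) * sqrt((df - 2) / df), n, total) *
      spec$innovation_sd
  } else {
    matrix(rnorm(n * total, sd = spec$innovation_sd), n, total)
  }
  X <- matrix(0, n, total)
  X[, 1L] <- innov[, 1L]
  A <- spec$base_coeff
  for (t in 2:total) X[, t] <- A %*% X[, t - 1L] + innov[, t]
  X <- X[, (spec$burn_in + 1L):total, drop = FALSE]
  tt <- seq_len(spec$T)
  for (dp in spec$dynamic_pairs) {
    e <- rnorm(spec$T)                       # always consumed, even at a = 0
    s <- as.numeric(stats::filter(e, spec$latent_ar, method = "recursive"))
    s <- s * sqrt(1 - spec$latent_ar^2)      # standardize to unit variance
    gain_j <- dp$amplitude * sin(2 * pi * dp$f_mod_hz * tt * spec$tr_seconds)
    X[dp$i, ] <- X[dp$i, ] + dp$amplitude * s
    X[dp$j, ] <- X[dp$j, ] + gain_j * s
  }
  roi_ts(X, spec$tr_seconds,
         subject_id = sprintf("sim%03d", subject_index))
}

#' Generate a synthetic cohort
#'
#' `spec$n_subjects` independent subjects, deterministic per seed.
#'
#' @param spec a [sim_spec()].
#' @return A [as_cohort()] cohort.
#' @export
gen_cohort <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  as_cohort(lapply(seq_len(spec$n_subjects), function(k) gen_subject(spec, k)))
}

# Stationary covariance of the base VAR(1): solves the discrete Lyapunov
# equation Sigma = A Sigma A' + Q by fixed-point iteration (used as an
# oracle in tests and for documentation of the generator's ground truth).
var1_stationary_cov <- function(A, Q, iter = 1000L, tol = 1e-12) {
  S <- Q
  for (k in seq_len(iter)) {
    S_new <- A %*% S %*% t(A) + Q
    if (max(abs(S_new - S)) < tol) return(S_new)
    S <- S_new
  }
  S
}
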