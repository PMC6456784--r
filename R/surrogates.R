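#' Multivariate phase-randomization (MVPR) surrogate
#'
#' Multiplies the discrete Fourier transform of every region's series by
#' one common random phase vector, uniform on `[0, 2pi)` per frequency,
#' with Hermitian symmetry imposed (opposite phases at mirrored
#' frequencies; zero phase at DC and, for even length, at Nyquist) so the
#' inverse transform is real.  Because all rows share the phase draw, every
#' per-row amplitude spectrum and every pairwise cross-spectrum -- hence all
#' circular auto- and cross-covariances -- are preserved exactly; only
#' nonstationary (time-locked) structure is destroyed.
#'
#' @param set a [roi_ts()] object with at least 4 time points.
#' @param phases optional explicit phase vector of length `T` (testing
#'   hook); an all-zero vector reproduces the input.  By default drawn from
#'   the current RNG stream.
#' @return A surrogate `roi_ts` with the same shape, TR and labels.
#' @export
mvpr_surrogate <- function(set, phases = NULL) {
  stopifnot(inherits(set, "roi_ts"))
  T <- ncol(set$data)
  if (T < 4L)
    stop_swdfc("need at least 4 time points", "swdfc_validation_error")
  phi <- phases %||% runif(T, 0, 2 * pi)
  stopifnot(length(phi) == T)
  # Hermitian symmetry: phi(DC) = 0, phi(-f) = -phi(f), Nyquist (even T) = 0
  phi[1L] <- 0
  half <- if (T %% 2L == 0L) T / 2L else (T - 1L) / 2L + 1L
  if (T %% 2L == 0L) phi[half + 1L] <- 0
  hi <- seq.int(2L, length.out = if (T %% 2L == 0L) half - 1L else half - 1L)
  phi[T + 2L - hi] <- -phi[hi]
  rot <- exp(1i * phi)
  Xf <- mvfft(t(set$data))          # columns are regions
  Yf <- Xf * rot                    # same phase for every region
  y <- mvfft(Yf, inverse = TRUE) / T
  if (max(abs(Im(y))) > 1e-8)
    stop_swdfc("inverse transform is not real; phase symmetry violated",
               "swdfc_internal_error")
  roi_ts(t(Re(y)), set$tr_seconds, set$region_labels, set$subject_id)
}

#' Schwarz Bayesian Criterion of a least-squares VAR fit
#'
#' Fits an order-`p` vector autoregression by least squares and scores it
#' with `log det(Sigma_hat) + log(T_eff) * p * n^2 / T_eff`, where
#' `Sigma_hat` is the maximum-likelihood residual covariance and
#' `T_eff = T - p` the number of regression rows.  Minimized over `p` to
#' select the model order.
#'
#' @param X numeric matrix, regions x time.
#' @param order candidate order `p >= 1`.
#' @return SBC score (finite for full-rank inputs).
#' @export
sbc_score <- function(X, order) {
  fit <- var_ls_fit(X, order)
  ld <- determinant(fit$sigma, logarithm = TRUE)
  t_eff <- ncol(fit$residuals)
  n <- nrow(X)
  as.numeric(ld$modulus) + log(t_eff) * order * n^2 / t_eff
}

# Least-squares VAR(p) without intercept (series assumed zero-mean, as
# produced by high-pass filtering or the synthetic generator).
var_ls_fit <- function(X, p) {
  n <- nrow(X); T <- ncol(X)
  if (T - p <= n * p + 1L)
    stop_swdfc(sprintf("series too short to fit order %d (T = %d, n = %d)",
                       p, T, n),
               "swdfc_validation_error")
  rows <- (p + 1L):T
  Y <- t(X[, rows, drop = FALSE])                       # (T-p) x n
  Z <- do.call(cbind, lapply(seq_len(p), function(l)    # (T-p) x (n*p)
    t(X[, rows - l, drop = FALSE])))
  qrz <- qr(Z)
  if (qrz$rank < ncol(Z))
    stop_swdfc("near-singular lagged regressor matrix", "swdfc_degenerate_error")
  B <- qr.coef(qrz, Y)                                   # (n*p) x n
  E <- Y - Z %*% B
  coef <- lapply(seq_len(p), function(l)
    t(B[((l - 1L) * n + 1L):(l * n), , drop = FALSE]))   # n x n per lag
  sigma <- crossprod(E) / nrow(E)
  list(order = p, coefficients = coef, residuals = t(E), sigma = sigma)
}

#' Fit a multivariate autoregressive (MVAR) model
#'
#' Selects the order `p` in `1..p_max` by minimizing [sbc_score()], fits the
#' coefficients by least squares, and stores the residuals (for surrogate
#' resampling) and their covariance.  Fitted values plus residuals
#' reconstruct the input exactly for `t > p`.
#'
#' @param set a [roi_ts()] object.
#' @param p_max maximum candidate order (default 20).
#' @return Object of class `mvar_model`: `order_p`, `coefficients` (list of
#'   `p` matrices `n x n`), `residuals` (`n x (T - p)`), `residual_covariance`,
#'   `sbc_by_order` (named vector), `spectral_radius` of the companion
#'   matrix, and the source set.
#' @export
fit_mvar <- function(set, p_max = 20L) {
  stopifnot(inherits(set, "roi_ts"))
  X <- set$data
  scores <- vapply(seq_len(p_max), function(p) sbc_score(X, p), 0.0)
  p <- which.min(scores)
  fit <- var_ls_fit(X, p)
  rho <- companion_radius(fit$coefficients)
  if (rho >= 1)
    warning(sprintf("fitted MVAR is not stable (companion spectral radius %.3f); surrogates may diverge", rho))
  structure(list(order_p = p, coefficients = fit$coefficients,
                 residuals = fit$residuals,
                 residual_covariance = fit$sigma,
                 sbc_by_order = stats::setNames(scores, seq_len(p_max)),
                 spectral_radius = rho,
                 source = set),
            class = "mvar_model")
}

companion_radius <- function(coefs) {
  p <- length(coefs); n <- nrow(coefs[[1L]])
  C <- matrix(0, n * p, n * p)
  C[seq_len(n), ] <- do.call(cbind, coefs)
  if (p > 1L)
    C[(n + 1L):(n * p), seq_len(n * (p - 1L))] <- diag(n * (p - 1L))
  max(Mod(eigen(C, only.values = TRUE)$values))
}

#' @export
print.mvar_model <- function(x, ...) {
  cat(sprintf("<mvar_model> order p = %d (SBC-selected of %d), %d regions, %d residual columns\n",
              x$order_p, length(x$sbc_by_order),
              nrow(x$residuals), ncol(x$residuals)))
  cat(sprintf("  companion spectral radius %.3f%s\n", x$spectral_radius,
              if (x$spectral_radius < 1) " (stable)" else " (UNSTABLE)"))
  invisible(x)
}

#' MVAR residual-resampling surrogate
#'
#' Builds one surrogate copy from a fitted MVAR model in four steps:
#' (1) draw a uniform starting point `t0` in `[1, T - p]`;
#' (2) seed the copy with the `p` consecutive original columns starting at
#' `t0`; (3) for each later time point draw a residual column uniformly
#' with replacement (whole columns, preserving contemporaneous residual
#' correlation); (4) propagate through the autoregressive recursion.  The
#' output has exactly `T` columns.
#'
#' @param model a fitted [fit_mvar()] model.
#' @param set the source [roi_ts()] the model was fitted on (defaults to
#'   the set stored in the model).
#' @return A surrogate `roi_ts`.
#' @export
mvar_surrogate <- function(model, set = model$source) {
  stopifnot(inherits(model, "mvar_model"), inherits(set, "roi_ts"))
  X <- set$data
  n <- nrow(X); T <- ncol(X); p <- model$order_p
  t0 <- sample.int(T - p, 1L)
  xs <- matrix(0, n, T)
  xs[, seq_len(p)] <- X[, t0:(t0 + p - 1L), drop = FALSE]
  draws <- sample.int(ncol(model$residuals), T - p, replace = TRUE)
  for (t in (p + 1L):T) {
    acc <- model$residuals[, draws[t - p]]
    for (l in seq_len(p))
      acc <- acc + model$coefficients[[l]] %*% xs[, t - l]
    xs[, t] <- acc
  }
  roi_ts(xs, set$tr_seconds, set$region_labels, set$subject_id)
}

#' Surrogate specification
#'
#' @param method `"mvpr"` (phase randomization) or `"mvar"` (autoregressive
#'   residual resampling).
#' @param n_surrogates copies per subject (study default 250).
#' @param seed root integer seed; each copy gets an independent derived
#'   stream, so ensembles are reproducible and order-independent.
#' @param p_max maximum MVAR order for SBC selection (MVAR only).
#' @return List of class `surrogate_spec`.
#' @export
surrogate_spec <- function(method = c("mvpr", "mvar"), n_surrogates = 250L,
                           seed = 1L, p_max = 20L) {
  method <- match.arg(method)
  stopifnot(n_surrogates >= 1L, p_max >= 1L)
  structure(list(method = method, n_surrogates = as.integer(n_surrogates),
                 seed = as.integer(seed), p_max = as.integer(p_max)),
            class = "surrogate_spec")
}

#' Generate a surrogate ensemble for one subject
#'
#' @param set a [roi_ts()] object.
#' @param spec a [surrogate_spec()].
#' @return Object of class `surrogate_ensemble`: `copies` (list of
#'   `roi_ts`), `method`, `source_subject`, and the fitted `model` for
#'   MVAR.
#' @export
generate_ensemble <- function(set, spec) {
  stopifnot(inherits(set, "roi_ts"), inherits(spec, "surrogate_spec"))
  model <- if (spec$method == "mvar") fit_mvar(set, spec$p_max) else NULL
  copies <- vector("list", spec$n_surrogates)
  for (k in seq_len(spec$n_surrogates)) {
    old <- local_seed(derive_seed(spec$seed, k))
    copies[[k]] <- if (spec$method == "mvpr") mvpr_surrogate(set)
                   else mvar_surrogate(model, set)
    restore_seed(old)
  }
  structure(list(source_subject = set$subject_id, method = spec$method,
                 copies = copies, model = model, seed = spec$seed),
            class = "surrogate_ensemble")
}

#' @export
print.surrogate_ensemble <- function(x, ...) {
  cat(sprintf("<surrogate_ensemble> %d %s copies of subject '%s'\n",
              length(x$copies), toupper(x$method), x$source_subject))
  invisible(x)
}

#' Preserved-property report for a surrogate ensemble
#'
#' Compares five stationary properties of the original series with their
#' ensemble averages: circular autocovariance sequence, circular stationary
#' cross-covariance, power spectral density (periodogram), cross power
#' spectral density magnitude, and amplitude distribution (sorted-value
#' match).  Each row reports the mean absolute deviation relative to the
#' property's mean absolute level.  Phase randomization preserves the first
#' four exactly (common-phase cancellation) but Gaussianizes amplitudes;
#' autoregressive resampling preserves them only in expectation.
#'
#' @param set the original [roi_ts()].
#' @param ensemble a [generate_ensemble()] result for that set.
#' @param max_lag covariance lags reported (default 20).
#' @return `data.frame` with columns `property` and `relative_discrepancy`.
#' @export
surrogate_property_report <- function(set, ensemble, max_lag = 20L) {
  stopifnot(inherits(set, "roi_ts"), inherits(ensemble, "surrogate_ensemble"),
            length(ensemble$copies) >= 1L)
  props <- function(s) {
    X <- s$data
    list(acov = circ_acov(X, max_lag),
         ccov = circ_ccov(X, max_lag),
         psd = row_psd(X),
         cpsd = cross_psd_mag(X),
         amp = apply(X, 1L, sort))
  }
  orig <- props(set)
  avg <- NULL
  for (cp in ensemble$copies) {
    pv <- props(cp)
    if (is.null(avg)) avg <- pv
    else avg <- Map(`+`, avg, pv)
  }
  avg <- lapply(avg, `/`, length(ensemble$copies))
  rel <- function(a, b) mean(abs(a - b)) / (mean(abs(a)) + 1e-300)
  data.frame(
    property = c("autocovariance", "stationary_cross_covariance",
                 "power_spectral_density", "cross_psd_magnitude",
                 "amplitude_distribution"),
    relative_discrepancy = c(rel(orig$acov, avg$acov),
                             rel(orig$ccov, avg$ccov),
                             rel(orig$psd, avg$psd),
                             rel(orig$cpsd, avg$cpsd),
                             rel(orig$amp, avg$amp)),
    stringsAsFactors = FALSE)
}

# Circular (periodic) autocovariance of each row up to max_lag.
circ_acov <- function(X, max_lag) {
  t(apply(X, 1L, function(x) circ_ccv(x, x, max_lag)))
}

# Circular cross-covariance for all pairs, lags -max_lag..max_lag.
circ_ccov <- function(X, max_lag) {
  pi <- pair_index(nrow(X))
  t(vapply(seq_len(nrow(pi)), function(p) {
    x <- X[pi[p, 1L], ]; y <- X[pi[p, 2L], ]
    c(rev(circ_ccv(y, x, max_lag))[-(max_lag + 1L)], circ_ccv(x, y, max_lag))
  }, numeric(2L * max_lag + 1L)))
}

# circular cross-covariance at lags 0..max_lag: mean over t of
# (x(t) - mx)(y(t + lag mod T) - my)
circ_ccv <- function(x, y, max_lag) {
  T <- length(x)
  cx <- x - mean(x); cy <- y - mean(y)
  vapply(0:max_lag, function(l) {
    mean(cx * cy[((seq_len(T) - 1L + l) %% T) + 1L])
  }, 0.0)
}

row_psd <- function(X) {
  t(apply(X, 1L, function(x) Mod(fft(x))^2 / length(x)))
}

cross_psd_mag <- function(X) {
  Xf <- mvfft(t(X))
  pi <- pair_index(nrow(X))
  t(vapply(seq_len(nrow(pi)), function(p) {
    Mod(Xf[, pi[p, 1L]] * Conj(Xf[, pi[p, 2L]])) / nrow(Xf)
  }, numeric(nrow(Xf))))
}
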