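#' Connectivity metric identifiers
#'
#' The ten pairwise functional-connectivity metrics supported throughout the
#' package: three linear (Pearson full/partial correlation, L1-penalized
#' inverse covariance) and seven nonlinear (Spearman full/partial, Kendall,
#' mutual information, variation of information, symmetrized KL divergence,
#' multiplication of temporal derivatives).
#'
#' @return Character vector of the ten metric ids.
#' @export
metric_ids <- function() {
  c("pearson", "pearson_partial", "icov", "spearman", "spearman_partial",
    "kendall", "mutual_information", "variation_of_information",
    "kl_symmetrized", "mtd")
}

#' Metric configuration
#'
#' Tunable parameters shared by the metric implementations.
#'
#' @param icov_lambda nonnegative L1 penalty for the sparse precision
#'   (inverse covariance) estimator; default 0.1.
#' @param kl_floor value substituted for zero bin probabilities in the
#'   symmetrized KL divergence (keeps the log-ratio finite); in (0, 1),
#'   default 1e-12.  No renormalization is applied after flooring.
#' @param mtd_inner_w inner half-window (in samples) of the multiplication
#'   of temporal derivatives; `NULL` couples it to the sliding-window
#'   length when the metric is evaluated through [windowed_metric()].
#' @param bin_rule histogram bin-count policy for the information-theoretic
#'   metrics: `"segment_length"` (number of bins equals the number of points
#'   in the evaluated segment) or a fixed positive integer.
#' @param icov_lw_shrinkage logical; apply Ledoit-Wolf shrinkage to the
#'   sample covariance before the L1 solve (default `FALSE`).
#' @param mtd_sd_population logical; population (divide by count) standard
#'   deviation for the derivative series (default `TRUE`).
#' @return A list of class `metric_config`.
#' @export
metric_config <- function(icov_lambda = 0.1, kl_floor = 1e-12,
                          mtd_inner_w = NULL, bin_rule = "segment_length",
                          icov_lw_shrinkage = FALSE,
                          mtd_sd_population = TRUE) {
  stopifnot(icov_lambda >= 0, kl_floor > 0, kl_floor < 1)
  if (!is.null(mtd_inner_w)) stopifnot(mtd_inner_w >= 1)
  structure(list(icov_lambda = icov_lambda, kl_floor = kl_floor,
                 mtd_inner_w = mtd_inner_w, bin_rule = bin_rule,
                 icov_lw_shrinkage = icov_lw_shrinkage,
                 mtd_sd_population = mtd_sd_population),
            class = "metric_config")
}

n_bins_for <- function(config, segment_length) {
  if (identical(config$bin_rule, "segment_length")) segment_length
  else as.integer(config$bin_rule)
}

#' Pearson linear correlation
#'
#' @param x,y numeric vectors of equal length >= 2; both non-constant.
#' @return Correlation in `[-1, 1]`.
#' @export
pearson_corr <- function(x, y) {
  check_pair(x, y)
  if (sd(x) == 0 || sd(y) == 0)
    stop_swdfc("constant input: Pearson correlation undefined",
               "swdfc_degenerate_error")
  cx <- x - mean(x); cy <- y - mean(y)
  sum(cx * cy) / sqrt(sum(cx * cx) * sum(cy * cy))
}

check_pair <- function(x, y) {
  if (length(x) != length(y))
    stop_swdfc("inputs must have equal length", "swdfc_validation_error")
  if (length(x) < 2L)
    stop_swdfc("need at least 2 observations", "swdfc_validation_error")
  invisible(NULL)
}

#' Rank transform with average ties
#'
#' Ascending ranks `1..N`; tied values receive the average of the ranks they
#' cover (the convention that keeps Spearman correlation well defined under
#' ties).
#'
#' @param x numeric vector.
#' @return Numeric vector of ranks.
#' @export
rank_transform <- function(x) {
  rank(x, ties.method = "average")
}

#' Spearman rank correlation
#'
#' Pearson correlation of the rank-transformed inputs.
#'
#' @inheritParams pearson_corr
#' @export
spearman_corr <- function(x, y) {
  pearson_corr(rank_transform(x), rank_transform(y))
}

#' Least-squares residuals for partial metrics
#'
#' Regresses rows `i` and `j` of a segment on all remaining rows (plus an
#' intercept) and returns the two residual series; partial correlations are
#' plain correlations of these residuals.
#'
#' @param X numeric matrix, `n x N` (regions x samples), `n >= 3`, `N > n`.
#' @param i,j row indices of the two target series.
#' @return List with components `ri` and `rj`.
#' @export
partial_residuals <- function(X, i, j) {
  n <- nrow(X); N <- ncol(X)
  if (n < 3L)
    stop_swdfc("partial metrics need at least one conditioning series (n >= 3)",
               "swdfc_validation_error")
  if (N <= n)
    stop_swdfc("need more samples than regions for the regression",
               "swdfc_validation_error")
  Z <- cbind(1, t(X[-c(i, j), , drop = FALSE]))
  qrz <- qr(Z)
  if (qrz$rank < ncol(Z)) {
    dep <- setdiff(seq_len(ncol(Z)), qrz$pivot[seq_len(qrz$rank)])
    stop_swdfc(sprintf("rank-deficient conditioning set (dependent columns: %s)",
                       paste(dep - 1L, collapse = ", ")),
               "swdfc_degenerate_error")
  }
  list(ri = qr.resid(qrz, X[i, ]), rj = qr.resid(qrz, X[j, ]))
}

#' Pearson and Spearman partial correlation
#'
#' Correlation between rows `i` and `j` of `X` after regressing out all
#' other rows (linear regression with intercept); `pearson_partial` applies
#' Pearson correlation to the residuals, `spearman_partial` applies
#' Spearman (rank) correlation to the same residuals.
#'
#' @inheritParams partial_residuals
#' @export
pearson_partial <- function(X, i, j) {
  r <- partial_residuals(X, i, j)
  pearson_corr(r$ri, r$rj)
}

#' @rdname pearson_partial
#' @export
spearman_partial <- function(X, i, j) {
  r <- partial_residuals(X, i, j)
  spearman_corr(r$ri, r$rj)
}

#' Kendall correlation (literal pair-counting rule)
#'
#' Counts concordant (`NC`) and discordant (`ND`) pairs over all unordered
#' observation pairs; pairs tied in both coordinates are excluded, pairs
#' tied in exactly one coordinate count toward neither.  Returns
#' `2 (NC - ND) / (N (N - 1))`.  Note this is the tau-a style denominator,
#' not the tie-corrected tau-b.
#'
#' @inheritParams pearson_corr
#' @export
kendall_corr <- function(x, y) {
  check_pair(x, y)
  N <- length(x)
  sx <- sign(outer(x, x, "-"))
  sy <- sign(outer(y, y, "-"))
  prod <- sx * sy
  nc <- sum(prod == 1) / 2
  nd <- sum(prod == -1) / 2
  2 * (nc - nd) / (N * (N - 1))
}

#' Histogram estimate of a marginal PDF
#'
#' Equal-width bins spanning `[min(x), max(x)]` with the rightmost bin
#' closed; probabilities are counts divided by the number of points.  A
#' constant input yields a single bin with probability 1.
#'
#' @param x numeric vector.
#' @param n_bins positive integer number of bins.
#' @param range optional length-2 support override (used to put two series
#'   on common bin edges).
#' @return List of class `histogram_pdf` with `bin_edges` and
#'   `probabilities` (summing to 1).
#' @export
marginal_pdf <- function(x, n_bins, range = NULL) {
  stopifnot(length(x) >= 1L, n_bins >= 1L)
  lo <- if (is.null(range)) min(x) else range[1L]
  hi <- if (is.null(range)) max(x) else range[2L]
  if (hi <= lo) {
    return(structure(list(bin_edges = c(lo, lo), probabilities = 1),
                     class = "histogram_pdf"))
  }
  idx <- bin_indices(x, lo, hi, n_bins)
  counts <- tabulate(idx, nbins = n_bins)
  structure(list(bin_edges = seq(lo, hi, length.out = n_bins + 1L),
                 probabilities = counts / length(x)),
            class = "histogram_pdf")
}

# 1-based equal-width bin index with the rightmost bin closed.  The same
# formula is used by the compiled windowed MI/VI kernels.
bin_indices <- function(x, lo, hi, n_bins) {
  s <- n_bins / (hi - lo)
  idx <- floor((x - lo) * s) + 1L
  pmin.int(pmax.int(idx, 1L), n_bins)
}

#' Shannon entropy of a histogram PDF, in bits
#'
#' @param p a `histogram_pdf` from [marginal_pdf()], or a bare probability
#'   vector summing to 1.
#' @return Entropy `-sum p log2 p` (with `0 log 0 = 0`), in bits.
#' @export
entropy_bits <- function(p) {
  if (inherits(p, "histogram_pdf")) p <- p$probabilities
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Plug-in mutual information, in bits
#'
#' Joint-histogram estimator: each axis is binned into `n_bins` equal-width
#' bins over its own range (bin count from `config$bin_rule`, by default the
#' number of points in the segment); cells with zero joint probability
#' contribute nothing.
#'
#' @inheritParams pearson_corr
#' @param config a [metric_config()].
#' @return Nonnegative mutual information in bits.
#' @export
mutual_information_bits <- function(x, y, config = metric_config()) {
  mi_vi_bits(x, y, config)[["mi"]]
}

#' Variation of information, in bits
#'
#' `VI = H(X) + H(Y) - 2 I(X, Y)` with all terms from the same histogram
#' configuration; a metric-like distance, 0 when `x` and `y` carry the same
#' binned information.
#'
#' @inheritParams mutual_information_bits
#' @export
variation_of_information_bits <- function(x, y, config = metric_config()) {
  mi_vi_bits(x, y, config)[["vi"]]
}

# Shared MI/VI core: entropies from marginal and joint histograms with the
# same per-axis binning.
mi_vi_bits <- function(x, y, config = metric_config()) {
  check_pair(x, y)
  N <- length(x)
  nb <- n_bins_for(config, N)
  bx <- bin_indices(x, min(x), max(x), nb)
  by <- bin_indices(y, min(y), max(y), nb)
  if (min(x) == max(x)) bx[] <- 1L
  if (min(y) == max(y)) by[] <- 1L
  hx <- entropy_bits(tabulate(bx, nb) / N)
  hy <- entropy_bits(tabulate(by, nb) / N)
  joint <- table(code = (bx - 1L) * nb + by)
  hxy <- entropy_bits(as.numeric(joint) / N)
  mi <- max(0, hx + hy - hxy)
  vi <- max(0, 2 * hxy - hx - hy)
  c(mi = mi, vi = vi)
}

#' Symmetrized Kullback-Leibler divergence between marginal PDFs, in bits
#'
#' Both marginal histograms are estimated on a common set of equal-width bin
#' edges spanning the union range of the two inputs (bin count from
#' `config$bin_rule`).  Zero probabilities are replaced by `config$kl_floor`
#' (without renormalization) before the log-ratio, and the two directed
#' divergences are averaged: `KLs = (KL(p||q) + KL(q||p)) / 2`.
#'
#' @inheritParams mutual_information_bits
#' @return Nonnegative symmetrized divergence in bits.
#' @export
kl_symmetrized_bits <- function(x, y, config = metric_config()) {
  check_pair(x, y)
  nb <- n_bins_for(config, length(x))
  rng <- range(c(x, y))
  p <- marginal_pdf(x, nb, range = rng)$probabilities
  q <- marginal_pdf(y, nb, range = rng)$probabilities
  kl_symmetrized_pdfs(p, q, config$kl_floor)
}

# Directed + symmetrized KL on two probability vectors over shared bins.
kl_symmetrized_pdfs <- function(p, q, floor = 1e-12) {
  pf <- pmax(p, floor)
  qf <- pmax(q, floor)
  klpq <- sum(ifelse(p > 0, p * log2(pf / qf), 0))
  klqp <- sum(ifelse(q > 0, q * log2(qf / pf), 0))
  max(0, (klpq + klqp) / 2)
}

#' Multiplication of temporal derivatives (MTD)
#'
#' For each region the first temporal derivative `dt_i(k) = x_i(k) -
#' x_i(k-1)` is computed and scaled by the standard deviation of the full
#' derivative series; the MTD coupling series of a pair is the centered
#' moving average of the normalized derivative products:
#' `MTD_ij(t) = mean over k in [t-w, t+w] of dt_i(k) dt_j(k) / (sd_i sd_j)`,
#' evaluated only where the centered window fits (no padding).
#'
#' @param X numeric matrix, regions x samples, with
#'   `ncol(X) >= 2 * w + 2`.
#' @param w inner half-window in samples (the average spans `2w + 1`
#'   derivative samples).
#' @param config a [metric_config()]; `mtd_sd_population` selects the
#'   derivative-sd convention.
#' @return Matrix `n_pairs x n_valid` of coupling values, pairs ordered as
#'   in `pair_index(nrow(X))`; attribute `"offset"` gives the index (into
#'   the derivative series) of the first valid center.
#' @export
mtd_series <- function(X, w, config = metric_config()) {
  n <- nrow(X); N <- ncol(X)
  stopifnot(w >= 1L)
  if (N < 2L * w + 2L)
    stop_swdfc("series too short for the requested MTD window",
               "swdfc_validation_error")
  dt <- X[, -1L, drop = FALSE] - X[, -N, drop = FALSE]
  m <- ncol(dt)
  sds <- apply(dt, 1L, function(v) {
    if (config$mtd_sd_population) sqrt(mean((v - mean(v))^2)) else sd(v)
  })
  if (any(sds == 0))
    stop_swdfc(sprintf("region %d has a constant series (zero derivative sd)",
                       which(sds == 0)[1L]),
               "swdfc_degenerate_error")
  pi <- pair_index(n)
  centers <- (w + 1L):(m - w)
  out <- matrix(NA_real_, nrow(pi), length(centers))
  kernel <- rep(1 / (2 * w + 1), 2L * w + 1L)
  for (p in seq_len(nrow(pi))) {
    prod <- dt[pi[p, 1L], ] * dt[pi[p, 2L], ] / (sds[pi[p, 1L]] * sds[pi[p, 2L]])
    ma <- stats::filter(prod, kernel, sides = 2)
    out[p, ] <- ma[centers]
  }
  attr(out, "offset") <- w + 1L
  out
}

#' Uniform metric dispatch on a data segment
#'
#' Evaluates any of the ten metrics for the pair `(i, j)` of a segment.
#' Partial metrics and the inverse-covariance metric use the full row set of
#' the segment (conditioning on the in-segment samples of all other
#' regions); the remaining metrics use rows `i` and `j` only.  For `"icov"`
#' the value is the `(i, j)` off-diagonal entry of the L1-penalized
#' precision matrix; for `"mtd"` the value is the mean of the in-segment
#' coupling series.
#'
#' @param id one of [metric_ids()].
#' @param X_segment numeric matrix, regions x samples.
#' @param i,j region (row) indices.
#' @param config a [metric_config()].
#' @return A single numeric value.
#' @export
metric_value <- function(id, X_segment, i, j, config = metric_config()) {
  id <- match.arg(id, metric_ids())
  x <- X_segment[i, ]; y <- X_segment[j, ]
  switch(id,
    pearson = pearson_corr(x, y),
    spearman = spearman_corr(x, y),
    kendall = kendall_corr(x, y),
    pearson_partial = pearson_partial(X_segment, i, j),
    spearman_partial = spearman_partial(X_segment, i, j),
    icov = sparse_precision(X_segment, lambda = config$icov_lambda,
                            lw_shrinkage = config$icov_lw_shrinkage)[i, j],
    mutual_information = mutual_information_bits(x, y, config),
    variation_of_information = variation_of_information_bits(x, y, config),
    kl_symmetrized = kl_symmetrized_bits(x, y, config),
    mtd = {
      w <- config$mtd_inner_w %||% max(1L, floor((ncol(X_segment) - 2L) / 2L))
      mean(mtd_series(rbind(x, y), w, config)[1L, ])
    })
}
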