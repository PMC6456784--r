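#' L1-penalized sparse precision (inverse covariance) estimate
#'
#' Estimates the precision matrix of a data segment by penalized maximum
#' likelihood: maximize `log det Theta - tr(S Theta) - lambda ||Theta||_1`
#' (off-diagonal penalty), where `S` is the segment's sample covariance
#' (maximum-likelihood, divisor `N`).  Solved by block coordinate descent
#' over columns, each column update a coordinate-descent lasso on the
#' current working covariance.  At `lambda = 0` the solution is the plain
#' inverse of `S`; at `lambda >=` the largest absolute off-diagonal
#' covariance the off-diagonal entries are exactly zero.
#'
#' Optionally the sample covariance is first shrunk toward a scaled
#' identity with the Ledoit-Wolf oracle weight (`lw_shrinkage = TRUE`),
#' which conditions the problem for very short segments.
#'
#' @param X_segment numeric matrix, regions x samples (`n >= 2`, `N >= 3`).
#' @param lambda nonnegative L1 penalty (the study default is 0.1).
#' @param lw_shrinkage logical; Ledoit-Wolf precondition the covariance.
#' @param max_iter outer iteration cap (default 1000).
#' @param tol convergence tolerance on the mean absolute change of the
#'   working covariance, scaled by the mean absolute off-diagonal of `S`.
#' @return Symmetric positive-definite `n x n` precision matrix.  The
#'   pairwise connectivity value used elsewhere in the package is the
#'   `(i, j)` off-diagonal entry.
#' @export
sparse_precision <- function(X_segment, lambda = 0.1, lw_shrinkage = FALSE,
                             max_iter = 1000L, tol = 1e-6) {
  n <- nrow(X_segment); N <- ncol(X_segment)
  if (n < 2L || N < 3L)
    stop_swdfc("need at least 2 regions and 3 samples", "swdfc_validation_error")
  stopifnot(lambda >= 0)
  Xc <- X_segment - rowMeans(X_segment)
  S <- tcrossprod(Xc) / N
  if (lw_shrinkage) S <- ledoit_wolf_shrink(Xc, S)
  if (lambda == 0) {
    P <- tryCatch(solve(S), error = function(e)
      stop_swdfc("sample covariance is singular at lambda = 0",
                 "swdfc_degenerate_error"))
    return((P + t(P)) / 2)
  }
  W <- S + diag(lambda, n)
  scale <- mean(abs(S[upper.tri(S)])) + mean(diag(S))
  B <- matrix(0, n, n)  # lasso coefficients per column
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    W_old <- W
    for (j in seq_len(n)) {
      idx <- setdiff(seq_len(n), j)
      W11 <- W[idx, idx, drop = FALSE]
      s12 <- S[idx, j]
      beta <- lasso_cd(W11, s12, lambda, beta0 = B[idx, j])
      B[idx, j] <- beta
      w12 <- W11 %*% beta
      W[idx, j] <- w12
      W[j, idx] <- w12
    }
    delta <- mean(abs(W - W_old))
    if (delta <= tol * scale) { converged <- TRUE; break }
  }
  if (!converged)
    stop_swdfc(sprintf("graphical lasso did not converge in %d iterations (last change %.3g)",
                       max_iter, delta),
               "swdfc_convergence_error")
  # recover Theta from W and the column coefficients
  P <- matrix(0, n, n)
  for (j in seq_len(n)) {
    idx <- setdiff(seq_len(n), j)
    theta_jj <- 1 / (W[j, j] - sum(W[idx, j] * B[idx, j]))
    P[j, j] <- theta_jj
    P[idx, j] <- -B[idx, j] * theta_jj
  }
  (P + t(P)) / 2
}

# Coordinate-descent lasso: minimize (1/2) b' W11 b - s12' b + lambda |b|_1.
lasso_cd <- function(W11, s12, lambda, beta0 = NULL,
                     max_iter = 2000L, tol = 1e-10) {
  p <- length(s12)
  beta <- beta0 %||% rep(0, p)
  if (p == 1L) {
    return(soft_threshold(s12, lambda) / W11[1L, 1L])
  }
  for (it in seq_len(max_iter)) {
    max_d <- 0
    for (k in seq_len(p)) {
      r <- s12[k] - sum(W11[k, -k] * beta[-k])
      bk <- soft_threshold(r, lambda) / W11[k, k]
      d <- abs(bk - beta[k])
      if (d > max_d) max_d <- d
      beta[k] <- bk
    }
    if (max_d < tol) break
  }
  beta
}

soft_threshold <- function(z, g) sign(z) * max(abs(z) - g, 0)

# Ledoit-Wolf shrinkage of a sample covariance toward mu * I (oracle
# weight from the centered data); used only as optional preconditioning.
ledoit_wolf_shrink <- function(Xc, S) {
  n <- nrow(Xc); N <- ncol(Xc)
  mu <- mean(diag(S))
  d2 <- sum((S - diag(mu, n))^2) / n
  b2_sum <- 0
  for (t in seq_len(N)) {
    xt <- Xc[, t]
    b2_sum <- b2_sum + sum((tcrossprod(xt) - S)^2) / n
  }
  b2 <- min(b2_sum / N^2, d2)
  rho <- b2 / d2
  (1 - rho) * S + rho * diag(mu, n)
}
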