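test_that("correlation metrics reproduce hand-computed values", {
  expect_equal(pearson_corr(c(1, 2, 3, 4), c(2, 4, 6, 8)), 1.0)
  expect_equal(pearson_corr(c(1, 2, 3), c(3, 2, 1)), -1.0)
  # deviation products 4; deviation sums-of-squares 5 and 5 -> 4/5
  expect_equal(pearson_corr(c(1, 2, 3, 4), c(1, 3, 2, 4)), 0.8)
  expect_error(pearson_corr(c(1, 1, 1), c(1, 2, 3)),
               class = "swdfc_degenerate_error")

  expect_equal(spearman_corr(c(1, 2, 3), c(1, 8, 27)), 1.0)
  expect_equal(spearman_corr(c(1, 2, 3), c(9, 4, 1)), -1.0)
  expect_equal(spearman_corr(c(1, 2, 3, 4), c(1, 3, 2, 4)), 0.8)

  expect_equal(kendall_corr(1:5, 1:5), 1.0)
  expect_equal(kendall_corr(1:5, 5:1), -1.0)
  # triple (1,2,3) vs (1,3,2): NC = 2, ND = 1, N = 3 -> 2(2-1)/(3*2) = 1/3
  expect_equal(kendall_corr(c(1, 2, 3), c(1, 3, 2)), 1 / 3)
})

test_that("rank transform uses ascending ranks with average ties", {
  expect_equal(rank_transform(c(3, 1, 2)), c(3, 1, 2))
  expect_equal(rank_transform(c(1, 1, 2)), c(1.5, 1.5, 3))
  # O(N^2) counting oracle: rank = #smaller + (#equal + 1) / 2
  set.seed(10)
  x <- sample(c(rnorm(40), rnorm(10)[rep(1:5, 2)]))
  oracle <- vapply(x, function(v) sum(x < v) + (sum(x == v) + 1) / 2, 0.0)
  expect_equal(rank_transform(x), oracle)
  # spearman is exactly pearson on ranks
  set.seed(11)
  a <- rnorm(30); b <- rnorm(30)
  expect_identical(spearman_corr(a, b),
                   pearson_corr(rank_transform(a), rank_transform(b)))
})

test_that("kendall matches an exhaustive pair-enumeration oracle under ties", {
  kendall_oracle <- function(x, y) {
    N <- length(x); nc <- 0; nd <- 0
    for (i in 1:(N - 1)) for (j in (i + 1):N) {
      if ((x[i] > x[j] && y[i] > y[j]) || (x[i] < x[j] && y[i] < y[j])) nc <- nc + 1
      else if ((x[i] > x[j] && y[i] < y[j]) || (x[i] < x[j] && y[i] > y[j])) nd <- nd + 1
      # ties in either coordinate count toward neither
    }
    2 * (nc - nd) / (N * (N - 1))
  }
  set.seed(12)
  for (k in 1:20) {
    x <- sample(1:6, 15, replace = TRUE)   # plenty of ties
    y <- sample(1:6, 15, replace = TRUE)
    expect_equal(kendall_corr(x, y), kendall_oracle(x, y))
  }
})

test_that("partial residuals are orthogonal projections", {
  set.seed(13)
  X <- matrix(rnorm(4 * 200), 4, 200)
  X[3, ] <- X[1, ]                      # target equals a conditioning row
  r <- partial_residuals(X, 1, 2)
  expect_lt(max(abs(r$ri)), 1e-9)

  X <- matrix(rnorm(4 * 200), 4, 200)
  r <- partial_residuals(X, 1, 2)
  Z <- cbind(1, t(X[3:4, ]))
  expect_lt(max(abs(crossprod(Z, r$ri))) / sum(abs(r$ri)), 1e-8)
  # normal-equations oracle by explicit Gram inversion
  beta <- solve(crossprod(Z), crossprod(Z, X[1, ]))
  expect_equal(r$ri, as.numeric(X[1, ] - Z %*% beta), tolerance = 1e-9)

  Xc <- matrix(rnorm(4 * 100), 4, 100)
  Xc[4, ] <- Xc[3, ]                    # collinear conditioning set
  expect_error(partial_residuals(Xc, 1, 2), class = "swdfc_degenerate_error")
})

test_that("partial correlations match the precision-matrix identity", {
  set.seed(14)
  X <- matrix(rnorm(5 * 300), 5, 300)
  P <- solve(cor(t(X)))
  for (i in 1:4) for (j in (i + 1):5) {
    expect_equal(pearson_partial(X, i, j),
                 -P[i, j] / sqrt(P[i, i] * P[j, j]), tolerance = 1e-6)
  }
  # orthogonal conditioning leaves the full correlation unchanged
  Xo <- matrix(rnorm(3 * 4000), 3, 4000)
  Xo <- Xo - rowMeans(Xo)
  # orthogonalize row 3 against rows 1, 2 exactly
  Z <- cbind(1, Xo[1, ], Xo[2, ])
  Xo[3, ] <- qr.resid(qr(Z), Xo[3, ])
  expect_equal(pearson_partial(Xo, 1, 2), pearson_corr(Xo[1, ], Xo[2, ]),
               tolerance = 1e-9)
})

test_that("histogram PDFs and entropy match closed forms", {
  p <- marginal_pdf(c(0, 1, 2, 3), 4)
  expect_equal(p$probabilities, rep(0.25, 4))
  expect_equal(p$bin_edges, c(0, 0.75, 1.5, 2.25, 3))
  expect_equal(marginal_pdf(rep(2, 5), 4)$probabilities, 1)
  set.seed(15)
  expect_equal(sum(marginal_pdf(rnorm(37), 12)$probabilities), 1)

  expect_equal(entropy_bits(marginal_pdf(rep(1, 3), 1)), 0)
  expect_equal(entropy_bits(rep(0.25, 4)), 2)
  expect_equal(entropy_bits(c(0.5, 0.25, 0.25)), 1.5)
})

test_that("MI and VI match a brute-force joint-histogram oracle", {
  mi_oracle <- function(x, y) {
    N <- length(x)
    bx <- swdfc:::bin_indices(x, min(x), max(x), N)
    by <- swdfc:::bin_indices(y, min(y), max(y), N)
    tot <- 0
    for (a in unique(bx)) for (b in unique(by)) {
      pxy <- sum(bx == a & by == b) / N
      if (pxy > 0)
        tot <- tot + pxy * log2(pxy / ((sum(bx == a) / N) * (sum(by == b) / N)))
    }
    tot
  }
  set.seed(16)
  x8 <- c(1.1, 2.3, 2.4, 0.2, 5.1, 5.0, 2.2, 1.0)
  y8 <- c(0.9, 2.0, 2.1, 0.1, 4.0, 4.2, 2.3, 1.2)
  expect_equal(mutual_information_bits(x8, y8), mi_oracle(x8, y8),
               tolerance = 1e-10)
  for (k in 1:10) {
    x <- rnorm(25); y <- 0.5 * x + rnorm(25)
    expect_equal(mutual_information_bits(x, y), mi_oracle(x, y),
                 tolerance = 1e-10)
    hx <- entropy_bits(marginal_pdf(x, 25))
    hy <- entropy_bits(marginal_pdf(y, 25))
    expect_equal(variation_of_information_bits(x, y),
                 hx + hy - 2 * mi_oracle(x, y), tolerance = 1e-10)
  }
  # identities and degenerate cases
  x <- rnorm(20)
  expect_equal(mutual_information_bits(x, x),
               entropy_bits(marginal_pdf(x, 20)))
  expect_equal(mutual_information_bits(x, rep(1, 20)), 0)
  expect_equal(variation_of_information_bits(x, x), 0)
})

test_that("symmetrized KL reproduces the two-bin closed form", {
  # common edges over [0.1, 0.9]; p = (3/4, 1/4), q = (1/4, 3/4)
  cfg <- metric_config(bin_rule = 2)
  x <- c(0.1, 0.2, 0.3, 0.9)
  y <- c(0.1, 0.7, 0.8, 0.9)
  expect_equal(kl_symmetrized_bits(x, y, cfg), 0.5 * log2(3),
               tolerance = 1e-12)
  expect_equal(kl_symmetrized_bits(x, x, cfg), 0)
  set.seed(17)
  a <- rnorm(40); b <- rnorm(40, 1)
  expect_identical(kl_symmetrized_bits(a, b), kl_symmetrized_bits(b, a))
  expect_gte(kl_symmetrized_bits(a, b), 0)
})

test_that("MTD matches a direct loop oracle and its sign structure", {
  mtd_oracle <- function(x, y, w) {
    dx <- diff(x); dy <- diff(y)
    sx <- sqrt(mean((dx - mean(dx))^2)); sy <- sqrt(mean((dy - mean(dy))^2))
    m <- length(dx)
    vapply((w + 1):(m - w), function(t)
      sum(dx[(t - w):(t + w)] * dy[(t - w):(t + w)]) / ((2 * w + 1) * sx * sy),
      0.0)
  }
  set.seed(18)
  x <- rnorm(10); y <- rnorm(10)
  got <- mtd_series(rbind(x, y), 2)
  expect_equal(as.numeric(got[1, ]), mtd_oracle(x, y, 2), tolerance = 1e-12)
  self <- mtd_series(rbind(x, x), 2)
  expect_true(all(self[1, ] >= 0))
  anti <- mtd_series(rbind(x, -x), 2)
  expect_equal(as.numeric(anti[1, ]), -as.numeric(self[1, ]))
  expect_error(mtd_series(rbind(x, rep(1, 10)), 2),
               class = "swdfc_degenerate_error")
})

test_that("sparse precision: unpenalized inverse, diagonal limit, KKT optimality", {
  set.seed(19)
  X <- matrix(rnorm(3 * 500), 3, 500)
  S <- tcrossprod(X - rowMeans(X)) / 500
  expect_equal(sparse_precision(X, lambda = 0), solve(S), tolerance = 1e-6)

  big <- max(abs(S[upper.tri(S)]))
  Pd <- sparse_precision(X, lambda = big + 0.01)
  expect_identical(Pd[upper.tri(Pd)], rep(0, 3))

  # KKT subgradient of the penalized likelihood at the reported solution:
  # S - Theta^{-1} + lambda * G = 0 with G = sign(Theta) off-diagonal,
  # |G| <= 1 where Theta = 0
  P <- sparse_precision(X, lambda = 0.1)
  G <- S - solve(P)
  off <- which(upper.tri(P))
  expect_true(all(abs(G[off]) <= 0.1 + 1e-4))
  nz <- off[P[off] != 0]
  expect_equal(G[nz], -0.1 * sign(P[nz]), tolerance = 1e-4)
  expect_true(all(eigen(P, only.values = TRUE)$values > 0))

  # independent unit-variance noise: penalized off-diagonal near zero
  X2 <- matrix(rnorm(2 * 2000), 2, 2000)
  expect_lt(abs(sparse_precision(X2, lambda = 0.1)[1, 2]), 0.05)
})

test_that("metric dispatch hits every metric and respects the full row set", {
  set.seed(20)
  X <- matrix(rnorm(5 * 60), 5, 60)
  X[2, ] <- X[1, ]
  expect_equal(metric_value("pearson", X, 1, 2), 1.0)
  expect_equal(metric_value("variation_of_information", X, 1, 2), 0)
  expect_equal(metric_value("kendall", rbind(c(1, 2, 3), c(1, 3, 2)), 1, 2),
               1 / 3)
  expect_error(metric_value("not_a_metric", X, 1, 2))
})

test_that("all ten metrics are symmetric in the pair for random segments", {
  set.seed(21)
  for (k in 1:5) {
    X <- matrix(rnorm(5 * 40), 5, 40)
    for (m in metric_ids()) {
      expect_equal(metric_value(m, X, 2, 4), metric_value(m, X, 4, 2),
                   tolerance = 1e-9, label = m)
    }
  }
})

test_that("rank metrics are invariant to monotone transforms, linear ones to affine", {
  set.seed(22)
  x <- rnorm(50); y <- rnorm(50)
  expect_equal(pearson_corr(3.2 * x + 1, 0.7 * y - 2), pearson_corr(x, y),
               tolerance = 1e-9)
  expect_equal(spearman_corr(exp(x), y^3 + y), spearman_corr(x, y),
               tolerance = 1e-9)
  expect_equal(kendall_corr(exp(x), atan(y)), kendall_corr(x, y),
               tolerance = 1e-9)
})

test_that("plug-in MI and VI are nonnegative across random inputs", {
  set.seed(23)
  for (k in 1:50) {
    n <- sample(5:60, 1)
    x <- rnorm(n); y <- rnorm(n)
    expect_gte(mutual_information_bits(x, y), 0)
    expect_gte(variation_of_information_bits(x, y), 0)
  }
})
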