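# Internal helpers shared across modules.

# Deterministic derivation of a child RNG seed from a root seed and a stream
# index.  Keeps every derived seed a valid 32-bit integer so that ensembles
# are reproducible and order-independent (one independent stream per subject
# and per surrogate copy).
derive_seed <- function(seed, stream) {
  stopifnot(length(seed) == 1L, length(stream) == 1L)
  a <- (as.double(seed) %% 2147483647) + 1
  b <- (as.double(stream) %% 2147483647) + 1
  as.integer((a * 48271 + b * 69621) %% 2147483647L)
}

# Unordered pair index table for n regions: one row per pair (i < j), in the
# fixed order (1,2), (1,3), ..., (1,n), (2,3), ...  All pair-indexed vectors
# in the package follow this order.
pair_index <- function(n) {
  stopifnot(n >= 2)
  i <- rep.int(seq_len(n - 1L), times = (n - 1L):1L)
  j <- unlist(lapply(seq_len(n - 1L), function(k) (k + 1L):n))
  cbind(i = i, j = j)
}

n_pairs <- function(n) as.integer(n * (n - 1) / 2)

# Upper-triangle (i < j) vectorization matching pair_index() row order.
ut_vec <- function(m) {
  t(m)[lower.tri(m)]
}

# Fill a symmetric matrix from a pair-ordered vector; diagonal given.
sym_from_pairs <- function(v, n, diag_value = NA_real_) {
  m <- matrix(diag_value, n, n)
  pi <- pair_index(n)
  m[cbind(pi[, 1], pi[, 2])] <- v
  m[cbind(pi[, 2], pi[, 1])] <- v
  m
}

stop_swdfc <- function(msg, class) {
  stop(structure(class = c(class, "swdfc_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
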