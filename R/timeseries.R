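#' Single-subject ROI time-series set
#'
#' Container for one subject's region-of-interest (ROI) time series: an
#' `n x T` numeric matrix (one row per region, one column per time point),
#' the repetition time TR in seconds, and unique region labels.
#'
#' @param data numeric matrix, regions x time; all values finite, at least
#'   2 rows and 2 columns.
#' @param tr_seconds positive sampling interval (TR) in seconds.
#' @param region_labels character vector of unique labels, one per row.
#'   Defaults to `"R01"..."Rnn"`.
#' @param subject_id subject identifier.
#' @return An object of class `roi_ts`.
#' @examples
#' x <- roi_ts(matrix(rnorm(4 * 100), 4, 100), tr_seconds = 0.72)
#' x
#' @export
roi_ts <- function(data, tr_seconds, region_labels = NULL,
                   subject_id = "subject") {
  if (!is.matrix(data) || !is.numeric(data))
    stop_swdfc("`data` must be a numeric matrix (regions x time)",
               "swdfc_validation_error")
  if (!all(is.finite(data)))
    stop_swdfc("`data` contains non-finite values (missing values are not accepted)",
               "swdfc_validation_error")
  n <- nrow(data); T <- ncol(data)
  if (n < 2L || T < 2L)
    stop_swdfc(sprintf("need at least 2 regions and 2 time points, got %d x %d", n, T),
               "swdfc_validation_error")
  if (!is.numeric(tr_seconds) || length(tr_seconds) != 1L || tr_seconds <= 0)
    stop_swdfc("`tr_seconds` must be a single positive number",
               "swdfc_validation_error")
  if (is.null(region_labels))
    region_labels <- sprintf("R%02d", seq_len(n))
  region_labels <- as.character(region_labels)
  if (length(region_labels) != n || anyDuplicated(region_labels))
    stop_swdfc("`region_labels` must be unique and match the row count",
               "swdfc_validation_error")
  dimnames(data) <- NULL
  structure(list(subject_id = as.character(subject_id),
                 region_labels = region_labels,
                 tr_seconds = as.numeric(tr_seconds),
                 data = data),
            class = "roi_ts")
}

#' @export
print.roi_ts <- function(x, ...) {
  cat(sprintf("<roi_ts> subject '%s': %d regions x %d time points, TR = %g s (%.1f s)\n",
              x$subject_id, nrow(x$data), ncol(x$data), x$tr_seconds,
              ncol(x$data) * x$tr_seconds))
  cat("regions:", paste(x$region_labels, collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.roi_ts <- function(x) dim(x$data)

#' Multi-subject cohort
#'
#' A cohort is a list of [roi_ts()] sets sharing region labels, TR and
#' series length.
#'
#' @param subjects list of `roi_ts` objects (at least one).
#' @return An object of class `dfc_cohort`.
#' @export
as_cohort <- function(subjects) {
  if (inherits(subjects, "roi_ts")) subjects <- list(subjects)
  if (!length(subjects) || !all(vapply(subjects, inherits, TRUE, "roi_ts")))
    stop_swdfc("`subjects` must be a nonempty list of roi_ts objects",
               "swdfc_validation_error")
  ref <- subjects[[1L]]
  for (s in subjects) {
    if (!identical(s$region_labels, ref$region_labels) ||
        !identical(s$tr_seconds, ref$tr_seconds) ||
        ncol(s$data) != ncol(ref$data))
      stop_swdfc("all subjects must share region labels, TR, and series length",
                 "swdfc_validation_error")
  }
  structure(list(subjects = subjects), class = "dfc_cohort")
}

#' @export
print.dfc_cohort <- function(x, ...) {
  s <- x$subjects[[1L]]
  cat(sprintf("<dfc_cohort> %d subjects, %d regions x %d time points, TR = %g s\n",
              length(x$subjects), nrow(s$data), ncol(s$data), s$tr_seconds))
  invisible(x)
}

#' @export
length.dfc_cohort <- function(x) length(x$subjects)

#' Read an ROI-by-time matrix from delimited text
#'
#' One region per row, one time point per column.  A first column whose
#' entries do not parse as numbers is treated as region labels; otherwise
#' labels `"R01"...` are generated.
#'
#' @param path path to a delimited text file.
#' @param tr_seconds repetition time in seconds.
#' @param delimiter field delimiter (default tab).
#' @param subject_id subject identifier (defaults to the file name).
#' @return A [roi_ts()] object.
#' @export
read_roi_matrix <- function(path, tr_seconds, delimiter = "\t",
                            subject_id = NULL) {
  if (!file.exists(path))
    stop_swdfc(sprintf("file not found: %s", path), "swdfc_io_error")
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines))
    stop_swdfc("empty file", "swdfc_structural_error")
  cells <- strsplit(lines, delimiter, fixed = TRUE)
  ncols <- lengths(cells)
  if (length(unique(ncols)) != 1L)
    stop_swdfc(sprintf("ragged rows: row %d has %d fields, row 1 has %d",
                       which(ncols != ncols[1L])[1L],
                       ncols[ncols != ncols[1L]][1L], ncols[1L]),
               "swdfc_structural_error")
  first_col <- vapply(cells, `[[`, "", 1L)
  has_labels <- anyNA(suppressWarnings(as.numeric(first_col)))
  labels <- NULL
  if (has_labels) {
    labels <- trimws(first_col)
    cells <- lapply(cells, `[`, -1L)
  }
  mat <- matrix(NA_real_, length(cells), length(cells[[1L]]))
  for (r in seq_along(cells)) {
    v <- suppressWarnings(as.numeric(cells[[r]]))
    if (anyNA(v)) {
      bad <- which(is.na(v))[1L]
      stop_swdfc(sprintf("non-numeric value '%s' at row %d, column %d",
                         cells[[r]][bad], r, bad + has_labels),
                 "swdfc_parse_error")
    }
    mat[r, ] <- v
  }
  roi_ts(mat, tr_seconds, region_labels = labels,
         subject_id = subject_id %||% basename(path))
}

#' Write an ROI-by-time matrix as delimited text
#'
#' Inverse of [read_roi_matrix()]: region labels in the first column, values
#' written with 17 significant digits so a read/write cycle round-trips.
#'
#' @param set a [roi_ts()] object.
#' @param path output file path.
#' @param delimiter field delimiter (default tab).
#' @export
write_roi_matrix <- function(set, path, delimiter = "\t") {
  stopifnot(inherits(set, "roi_ts"))
  rows <- vapply(seq_len(nrow(set$data)), function(r) {
    paste(c(set$region_labels[r],
            formatC(set$data[r, ], digits = 17, format = "g")),
          collapse = delimiter)
  }, "")
  writeLines(rows, path)
  invisible(path)
}

#' High-pass filter an ROI time-series set
#'
#' Removes slow drifts below a cutoff frequency (default 0.0067 Hz, i.e.
#' a 150 s cutoff period) with a 2nd-order Butterworth high-pass applied
#' forward and backward (`signal::filtfilt`), so the effective filter is
#' 4th order with zero phase shift.  Each region's row is filtered
#' identically.
#'
#' @param set a [roi_ts()] object.
#' @param cutoff_hz high-pass cutoff in Hz; must lie strictly below the
#'   Nyquist frequency `1/(2 * tr_seconds)`.
#' @return A new `roi_ts` with filtered rows.
#' @export
highpass_filter <- function(set, cutoff_hz = 0.0067) {
  stopifnot(inherits(set, "roi_ts"))
  nyq <- 1 / (2 * set$tr_seconds)
  if (!is.numeric(cutoff_hz) || cutoff_hz <= 0 || cutoff_hz >= nyq)
    stop_swdfc(sprintf("cutoff %g Hz must lie in (0, Nyquist = %g Hz)",
                       cutoff_hz, nyq), "swdfc_validation_error")
  if (ncol(set$data) < 12L)
    stop_swdfc("series too short for the 4th-order zero-phase filter",
               "swdfc_validation_error")
  bw <- signal::butter(2, W = cutoff_hz / nyq, type = "high")
  out <- t(apply(set$data, 1L, function(row)
    filtfilt_zero_phase(bw$b, bw$a, row)))
  roi_ts(out, set$tr_seconds, set$region_labels, set$subject_id)
}

# Zero-phase IIR filtering with odd-reflection padding and steady-state
# initial conditions (the classic filtfilt construction): without the
# initial-state matching a slow high-pass leaves large transients at the
# series edges.
filtfilt_zero_phase <- function(b, a, x) {
  b <- b / a[1L]; a <- a / a[1L]
  nfact <- 3L * (length(a) - 1L)
  T <- length(x)
  if (T <= nfact + 1L)
    stop_swdfc("series too short for zero-phase filtering",
               "swdfc_validation_error")
  # steady-state filter state for a unit-step input (direct form II
  # transposed); scales with the first sample of each pass
  A_st <- rbind(c(-a[2L], 1), c(-a[3L], 0))
  Bv <- c(b[2L] - b[1L] * a[2L], b[3L] - b[1L] * a[3L])
  zi <- solve(diag(2) - A_st, Bv)
  xp <- c(2 * x[1L] - x[(nfact + 1L):2L], x,
          2 * x[T] - x[(T - 1L):(T - nfact)])
  y <- iir_df2t(b, a, xp, zi * xp[1L])
  y <- rev(iir_df2t(b, a, rev(y), zi * y[length(y)]))
  y[(nfact + 1L):(nfact + T)]
}

# second-order direct-form-II-transposed IIR filter with initial state
iir_df2t <- function(b, a, x, z) {
  n <- length(x)
  y <- numeric(n)
  z1 <- z[1L]; z2 <- z[2L]
  for (t in seq_len(n)) {
    y[t] <- b[1L] * x[t] + z1
    z1 <- b[2L] * x[t] - a[2L] * y[t] + z2
    z2 <- b[3L] * x[t] - a[3L] * y[t]
  }
  y
}

#' Split a cohort into disjoint groups
#'
#' Random, seed-deterministic partition of a cohort into two groups (e.g.
#' 100 subjects into two groups of 50 for a test--retest analysis).
#'
#' @param cohort a [as_cohort()] cohort with at least 2 subjects.
#' @param fractions two positive fractions summing to 1 (default `c(0.5, 0.5)`).
#' @param seed integer seed making the partition reproducible.
#' @return A list of two `dfc_cohort` objects; their subject sets are
#'   disjoint and exhaustive.
#' @export
split_cohort <- function(cohort, fractions = c(0.5, 0.5), seed = 1L) {
  stopifnot(inherits(cohort, "dfc_cohort"))
  ns <- length(cohort$subjects)
  if (ns < 2L)
    stop_swdfc("need at least 2 subjects to split", "swdfc_validation_error")
  if (length(fractions) != 2L || any(fractions <= 0) ||
      abs(sum(fractions) - 1) > 1e-9)
    stop_swdfc("`fractions` must be two positive numbers summing to 1",
               "swdfc_validation_error")
  n1 <- max(1L, min(ns - 1L, round(fractions[1L] * ns)))
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  idx <- sample.int(ns)
  list(as_cohort(cohort$subjects[sort(idx[seq_len(n1)])]),
       as_cohort(cohort$subjects[sort(idx[(n1 + 1L):ns])]))
}

# Seed scoping: set the RNG seed, return the previous state for restoration,
# so library functions do not clobber the caller's RNG stream.
local_seed <- function(seed) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  old
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}
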