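# Intrinsic neural timescale (INT) estimation.
#
# The INT index of a voxel is the sum of its sample autocorrelation values
# at incremental lags, starting at lag 1, up to (but not including) the
# first strictly negative value, multiplied by the repetition time. Under an
# AR(1) process with coefficient phi and sampling interval tr the population
# value is tr * phi / (1 - phi).

#' BOLD time series with acquisition metadata
#'
#' @param values Numeric vector, one sample per acquired frame.
#' @param tr Repetition time in seconds (> 0).
#' @param session_bounds Integer vector of session lengths summing to
#'   `length(values)`. Defaults to a single session. The autocorrelation
#'   function is never computed across a session boundary.
#' @return An object of class `bold_series`.
#' @export
bold_series <- function(values, tr, session_bounds = length(values)) {
  values <- as.double(values)
  if (!is.numeric(tr) || length(tr) != 1 || !is.finite(tr) || tr <= 0)
    stop("tr must be a single positive number, got ", tr)
  session_bounds <- as.integer(session_bounds)
  if (sum(session_bounds) != length(values))
    stop("session_bounds sum (", sum(session_bounds),
         ") must equal series length (", length(values), ")")
  if (any(session_bounds < 2))
    stop("every session must contain at least 2 frames")
  if (anyNA(values) || any(!is.finite(values)))
    stop("series contains non-finite values")
  structure(list(values = values, tr = tr, session_bounds = session_bounds),
            class = "bold_series")
}

#' @export
print.bold_series <- function(x, ...) {
  cat(sprintf("<bold_series> %d frames, TR %.4g s, %d session(s)\n",
              length(x$values), x$tr, length(x$session_bounds)))
  invisible(x)
}

#' Sample autocorrelation function of a single-session series
#'
#' Conventional biased (1/T denominator) sample ACF of the mean-removed
#' series. The lag-0 value is exactly 1 for any non-degenerate series. A
#' constant series is degenerate: the returned object carries
#' `degenerate = TRUE` and all-zero values, and downstream INT is 0.
#'
#' @param series A `bold_series` with a single session, or a numeric vector.
#' @param max_lag Largest lag to compute; must be < series length.
#' @return An object of class `acf_sequence`: list with `lags` (0..max_lag),
#'   `values`, and `degenerate`.
#' @export
sample_acf <- function(series, max_lag) {
  x <- if (inherits(series, "bold_series")) {
    if (length(series$session_bounds) != 1)
      stop("sample_acf operates on a single session")
    series$values
  } else as.double(series)
  n <- length(x)
  max_lag <- as.integer(max_lag)
  if (max_lag >= n) stop("max_lag (", max_lag, ") must be < T (", n, ")")
  if (max_lag < 1) stop("max_lag must be >= 1")
  x <- x - mean(x)
  ss <- sum(x^2)
  if (ss == 0) {
    return(structure(list(lags = 0:max_lag,
                          values = rep(0, max_lag + 1),
                          degenerate = TRUE),
                     class = "acf_sequence"))
  }
  vals <- vapply(1:max_lag, function(k) {
    sum(x[seq_len(n - k)] * x[seq.int(k + 1, n)]) / ss
  }, numeric(1))
  structure(list(lags = 0:max_lag, values = c(1, vals), degenerate = FALSE),
            class = "acf_sequence")
}

#' INT index from an autocorrelation sequence
#'
#' Scans lags 1, 2, ... until the first strictly negative ACF value and
#' returns the repetition time multiplied by the sum of the preceding
#' values. Exactly-zero values are included and scanning continues. If
#' ACF(1) < 0 the sum is empty and the INT is 0 seconds. If no negative
#' value occurs within the sequence, all computed lags are summed and a
#' truncation warning is raised.
#'
#' @param acf An `acf_sequence` from [sample_acf()].
#' @param tr Repetition time in seconds.
#' @param include_lag0 If `TRUE`, add `tr * 1` for the lag-0 value
#'   (sensitivity analysis only; the default reproduces sub-TR INT values).
#' @return INT in seconds (single nonnegative number).
#' @export
int_index <- function(acf, tr, include_lag0 = FALSE) {
  stopifnot(inherits(acf, "acf_sequence"))
  if (isTRUE(acf$degenerate)) return(0)
  v <- acf$values[acf$lags >= 1]
  neg <- which(v < 0)
  if (length(neg) == 0) {
    warning("no negative ACF value within max_lag; INT truncated at lag ",
            max(acf$lags))
    s <- sum(v)
  } else {
    s <- sum(v[seq_len(neg[1] - 1)])
  }
  tr * (s + if (include_lag0) 1 else 0)
}

# Vectorised INT scan over the columns of a T x V matrix (one session).
# Computes ACF lags incrementally and drops a column from the active set at
# its first strictly negative value, so cost is O(T * typical stopping lag)
# per voxel rather than O(T * max_lag). Returns the per-column sum of
# leading positive ACF values (unitless), plus degenerate/truncation flags.
.int_scan <- function(x, max_lag) {
  n <- nrow(x)
  v <- ncol(x)
  x <- sweep(x, 2, colMeans(x))
  ss <- colSums(x^2)
  degenerate <- ss == 0
  sums <- numeric(v)
  truncated <- rep(FALSE, v)
  active <- which(!degenerate)
  k <- 1L
  while (length(active) > 0 && k <= max_lag) {
    xa <- x[, active, drop = FALSE]
    r <- colSums(xa[seq_len(n - k), , drop = FALSE] *
                 xa[seq.int(k + 1, n), , drop = FALSE]) / ss[active]
    keep <- r >= 0
    sums[active[keep]] <- sums[active[keep]] + r[keep]
    active <- active[keep]
    k <- k + 1L
  }
  truncated[active] <- TRUE
  list(sums = sums, degenerate = degenerate, truncated = truncated)
}

#' INT of a time series
#'
#' Computes the INT index for each session separately (the ACF never crosses
#' a session boundary) and averages the per-session values.
#'
#' @param series A `bold_series`.
#' @param max_lag Largest ACF lag per session; default is half the session
#'   length. Truncation (no negative ACF value before `max_lag`) raises a
#'   warning.
#' @return INT in seconds.
#' @export
int_from_series <- function(series, max_lag = NULL) {
  stopifnot(inherits(series, "bold_series"))
  bounds <- series$session_bounds
  starts <- cumsum(c(1L, bounds[-length(bounds)]))
  ints <- vapply(seq_along(bounds), function(i) {
    x <- series$values[seq.int(starts[i], starts[i] + bounds[i] - 1L)]
    ml <- if (is.null(max_lag)) max(1L, bounds[i] %/% 2L)
          else min(as.integer(max_lag), bounds[i] - 1L)
    res <- .int_scan(matrix(x, ncol = 1), ml)
    if (res$truncated[1] && !res$degenerate[1])
      warning("no negative ACF value within max_lag = ", ml,
              "; INT truncated")
    series$tr * res$sums[1]
  }, numeric(1))
  mean(ints)
}

#' Voxel-wise INT map of a 4D volume
#'
#' Applies the INT estimator independently to every in-mask voxel. Constant
#' (degenerate) voxels yield INT = 0 and are counted in a message rather
#' than aborting the run.
#'
#' @param volume 4D numeric array (x, y, z, frames).
#' @param mask 3D logical (or 0/1) array matching the spatial grid.
#' @param tr Repetition time in seconds.
#' @param session_bounds Session lengths summing to the frame count.
#' @param max_lag Largest ACF lag per session (default: half the session
#'   length).
#' @param affine Optional 4x4 voxel-to-mm matrix carried as metadata.
#' @return An object of class `int_map`: list with `grid` (3D array,
#'   seconds, `NA` outside the mask), `mask`, `tr`, `affine`,
#'   `n_degenerate`, `n_truncated`.
#' @export
int_map <- function(volume, mask, tr, session_bounds = dim(volume)[4],
                    max_lag = NULL, affine = NULL) {
  dv <- dim(volume)
  if (length(dv) != 4) stop("volume must be a 4D array")
  mask <- array(as.logical(mask), dim = dim(mask))
  if (!identical(dim(mask), dv[1:3]))
    stop("mask shape (", paste(dim(mask), collapse = "x"),
         ") does not match volume grid (", paste(dv[1:3], collapse = "x"), ")")
  nvox <- sum(mask)
  if (nvox == 0) stop("mask contains no voxels")
  session_bounds <- as.integer(session_bounds)
  if (sum(session_bounds) != dv[4])
    stop("session_bounds sum (", sum(session_bounds),
         ") does not match frame count (", dv[4], ")")
  if (any(session_bounds < 2)) stop("every session needs >= 2 frames")

  mat <- matrix(volume, nrow = prod(dv[1:3]), ncol = dv[4])
  mat <- t(mat[as.vector(mask), , drop = FALSE])  # frames x voxels
  starts <- cumsum(c(1L, session_bounds[-length(session_bounds)]))
  acc <- numeric(nvox)
  degenerate <- rep(FALSE, nvox)
  truncated <- rep(FALSE, nvox)
  for (i in seq_along(session_bounds)) {
    rows <- seq.int(starts[i], starts[i] + session_bounds[i] - 1L)
    ml <- if (is.null(max_lag)) max(1L, session_bounds[i] %/% 2L)
          else min(as.integer(max_lag), session_bounds[i] - 1L)
    res <- .int_scan(mat[rows, , drop = FALSE], ml)
    acc <- acc + res$sums
    degenerate <- degenerate | res$degenerate
    truncated <- truncated | (res$truncated & !res$degenerate)
  }
  vals <- tr * acc / length(session_bounds)
  vals[degenerate] <- 0
  if (any(degenerate))
    message(sum(degenerate), " degenerate (constant) voxel(s) set to INT = 0")
  if (any(truncated))
    message(sum(truncated), " voxel(s) had no negative ACF value within ",
            "max_lag (INT truncated)")
  grid <- array(NA_real_, dim = dv[1:3])
  grid[mask] <- vals
  structure(list(grid = grid, mask = mask, tr = tr, affine = affine,
                 n_degenerate = sum(degenerate),
                 n_truncated = sum(truncated)),
            class = "int_map")
}

#' @export
print.int_map <- function(x, ...) {
  cat(sprintf(
    "<int_map> %s grid, %d in-mask voxels, TR %.4g s, mean INT %.3f s\n",
    paste(dim(x$grid), collapse = "x"), sum(x$mask), x$tr,
    mean(x$grid[x$mask])))
  invisible(x)
}
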