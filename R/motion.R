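# Framewise displacement and the two-phase greedy FD matching algorithm:
# phase 1 removes the highest-motion patients until the Welch p on mean FD
# clears alpha; phase 2 removes the lowest-motion controls while doing so
# strictly shrinks the absolute group mean-FD difference.

#' Framewise displacement from rigid-body motion parameters
#'
#' Power convention: per-frame sum of absolute backward differences of the
#' six realignment parameters, with rotations (radians) converted to arc
#' length on a sphere of radius `radius` mm. The first frame has FD = 0.
#'
#' @param trace Numeric T x 6 matrix: translations x, y, z in mm, then
#'   rotations in radians (one row per frame).
#' @param radius Sphere radius in mm for the rotation terms (default 50).
#' @return Numeric vector of per-frame FD in mm (length T, first element 0).
#' @export
framewise_displacement <- function(trace, radius = 50) {
  trace <- as.matrix(trace)
  if (ncol(trace) != 6) stop("trace must have 6 columns, got ", ncol(trace))
  if (nrow(trace) < 2) stop("trace needs at least 2 frames")
  bad <- which(!is.finite(trace), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop("non-finite motion parameter at frame ", bad[1, 1])
  d <- abs(diff(trace))
  fd <- rowSums(d[, 1:3, drop = FALSE]) +
        radius * rowSums(d[, 4:6, drop = FALSE])
  c(0, fd)
}

#' Read a 6-column motion parameter file
#'
#' Whitespace-delimited, one row per frame (the realignment parameter
#' format emitted by FSL/SPM), no header.
#'
#' @param path File path.
#' @return T x 6 numeric matrix.
#' @export
read_motion_params <- function(path) {
  m <- as.matrix(utils::read.table(path, header = FALSE))
  if (ncol(m) != 6)
    stop("expected 6 motion parameter columns in ", path, ", got ", ncol(m))
  unname(m)
}

# Welch p-value on two numeric vectors (raw data route).
.welch_p <- function(a, b) {
  if (stats::sd(a) == 0 && stats::sd(b) == 0)
    return(if (mean(a) == mean(b)) 1 else 0)
  stats::t.test(a, b)$p.value
}

#' Two-phase greedy FD group matching
#'
#' Phase 1: while the Welch p on mean FD between controls and patients is
#' below `alpha` (and the patient group is above `min_group`), remove the
#' single patient with the largest mean FD. Phase 2: repeatedly consider
#' removing the control with the smallest mean FD; remove it only while
#' that strictly decreases the absolute group mean-FD difference (and the
#' control group stays above `min_group`). FD ties are broken by
#' lexicographic subject id, so the result is a pure function of the input.
#'
#' @param hc,sz Data frames with columns `subject_id` and `mean_fd`
#'   (controls and patients respectively).
#' @param alpha Phase-1 significance threshold (default 0.05).
#' @param min_group Smallest allowed group size (default 10).
#' @return An object of class `fd_match_result`: kept and removed ids per
#'   group (removed in removal order), final Welch p, final group mean FDs.
#' @export
fd_match <- function(hc, sz, alpha = 0.05, min_group = 10) {
  for (d in list(hc, sz)) {
    if (!all(c("subject_id", "mean_fd") %in% names(d)))
      stop("FD tables need columns subject_id and mean_fd")
    if (any(d$mean_fd < 0)) stop("mean_fd must be nonnegative")
  }
  if (nrow(hc) < min_group || nrow(sz) < min_group)
    stop("both groups must start with at least min_group = ", min_group,
         " subjects")
  # ascending FD, ties by subject_id: SZ removals pop from the tail,
  # HC removals pop from the head
  hc <- hc[order(hc$mean_fd, hc$subject_id), , drop = FALSE]
  sz <- sz[order(sz$mean_fd, sz$subject_id), , drop = FALSE]
  removed_sz <- character(0)
  removed_hc <- character(0)

  p <- .welch_p(hc$mean_fd, sz$mean_fd)
  while (p < alpha) {
    if (nrow(sz) <= min_group)
      stop("FD matching failed: patient group at min_group = ", min_group,
           " with Welch p = ", signif(p, 3), " < alpha = ", alpha)
    removed_sz <- c(removed_sz, sz$subject_id[nrow(sz)])
    sz <- sz[-nrow(sz), , drop = FALSE]
    p <- .welch_p(hc$mean_fd, sz$mean_fd)
  }

  dmean <- abs(mean(hc$mean_fd) - mean(sz$mean_fd))
  while (nrow(hc) > min_group) {
    cand <- hc[-1, , drop = FALSE]
    dnew <- abs(mean(cand$mean_fd) - mean(sz$mean_fd))
    if (dnew >= dmean) break
    removed_hc <- c(removed_hc, hc$subject_id[1])
    hc <- cand
    dmean <- dnew
  }

  structure(list(kept_hc = hc$subject_id, kept_sz = sz$subject_id,
                 removed_hc = removed_hc, removed_sz = removed_sz,
                 final_p = .welch_p(hc$mean_fd, sz$mean_fd),
                 mean_fd_hc = mean(hc$mean_fd),
                 mean_fd_sz = mean(sz$mean_fd),
                 alpha = alpha),
            class = "fd_match_result")
}

#' @export
print.fd_match_result <- function(x, ...) {
  cat(sprintf(paste0(
    "<fd_match_result> kept %d HC / %d SZ (removed %d / %d), ",
    "Welch p = %.3f, mean FD %.3f vs %.3f mm\n"),
    length(x$kept_hc), length(x$kept_sz),
    length(x$removed_hc), length(x$removed_sz),
    x$final_p, x$mean_fd_hc, x$mean_fd_sz))
  invisible(x)
}
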