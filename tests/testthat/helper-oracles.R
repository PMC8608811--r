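# Independent brute-force oracles. These deliberately share no code with
# the package implementations they check.

# Connected components by iterative min-label propagation: every active
# voxel starts with its own label (its linear index) and repeatedly takes
# the minimum label over its active neighbours (whole-array shifts) until
# a fixed point. Independent of the package's BFS implementation.
oracle_label_components <- function(active, connectivity) {
  dims <- dim(active)
  lim <- switch(as.character(connectivity), "6" = 1L, "18" = 2L, "26" = 3L)
  g <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  g <- g[rowSums(abs(g)) > 0 & rowSums(abs(g)) <= lim, , drop = FALSE]
  shift <- function(arr, off, fill) {
    out <- array(fill, dims)
    src <- lapply(1:3, function(d) {
      s <- seq_len(dims[d]) - off[d]
      s[s >= 1 & s <= dims[d]]
    })
    dst <- lapply(1:3, function(d) src[[d]] + off[d])
    out[dst[[1]], dst[[2]], dst[[3]]] <- arr[src[[1]], src[[2]], src[[3]]]
    out
  }
  lab <- array(Inf, dims)
  lab[active] <- which(active)
  repeat {
    new <- lab
    for (r in seq_len(nrow(g))) {
      sh <- shift(lab, g[r, ], Inf)
      new <- pmin(new, sh)
    }
    new[!active] <- Inf
    if (identical(new, lab)) break
    lab <- new
  }
  lab[!active] <- 0
  array(lab, dims)
}

# TRUE iff two labelled arrays induce the same partition of active voxels.
same_partition <- function(a, b) {
  if (!identical(a > 0, b > 0)) return(FALSE)
  act <- which(a > 0)
  length(unique(paste(a[act], b[act]))) ==
    length(unique(a[act])) &&
  length(unique(a[act])) == length(unique(b[act]))
}

# Least squares by explicit normal equations, with Type II F per term:
# refit without that term's columns and compare residual sums of squares.
oracle_main_effects <- function(y, data) {
  data <- as.data.frame(data)
  for (nm in names(data))
    if (is.character(data[[nm]])) data[[nm]] <- factor(data[[nm]])
  X <- stats::model.matrix(~ ., data = data)
  asg <- attr(X, "assign")
  beta <- solve(t(X) %*% X, t(X) %*% y)
  rss_full <- sum((y - X %*% beta)^2)
  df_res <- length(y) - ncol(X)
  terms <- attr(stats::terms(~ ., data = data), "term.labels")
  res <- lapply(seq_along(terms), function(i) {
    keep <- asg != i
    Xr <- X[, keep, drop = FALSE]
    br <- solve(t(Xr) %*% Xr, t(Xr) %*% y)
    rss_r <- sum((y - Xr %*% br)^2)
    df_t <- sum(!keep)
    Fv <- ((rss_r - rss_full) / df_t) / (rss_full / df_res)
    data.frame(term = terms[i], df = df_t, F = Fv,
               p = stats::pf(Fv, df_t, df_res, lower.tail = FALSE))
  })
  do.call(rbind, res)
}

# Exhaustive replay of the two-phase greedy FD matching rule, written as a
# direct transcription of the procedure (no shared code with fd_match).
oracle_fd_match <- function(hc, sz, alpha = 0.05, min_group = 10) {
  ord <- function(d) d[order(d$mean_fd, d$subject_id), ]
  hc <- ord(hc); sz <- ord(sz)
  wp <- function(a, b) stats::t.test(a, b)$p.value
  removed_sz <- character(0)
  while (wp(hc$mean_fd, sz$mean_fd) < alpha && nrow(sz) > min_group) {
    removed_sz <- c(removed_sz, sz$subject_id[nrow(sz)])
    sz <- sz[-nrow(sz), ]
  }
  removed_hc <- character(0)
  repeat {
    if (nrow(hc) <= min_group) break
    d_now <- abs(mean(hc$mean_fd) - mean(sz$mean_fd))
    d_try <- abs(mean(hc$mean_fd[-1]) - mean(sz$mean_fd))
    if (d_try >= d_now) break
    removed_hc <- c(removed_hc, hc$subject_id[1])
    hc <- hc[-1, ]
  }
  list(kept_hc = hc$subject_id, kept_sz = sz$subject_id,
       removed_hc = removed_hc, removed_sz = removed_sz)
}

# Tiny test cohort: small grid, optional planted regions, short series.
tiny_cohort_spec <- function(seed, n_per_group = 12, grid = c(14, 14, 12),
                             n_frames = 100, regions = list(), ...) {
  cohort_spec(n_per_group = n_per_group, grid_shape = grid,
              n_frames = n_frames, planted_regions = regions,
              seed = seed, ...)
}
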