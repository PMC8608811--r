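# Mass-univariate group comparison of INT maps, cluster extraction at an
# uncorrected threshold, BH-FDR at cluster peaks, ROI mean extraction.

# Stack a list of int_map grids into a voxels x subjects matrix over the
# shared mask, checking grid compatibility.
.stack_maps <- function(maps) {
  mask <- maps[[1]]$mask
  for (m in maps) {
    if (!identical(dim(m$grid), dim(mask)))
      stop("INT map grids differ: ", paste(dim(m$grid), collapse = "x"),
           " vs ", paste(dim(mask), collapse = "x"))
    if (!identical(m$mask, mask)) stop("INT map masks differ")
  }
  vapply(maps, function(m) m$grid[mask], numeric(sum(mask)))
}

#' Voxel-wise two-sample t test between groups of INT maps
#'
#' Pooled-variance t by default (the mass-univariate convention under which
#' discovery ROIs are defined); Welch with Satterthwaite degrees of freedom
#' by flag. The sign convention is `a - b`: positive t where group A has the
#' longer timescale.
#'
#' @param maps_a,maps_b Lists of `int_map` objects (>= 2 each) on identical
#'   grids and masks.
#' @param variant `"pooled"` or `"welch"`.
#' @return An object of class `stat_map`: list with 3D `t` and `p` grids
#'   (`NA` outside the mask), `df` (scalar for pooled, 3D grid for Welch),
#'   `mask`, `affine`, `variant`.
#' @export
voxelwise_ttest <- function(maps_a, maps_b,
                            variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  if (length(maps_a) < 2 || length(maps_b) < 2)
    stop("need at least 2 maps per group")
  xa <- .stack_maps(c(maps_a, maps_b))
  n1 <- length(maps_a); n2 <- length(maps_b)
  a <- xa[, seq_len(n1), drop = FALSE]
  b <- xa[, n1 + seq_len(n2), drop = FALSE]
  m1 <- rowMeans(a); m2 <- rowMeans(b)
  v1 <- rowSums((a - m1)^2) / (n1 - 1)
  v2 <- rowSums((b - m2)^2) / (n2 - 1)
  if (variant == "pooled") {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    tv <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
    pv <- 2 * stats::pt(-abs(tv), df)
  } else {
    se2 <- v1 / n1 + v2 / n2
    tv <- (m1 - m2) / sqrt(se2)
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
    pv <- 2 * stats::pt(-abs(tv), df)
  }
  mask <- maps_a[[1]]$mask
  tg <- array(NA_real_, dim = dim(mask)); tg[mask] <- tv
  pg <- array(NA_real_, dim = dim(mask)); pg[mask] <- pv
  dfout <- if (variant == "pooled") df else {
    dg <- array(NA_real_, dim = dim(mask)); dg[mask] <- df; dg
  }
  structure(list(t = tg, p = pg, df = dfout, mask = mask,
                 affine = maps_a[[1]]$affine, variant = variant),
            class = "stat_map")
}

# Neighbourhood offsets for 6/18/26 connectivity.
.conn_offsets <- function(connectivity) {
  connectivity <- as.integer(connectivity)
  if (!connectivity %in% c(6L, 18L, 26L))
    stop("connectivity must be 6, 18 or 26")
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  s <- rowSums(abs(g))
  lim <- c(`6` = 1L, `18` = 2L, `26` = 3L)[[as.character(connectivity)]]
  g[s > 0 & s <= lim, , drop = FALSE]
}

# BFS connected-component labelling of a 3D logical array.
# Returns an integer array: 0 background, 1..k component labels.
.label_components <- function(active, connectivity) {
  dims <- dim(active)
  labels <- array(0L, dim = dims)
  offs <- .conn_offsets(connectivity)
  lin <- which(active)
  if (length(lin) == 0) return(labels)
  coords <- arrayInd(lin, dims)
  next_label <- 0L
  for (start in lin) {
    if (labels[start] != 0L) next
    next_label <- next_label + 1L
    labels[start] <- next_label
    queue <- matrix(arrayInd(start, dims), ncol = 3)
    while (nrow(queue) > 0) {
      cur <- queue[nrow(queue), , drop = FALSE]
      queue <- queue[-nrow(queue), , drop = FALSE]
      nb <- sweep(offs, 2, as.numeric(cur), `+`)
      ok <- nb[, 1] >= 1 & nb[, 1] <= dims[1] &
            nb[, 2] >= 1 & nb[, 2] <= dims[2] &
            nb[, 3] >= 1 & nb[, 3] <= dims[3]
      nb <- nb[ok, , drop = FALSE]
      if (nrow(nb) == 0) next
      nlin <- nb[, 1] + (nb[, 2] - 1L) * dims[1] +
              (nb[, 3] - 1L) * dims[1] * dims[2]
      take <- active[nlin] & labels[nlin] == 0L
      if (any(take)) {
        labels[nlin[take]] <- next_label
        queue <- rbind(queue, nb[take, , drop = FALSE])
      }
    }
  }
  labels
}

#' Extract supra-threshold clusters from a statistic map
#'
#' Thresholds the map at `p < p_thresh` in the requested direction, labels
#' connected components, drops components below `min_cluster_size`, and
#' reports each surviving cluster's size, peak voxel (maximal |t|, ties
#' broken by smallest linear index), peak coordinate in mm through the
#' affine, and the BH-FDR q-value of the peak voxel computed over all
#' in-mask voxel p-values. Clusters are sorted by size descending, then
#' peak |t| descending.
#'
#' @param stat A `stat_map`.
#' @param p_thresh Uncorrected voxel threshold (default 0.001).
#' @param direction `"a_gt_b"` (t > 0) or `"b_gt_a"` (t < 0).
#' @param connectivity 6, 18 (default) or 26.
#' @param min_cluster_size Minimum surviving component size (default 5).
#' @return An object of class `cluster_set`: list with `clusters` (data
#'   frame: label, size, peak x/y/z mm, peak_t, fdr_q_at_peak), `labels`
#'   (3D integer array, 0 background), and `rois` (list of `roi_mask`
#'   objects, one per cluster, in table order).
#' @export
extract_clusters <- function(stat, p_thresh = 0.001,
                             direction = c("a_gt_b", "b_gt_a"),
                             connectivity = 18, min_cluster_size = 5) {
  stopifnot(inherits(stat, "stat_map"))
  direction <- match.arg(direction)
  signok <- if (direction == "a_gt_b") stat$t > 0 else stat$t < 0
  active <- !is.na(stat$p) & stat$p < p_thresh & signok
  active[is.na(active)] <- FALSE
  empty <- list(
    clusters = data.frame(label = integer(0), size = integer(0),
                          peak_x = numeric(0), peak_y = numeric(0),
                          peak_z = numeric(0), peak_t = numeric(0),
                          fdr_q_at_peak = numeric(0)),
    labels = array(0L, dim = dim(stat$mask)), rois = list())
  if (!any(active)) return(structure(empty, class = "cluster_set"))

  raw <- .label_components(active, connectivity)
  sizes <- tabulate(raw[raw > 0L])
  keep <- which(sizes >= min_cluster_size)
  if (length(keep) == 0) return(structure(empty, class = "cluster_set"))

  affine <- if (is.null(stat$affine)) diag(4) else stat$affine
  qall <- array(NA_real_, dim = dim(stat$mask))
  qall[stat$mask] <- stats::p.adjust(stat$p[stat$mask], method = "BH")
  info <- lapply(keep, function(lab) {
    lin <- which(raw == lab)
    peak <- lin[order(-abs(stat$t[lin]), lin)[1]]
    ijk <- arrayInd(peak, dim(stat$mask)) - 1L   # 0-based voxel index
    mm <- voxel_to_mm(as.numeric(ijk), affine)
    list(size = length(lin), peak_t = stat$t[peak], mm = mm,
         q = qall[peak], lin = lin)
  })
  ord <- order(-vapply(info, `[[`, numeric(1), "size"),
               -abs(vapply(info, `[[`, numeric(1), "peak_t")))
  info <- info[ord]
  labels <- array(0L, dim = dim(stat$mask))
  rois <- vector("list", length(info))
  for (i in seq_along(info)) {
    labels[info[[i]]$lin] <- i
    vox <- array(FALSE, dim = dim(stat$mask))
    vox[info[[i]]$lin] <- TRUE
    rois[[i]] <- roi_mask(paste0("cluster_", i), vox)
  }
  clusters <- data.frame(
    label = seq_along(info),
    size = vapply(info, `[[`, numeric(1), "size"),
    peak_x = vapply(info, function(x) x$mm[1], numeric(1)),
    peak_y = vapply(info, function(x) x$mm[2], numeric(1)),
    peak_z = vapply(info, function(x) x$mm[3], numeric(1)),
    peak_t = vapply(info, `[[`, numeric(1), "peak_t"),
    fdr_q_at_peak = vapply(info, `[[`, numeric(1), "q"))
  structure(list(clusters = clusters, labels = labels, rois = rois),
            class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  cat(sprintf("<cluster_set> %d cluster(s)\n", nrow(x$clusters)))
  if (nrow(x$clusters)) print(x$clusters)
  invisible(x)
}

#' Region-of-interest mask
#'
#' @param name Label for reports.
#' @param voxels 3D logical array; must be nonempty.
#' @return An object of class `roi_mask`.
#' @export
roi_mask <- function(name, voxels) {
  voxels <- array(as.logical(voxels), dim = dim(voxels))
  if (!any(voxels)) stop("ROI '", name, "' is empty")
  structure(list(name = name, voxels = voxels), class = "roi_mask")
}

#' Mean INT over an ROI
#'
#' Arithmetic mean of the INT map over the ROI voxels (the REX-style
#' extraction used for cluster-level group comparisons).
#'
#' @param map An `int_map`.
#' @param roi An `roi_mask` lying within the map's brain mask.
#' @return Mean INT in seconds.
#' @export
roi_mean <- function(map, roi) {
  stopifnot(inherits(map, "int_map"), inherits(roi, "roi_mask"))
  if (!identical(dim(roi$voxels), dim(map$grid)))
    stop("ROI grid does not match map grid")
  sel <- roi$voxels & map$mask
  if (!any(sel))
    stop("ROI '", roi$name, "' does not intersect the map mask")
  if (any(roi$voxels & !map$mask))
    stop("ROI '", roi$name, "' extends outside the map mask")
  mean(map$grid[sel])
}
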