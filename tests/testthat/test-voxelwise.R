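# Build a stack of small int_map objects directly (no simulation needed).
make_maps <- function(n, dims = c(6, 5, 4), mask = NULL, seed = 1,
                      shift = 0) {
  set.seed(seed)
  if (is.null(mask)) mask <- array(TRUE, dims)
  lapply(seq_len(n), function(i) {
    g <- array(NA_real_, dims)
    g[mask] <- rnorm(sum(mask)) + shift
    structure(list(grid = g, mask = mask, tr = 2, affine = diag(4),
                   n_degenerate = 0, n_truncated = 0), class = "int_map")
  })
}

test_that("voxelwise_ttest matches the scalar two-sample test per voxel", {
  dims <- c(6, 5, 4)
  mask <- array(runif(prod(dims)) < 0.8, dims)
  a <- make_maps(8, dims, mask, seed = 2)
  b <- make_maps(9, dims, mask, seed = 3, shift = 0.4)
  for (variant in c("pooled", "welch")) {
    st <- voxelwise_ttest(a, b, variant = variant)
    lin <- sample(which(mask), 10)
    for (v in lin) {
      xa <- vapply(a, function(m) m$grid[v], numeric(1))
      xb <- vapply(b, function(m) m$grid[v], numeric(1))
      ref <- t.test(xa, xb, var.equal = (variant == "pooled"))
      expect_equal(st$t[v], unname(ref$statistic))
      expect_equal(st$p[v], ref$p.value)
      df <- if (variant == "pooled") st$df else st$df[v]
      expect_equal(df, unname(ref$parameter))
    }
    # antisymmetry and invariance to within-group subject order
    st_rev <- voxelwise_ttest(b, a, variant = variant)
    expect_equal(st_rev$t[mask], -st$t[mask])
    st_perm <- voxelwise_ttest(a[sample(8)], b[sample(9)],
                               variant = variant)
    expect_identical(st_perm$t, st$t)
  }
  expect_error(voxelwise_ttest(a[1], b), "at least 2")
  expect_error(voxelwise_ttest(a, make_maps(3, c(5, 5, 4))), "differ")
})

test_that("null maps give ~alpha-level supra-threshold rates", {
  a <- make_maps(10, c(12, 12, 10), seed = 8)
  b <- make_maps(10, c(12, 12, 10), seed = 9)
  st <- voxelwise_ttest(a, b)
  expect_lt(mean(st$p[st$mask] < 0.01), 0.025)
  expect_gt(ks.test(st$p[st$mask], "punif")$p.value, 0.01)
})

# Wrap a t grid (with sign) into a stat_map for cluster tests.
make_stat <- function(tgrid, mask = NULL, df = 30, affine = diag(4)) {
  if (is.null(mask)) mask <- array(TRUE, dim(tgrid))
  p <- array(NA_real_, dim(tgrid))
  p[mask] <- 2 * pt(-abs(tgrid[mask]), df)
  structure(list(t = tgrid, p = p, df = df, mask = mask, affine = affine,
                 variant = "pooled"), class = "stat_map")
}

test_that("extract_clusters finds planted blobs with exact sizes", {
  dims <- c(16, 16, 16)
  tg <- array(0.1, dims)
  mask <- array(TRUE, dims)
  blob1 <- compact_region(mask, c(4, 4, 4), 30)
  blob2 <- compact_region(mask, c(13, 13, 13), 12)
  tg[blob1] <- 8; tg[blob2] <- 6
  cs <- extract_clusters(make_stat(tg), min_cluster_size = 5)
  expect_equal(nrow(cs$clusters), 2)
  expect_equal(cs$clusters$size, c(30, 12))
  expect_setequal(which(cs$labels == 1), blob1)
  expect_setequal(which(cs$labels == 2), blob2)
  # ROI masks mirror the label array, in table order
  expect_setequal(which(cs$rois[[1]]$voxels), blob1)

  # sub-threshold map: empty result, not an error
  cs0 <- extract_clusters(make_stat(array(0.1, dims)))
  expect_equal(nrow(cs0$clusters), 0)
  expect_length(cs0$rois, 0)

  # wrong-direction effects are ignored
  tg2 <- array(0.1, dims); tg2[blob1] <- -8
  expect_equal(nrow(extract_clusters(make_stat(tg2),
                                     direction = "a_gt_b")$clusters), 0)
  expect_equal(extract_clusters(make_stat(tg2),
                                direction = "b_gt_a")$clusters$size, 30)
})

test_that("singleton cluster reports its peak through the affine", {
  dims <- c(8, 8, 8)
  tg <- array(0, dims)
  tg[3, 5, 7] <- 9
  aff <- rbind(c(3, 0, 0, -12), c(0, 3, 0, -15), c(0, 0, 3, -18),
               c(0, 0, 0, 1))
  cs <- extract_clusters(make_stat(tg, affine = aff), min_cluster_size = 1)
  expect_equal(nrow(cs$clusters), 1)
  expect_equal(cs$clusters$size, 1)
  # 0-based voxel (2, 4, 6) through the affine
  expect_equal(unlist(cs$clusters[1, c("peak_x", "peak_y", "peak_z")]),
               c(peak_x = 3 * 2 - 12, peak_y = 3 * 4 - 15,
                 peak_z = 3 * 6 - 18))
  expect_equal(cs$clusters$peak_t, 9)
})

test_that("peak FDR q equals BH over all in-mask p-values", {
  set.seed(5)
  dims <- c(10, 10, 8)
  tg <- array(rnorm(prod(dims)), dims)
  blob <- compact_region(array(TRUE, dims), c(5, 5, 4), 20)
  tg[blob] <- 7
  st <- make_stat(tg)
  cs <- extract_clusters(st, min_cluster_size = 5)
  expect_gte(nrow(cs$clusters), 1)
  qref <- p.adjust(st$p[st$mask], method = "BH")
  peaklin <- which(st$mask)[which.min(st$p[st$mask])]
  expect_equal(cs$clusters$fdr_q_at_peak[1], qref[which.min(st$p[st$mask])])
})

test_that("component labelling agrees with the brute-force oracle", {
  set.seed(77)
  for (i in 1:5) {
    act <- array(runif(16^3) < 0.25, c(16, 16, 16))
    for (conn in c(6, 18, 26)) {
      mine <- intpipe:::.label_components(act, conn)
      ref <- oracle_label_components(act, conn)
      expect_true(same_partition(mine, ref),
                  label = sprintf("partition equality, grid %d conn %d",
                                  i, conn))
    }
  }
})

test_that("cluster ordering is a stable size-then-peak sort", {
  dims <- c(16, 8, 8)
  tg <- array(0, dims)
  mask <- array(TRUE, dims)
  b1 <- compact_region(mask, c(3, 4, 4), 10)
  b2 <- compact_region(mask, c(13, 4, 4), 10)
  tg[b1] <- 5; tg[b2] <- 9
  cs <- extract_clusters(make_stat(tg), min_cluster_size = 5)
  expect_equal(cs$clusters$peak_t, c(9, 5))  # equal size: larger |t| first
})

test_that("roi_mean is an arithmetic mean with strict containment", {
  dims <- c(6, 6, 6)
  mask <- array(TRUE, dims)
  g <- array(rnorm(prod(dims))^2, dims)
  map <- structure(list(grid = g, mask = mask, tr = 2, affine = diag(4)),
                   class = "int_map")
  vox <- array(FALSE, dims); vox[compact_region(mask, c(3, 3, 3), 17)] <- TRUE
  roi <- roi_mask("r", vox)
  expect_equal(roi_mean(map, roi), sum(g[vox]) / 17)

  single <- array(FALSE, dims); single[2, 3, 4] <- TRUE
  expect_equal(roi_mean(map, roi_mask("s", single)), g[2, 3, 4])

  cmap <- map; cmap$grid[] <- 3.14
  expect_equal(roi_mean(cmap, roi), 3.14)

  # ROI leaking outside the brain mask is rejected
  map2 <- map; map2$mask[1, , ] <- FALSE; map2$grid[1, , ] <- NA
  out <- array(FALSE, dims); out[1, 1, 1] <- TRUE
  expect_error(roi_mean(map2, roi_mask("o", out)), "intersect")
  leak <- out; leak[3, 3, 3] <- TRUE
  expect_error(roi_mean(map2, roi_mask("l", leak)), "outside")
  expect_error(roi_mask("empty", array(FALSE, dims)), "empty")
})
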