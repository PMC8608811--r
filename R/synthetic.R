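# Seeded synthetic rsfMRI cohorts.
#
# Voxel time series are stationary Gaussian AR(1) processes with spatially
# varying lag-1 coefficients; case-control timescale reductions are planted
# as compact voxel clusters where patients receive a lower phi. Per-subject
# mean framewise displacement is lognormal with a group-specific location,
# and one symptom score is linearly coupled to the subject's true mean INT
# over the first planted region.

#' Simulate a stationary AR(1) series
#'
#' `x_t = phi * x_{t-1} + e_t` with Gaussian innovations; the initial state
#' is drawn from the stationary distribution so the series is stationary
#' from the first frame. The same `(phi, n_frames, innovation_sd, seed)`
#' always yields the identical sequence.
#'
#' @param phi Lag-1 autocorrelation coefficient in `[0, 1)`.
#' @param n_frames Number of samples (>= 2).
#' @param innovation_sd Innovation standard deviation (> 0).
#' @param seed Integer RNG seed; `NULL` uses the current RNG state.
#' @param tr Repetition time attached to the returned series (seconds).
#' @return A `bold_series`.
#' @export
simulate_series <- function(phi, n_frames, innovation_sd = 1, seed = NULL,
                            tr = 2) {
  if (!is.finite(phi) || phi < 0 || phi >= 1)
    stop("phi must lie in [0, 1) for a stationary AR(1); got ", phi)
  n_frames <- as.integer(n_frames)
  if (n_frames < 2) stop("n_frames must be >= 2")
  if (!is.null(seed)) set.seed(as.integer(seed))
  e <- rnorm(n_frames, sd = innovation_sd)
  x <- numeric(n_frames)
  x[1] <- e[1] / sqrt(1 - phi^2)  # stationary marginal sd
  if (n_frames > 1 && phi > 0) {
    x[2:n_frames] <- as.vector(
      stats::filter(e[-1], phi, method = "recursive", init = x[1]))
  } else if (phi == 0) {
    x[2:n_frames] <- e[-1]
  }
  bold_series(x, tr = tr)
}

# AR(1) matrix simulation: one row per voxel (voxels x frames), per-voxel
# phi. Column-major recursion keeps each time step contiguous in memory.
.simulate_ar1_matrix <- function(phi, n_frames, innovation_sd = 1) {
  v <- length(phi)
  x <- matrix(rnorm(n_frames * v, sd = innovation_sd), v, n_frames)
  x[, 1] <- x[, 1] / sqrt(1 - phi^2)
  for (t in 2:n_frames) x[, t] <- phi * x[, t - 1] + x[, t]
  x
}

#' Ellipsoidal brain-like mask
#'
#' @param grid_shape Integer vector of 3 voxel dimensions.
#' @return 3D logical array: the ellipsoid inscribed in the grid.
#' @export
ellipsoid_mask <- function(grid_shape) {
  c0 <- (grid_shape - 1) / 2
  r <- grid_shape / 2
  idx <- expand.grid(i = seq_len(grid_shape[1]) - 1,
                     j = seq_len(grid_shape[2]) - 1,
                     k = seq_len(grid_shape[3]) - 1)
  inside <- ((idx$i - c0[1]) / r[1])^2 + ((idx$j - c0[2]) / r[2])^2 +
            ((idx$k - c0[3]) / r[3])^2 <= 1
  array(inside, dim = grid_shape)
}

#' Compact region of a given size inside a mask
#'
#' Returns the `n_voxels` in-mask voxels closest to `center` (Euclidean
#' distance in voxel units, ties broken by linear index), as linear indices
#' into the grid. Used to plant case-control effects as compact clusters.
#'
#' @param mask 3D logical array.
#' @param center Numeric length-3 voxel coordinate (1-based).
#' @param n_voxels Region size.
#' @return Integer vector of linear voxel indices.
#' @export
compact_region <- function(mask, center, n_voxels) {
  lin <- which(mask)
  if (n_voxels > length(lin))
    stop("region size exceeds in-mask voxel count")
  ijk <- arrayInd(lin, dim(mask))
  d2 <- (ijk[, 1] - center[1])^2 + (ijk[, 2] - center[2])^2 +
        (ijk[, 3] - center[3])^2
  lin[order(d2, lin)[seq_len(n_voxels)]]
}

#' Cohort simulation specification
#'
#' Collects every parameter of the synthetic cohort. Defaults emulate a
#' single-session resting-state acquisition with TR = 2 s and 150 frames,
#' a baseline lag-1 autocorrelation of 0.3 (true INT 0.86 s, matching the
#' sub-second ROI means seen in short-TR samples), and a patient group with
#' moderately higher head motion.
#'
#' @param n_per_group Subjects per diagnostic group (HC and SZ).
#' @param grid_shape 3D voxel dimensions.
#' @param mask 3D logical array; default ellipsoid inscribed in the grid.
#' @param tr Repetition time, seconds per frame (> 0).
#' @param n_frames Frames per session (>= 50).
#' @param n_sessions Session count.
#' @param base_phi Baseline lag-1 coefficient in `[0, 1)`.
#' @param planted_regions List of regions, each a list with `voxels`
#'   (linear indices into the grid), `phi_control`, `phi_patient`. Regions
#'   must be disjoint and inside the mask.
#' @param phi_jitter_sd SD of the per-subject, per-voxel Gaussian jitter
#'   added to phi (truncated to `[0, 0.95]`); gives nonzero between-subject
#'   variance, which the group t tests require.
#' @param noise_sd Innovation scale of the AR(1) observation process.
#' @param fd_params List with `hc` and `sz`, each `c(meanlog, sdlog)` of the
#'   per-subject mean-FD lognormal (mm). Default: HC location log(0.15) mm,
#'   SZ location log(0.22) mm, sdlog 0.4 — positive, right-skewed, patients
#'   shifted upward as in clinical samples.
#' @param symptom_model List with `intercept`, `slope` (per second of true
#'   mean INT over the first planted region), `noise_sd`; scores are
#'   generated for patients only. Default 20 - 5 * INT + N(0, 4), a
#'   PANSS-positive-like scale decreasing with longer timescales.
#' @param prop_male Proportion of males per group.
#' @param age_mean,age_sd Age distribution (years), shared across groups.
#' @param cpz_meanlog,cpz_sdlog Lognormal chlorpromazine-equivalent dose
#'   (mg/day), patients only.
#' @param seed Integer seed; the cohort is a pure function of the spec.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_group = 20,
                        grid_shape = c(24, 24, 24),
                        mask = NULL,
                        tr = 2,
                        n_frames = 150,
                        n_sessions = 1,
                        base_phi = 0.3,
                        planted_regions = list(),
                        phi_jitter_sd = 0.05,
                        noise_sd = 1,
                        fd_params = list(hc = c(log(0.15), 0.4),
                                         sz = c(log(0.22), 0.4)),
                        symptom_model = list(intercept = 20, slope = -5,
                                             noise_sd = 4),
                        prop_male = 0.6,
                        age_mean = 35, age_sd = 10,
                        cpz_meanlog = log(400), cpz_sdlog = 0.5,
                        seed = 1) {
  if (is.null(mask)) mask <- ellipsoid_mask(grid_shape)
  mask <- array(as.logical(mask), dim = dim(mask))
  if (!identical(as.integer(dim(mask)), as.integer(grid_shape)))
    stop("mask shape does not match grid_shape")
  if (sum(mask) == 0) stop("mask contains no voxels")
  if (n_frames < 50) stop("n_frames must be >= 50")
  if (tr <= 0) stop("tr must be positive")
  if (base_phi < 0 || base_phi >= 1) stop("base_phi must lie in [0, 1)")
  seen <- integer(0)
  for (r in planted_regions) {
    if (any(!mask[r$voxels])) stop("planted region extends outside the mask")
    if (any(r$voxels %in% seen)) stop("planted regions must be disjoint")
    for (p in c(r$phi_control, r$phi_patient))
      if (p < 0 || p >= 1) stop("planted phi must lie in [0, 1)")
    seen <- c(seen, r$voxels)
  }
  structure(list(n_per_group = as.integer(n_per_group),
                 grid_shape = as.integer(grid_shape), mask = mask,
                 tr = tr, n_frames = as.integer(n_frames),
                 n_sessions = as.integer(n_sessions),
                 base_phi = base_phi, planted_regions = planted_regions,
                 phi_jitter_sd = phi_jitter_sd, noise_sd = noise_sd,
                 fd_params = fd_params, symptom_model = symptom_model,
                 prop_male = prop_male, age_mean = age_mean, age_sd = age_sd,
                 cpz_meanlog = cpz_meanlog, cpz_sdlog = cpz_sdlog,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Simulate a case-control cohort
#'
#' Every in-mask voxel of every subject is an independent AR(1) draw with
#' that subject's group phi at that voxel (plus truncated per-voxel jitter);
#' out-of-mask voxels are zero. Returns the ground-truth phi and INT maps
#' (`tr * phi / (1 - phi)`) for recovery tests.
#'
#' @param spec A [cohort_spec()].
#' @return An object of class `synthetic_cohort`: list with `volumes` (list
#'   of 4D arrays, one per subject), `records` (data.frame of subject
#'   metadata), `truth` (list with per-subject `phi` and `int` 3D maps, and
#'   `region_true_int` per-subject mean true INT over region 1), `spec`.
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  n <- spec$n_per_group
  groups <- rep(c("HC", "SZ"), each = n)
  ids <- sprintf("sub-%03d", seq_len(2 * n))
  mask_lin <- which(spec$mask)
  nvox <- length(mask_lin)
  nt <- spec$n_frames * spec$n_sessions

  # group-level phi fields over in-mask voxels
  phi_group <- list(HC = rep(spec$base_phi, nvox),
                    SZ = rep(spec$base_phi, nvox))
  pos <- match(unlist(lapply(spec$planted_regions, `[[`, "voxels")),
               mask_lin)
  off <- 0
  for (r in spec$planted_regions) {
    j <- pos[off + seq_along(r$voxels)]
    phi_group$HC[j] <- r$phi_control
    phi_group$SZ[j] <- r$phi_patient
    off <- off + length(r$voxels)
  }

  volumes <- vector("list", 2 * n)
  phi_maps <- vector("list", 2 * n)
  int_maps <- vector("list", 2 * n)
  region_true_int <- numeric(2 * n)
  r1 <- if (length(spec$planted_regions) > 0)
    match(spec$planted_regions[[1]]$voxels, mask_lin) else seq_len(nvox)

  for (s in seq_len(2 * n)) {
    phi_s <- phi_group[[groups[s]]] +
      rnorm(nvox, sd = spec$phi_jitter_sd)
    phi_s <- pmin(pmax(phi_s, 0), 0.95)
    flat <- matrix(0, prod(spec$grid_shape), nt)
    for (sess in seq_len(spec$n_sessions)) {
      cols <- (sess - 1) * spec$n_frames + seq_len(spec$n_frames)
      flat[mask_lin, cols] <-
        .simulate_ar1_matrix(phi_s, spec$n_frames, spec$noise_sd)
    }
    dim(flat) <- c(spec$grid_shape, nt)
    volumes[[s]] <- flat
    pm <- array(NA_real_, dim = spec$grid_shape)
    pm[mask_lin] <- phi_s
    phi_maps[[s]] <- pm
    im <- array(NA_real_, dim = spec$grid_shape)
    im[mask_lin] <- spec$tr * phi_s / (1 - phi_s)
    int_maps[[s]] <- im
    region_true_int[s] <- mean(im[mask_lin[r1]])
  }

  fd <- ifelse(groups == "HC",
               rlnorm(2 * n, spec$fd_params$hc[1], spec$fd_params$hc[2]),
               rlnorm(2 * n, spec$fd_params$sz[1], spec$fd_params$sz[2]))
  sex <- ifelse(runif(2 * n) < spec$prop_male, "M", "F")
  age <- round(pmax(18, rnorm(2 * n, spec$age_mean, spec$age_sd)), 1)
  cpz <- ifelse(groups == "SZ",
                round(rlnorm(2 * n, spec$cpz_meanlog, spec$cpz_sdlog)),
                NA_real_)
  sm <- spec$symptom_model
  symptom <- ifelse(
    groups == "SZ",
    pmax(0, sm$intercept + sm$slope * region_true_int +
              rnorm(2 * n, sd = sm$noise_sd)),
    NA_real_)
  records <- data.frame(subject_id = ids, group = groups, sex = sex,
                        age = age, mean_fd = fd, cpz = cpz,
                        panss_positive = round(symptom, 2),
                        stringsAsFactors = FALSE)
  structure(list(volumes = volumes, records = records,
                 truth = list(phi = phi_maps, int = int_maps,
                              region_true_int = region_true_int),
                 spec = spec),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(
    "<synthetic_cohort> %d subjects (%d/group), grid %s, %d frames, TR %g s\n",
    nrow(x$records), x$spec$n_per_group,
    paste(x$spec$grid_shape, collapse = "x"),
    x$spec$n_frames * x$spec$n_sessions, x$spec$tr))
  invisible(x)
}

#' Write a cohort to disk
#'
#' One NIfTI volume per subject, one NIfTI mask, a TSV of subject records, a
#' TSV of per-subject truth summaries, and a JSON manifest listing all
#' paths. Files round-trip losslessly through [read_nifti()] /
#' [read_records()] (volumes are stored as float64).
#'
#' @param cohort A `synthetic_cohort`.
#' @param directory Output directory (created if needed).
#' @return The manifest as a named list, invisibly; also written as
#'   `manifest.json`.
#' @export
write_cohort <- function(cohort, directory) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(directory))
    stop("cannot create output directory: ", directory)
  spec <- cohort$spec
  affine <- diag(c(3, 3, 3, 1))
  vol_paths <- character(nrow(cohort$records))
  for (s in seq_len(nrow(cohort$records))) {
    vol_paths[s] <- file.path(
      directory, paste0(cohort$records$subject_id[s], "_bold.nii.gz"))
    write_nifti(cohort$volumes[[s]], vol_paths[s], affine = affine,
                tr = spec$tr, datatype = 64L)
  }
  mask_path <- file.path(directory, "mask.nii.gz")
  write_nifti(array(as.integer(spec$mask), dim = spec$grid_shape),
              mask_path, affine = affine, datatype = 2L)
  rec_path <- file.path(directory, "participants.tsv")
  write_records(cohort$records, rec_path)
  truth <- data.frame(subject_id = cohort$records$subject_id,
                      region1_true_int = cohort$truth$region_true_int,
                      mean_true_int = vapply(cohort$truth$int, function(m)
                        mean(m[spec$mask]), numeric(1)))
  truth_path <- file.path(directory, "truth.tsv")
  utils::write.table(truth, truth_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  manifest <- list(volumes = vol_paths, mask = mask_path,
                   records = rec_path, truth = truth_path,
                   tr = spec$tr,
                   session_bounds = rep(spec$n_frames, spec$n_sessions))
  jsonlite::write_json(manifest, file.path(directory, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Read / write subject record tables
#'
#' TSV with a header row; columns `subject_id`, `group` (HC/SZ), `sex`
#' (M/F), `age`, `mean_fd`, `cpz`, plus any symptom columns.
#'
#' @param records Data frame of subject records.
#' @param path TSV path.
#' @return `read_records` returns the data frame.
#' @export
write_records <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_records
#' @export
read_records <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
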