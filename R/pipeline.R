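# Config-driven orchestration of the full study design: discovery dataset
# -> ROI definition -> replication datasets -> motion-matched reanalysis,
# with TSV/JSON reports and an exclusions log.

#' Pipeline dataset entry
#'
#' Either file-backed (`volumes`, `mask`, `records` paths) or synthetic
#' (a [cohort_spec()]; volumes and records are generated in memory).
#'
#' @param name Dataset name.
#' @param role `"discovery"` (ROIs are defined here) or `"replication"`.
#' @param synthetic_spec Optional `cohort_spec`; when given, file paths are
#'   ignored.
#' @param volumes Character vector of per-subject 4D NIfTI paths, aligned
#'   with the rows of the records table.
#' @param mask Path to the 3D NIfTI brain mask.
#' @param records Path to the subject records TSV (see [read_records()]).
#' @param motion Optional character vector of 6-column motion parameter
#'   files, aligned with records; used to fill `mean_fd` when the records
#'   table lacks it.
#' @param tr Repetition time in seconds.
#' @param session_bounds Session lengths summing to the frame count.
#' @return A list of class `pipeline_dataset`.
#' @export
pipeline_dataset <- function(name, role = c("replication", "discovery"),
                             synthetic_spec = NULL, volumes = NULL,
                             mask = NULL, records = NULL, motion = NULL,
                             tr = NULL, session_bounds = NULL) {
  role <- match.arg(role)
  if (is.null(synthetic_spec) &&
      (is.null(volumes) || is.null(mask) || is.null(records)))
    stop("dataset '", name, "': need either synthetic_spec or ",
         "volumes + mask + records paths")
  structure(list(name = name, role = role, synthetic_spec = synthetic_spec,
                 volumes = volumes, mask = mask, records = records,
                 motion = motion, tr = tr, session_bounds = session_bounds),
            class = "pipeline_dataset")
}

#' Pipeline configuration
#'
#' @param datasets List of [pipeline_dataset()] entries; exactly one must
#'   have role `"discovery"`.
#' @param p_thresh Uncorrected voxel threshold for cluster discovery.
#' @param connectivity Cluster connectivity (6/18/26).
#' @param min_cluster_size Minimum cluster size in voxels.
#' @param max_rois Keep at most this many discovery clusters as ROIs.
#' @param alpha_fd Phase-1 threshold of the FD matching.
#' @param fd_min_group Smallest group size the FD matching may reach.
#' @param bonferroni_m Family size for ROI-level corrections; `NULL` uses
#'   the number of discovered ROIs.
#' @param include_lag0 Add the lag-0 term to the INT index (sensitivity
#'   flag; default `FALSE`).
#' @param ttest_variant Voxel-level test: `"pooled"` (default) or
#'   `"welch"`. ROI-level tests are always Welch.
#' @param seed Seed for synthetic datasets lacking one.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(datasets, p_thresh = 0.001, connectivity = 18,
                            min_cluster_size = 5, max_rois = 5,
                            alpha_fd = 0.05, fd_min_group = 10,
                            bonferroni_m = NULL, include_lag0 = FALSE,
                            ttest_variant = "pooled", seed = 1) {
  roles <- vapply(datasets, `[[`, character(1), "role")
  if (sum(roles == "discovery") != 1)
    stop("config must contain exactly one discovery dataset, found ",
         sum(roles == "discovery"))
  nms <- vapply(datasets, `[[`, character(1), "name")
  if (anyDuplicated(nms)) stop("dataset names must be unique")
  structure(list(datasets = datasets, p_thresh = p_thresh,
                 connectivity = connectivity,
                 min_cluster_size = min_cluster_size, max_rois = max_rois,
                 alpha_fd = alpha_fd, fd_min_group = fd_min_group,
                 bonferroni_m = bonferroni_m, include_lag0 = include_lag0,
                 ttest_variant = ttest_variant, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from JSON
#'
#' Flat JSON with a `datasets` array (fields as in [pipeline_dataset()],
#' plus an optional `synthetic` block of [cohort_spec()] arguments) and
#' top-level analysis settings.
#'
#' @param path JSON file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  datasets <- lapply(cfg$datasets, function(d) {
    spec <- NULL
    if (!is.null(d$synthetic)) {
      args <- d$synthetic
      if (!is.null(args$grid_shape))
        args$grid_shape <- as.integer(unlist(args$grid_shape))
      spec <- do.call(cohort_spec, args)
    }
    pipeline_dataset(name = d$name, role = d$role, synthetic_spec = spec,
                     volumes = unlist(d$volumes), mask = d$mask,
                     records = d$records, motion = unlist(d$motion),
                     tr = d$tr,
                     session_bounds = as.integer(unlist(d$session_bounds)))
  })
  keep <- intersect(names(cfg), setdiff(names(formals(pipeline_config)),
                                        "datasets"))
  do.call(pipeline_config, c(list(datasets = datasets), cfg[keep]))
}

# Materialise one dataset: volumes in memory, records with mean_fd, grid
# metadata. Synthetic datasets are generated from their spec.
.load_dataset <- function(ds, default_seed) {
  if (!is.null(ds$synthetic_spec)) {
    spec <- ds$synthetic_spec
    if (is.null(spec$seed)) spec$seed <- default_seed
    cohort <- simulate_cohort(spec)
    return(list(name = ds$name, role = ds$role,
                volumes = cohort$volumes, mask = spec$mask,
                records = cohort$records, tr = spec$tr,
                session_bounds = rep(spec$n_frames, spec$n_sessions),
                affine = diag(c(3, 3, 3, 1)), truth = cohort$truth))
  }
  records <- read_records(ds$records)
  if (length(ds$volumes) != nrow(records))
    stop("dataset '", ds$name, "': ", length(ds$volumes),
         " volumes for ", nrow(records), " records")
  maskimg <- read_nifti(ds$mask)
  mask <- array(maskimg$data != 0, dim = dim(maskimg$data))
  vols <- lapply(ds$volumes, function(p) read_nifti(p)$data)
  tr <- ds$tr
  if (is.null(tr)) tr <- read_nifti(ds$volumes[[1]])$tr
  if (is.null(ds$session_bounds)) ds$session_bounds <- dim(vols[[1]])[4]
  if (is.null(records$mean_fd) && !is.null(ds$motion)) {
    records$mean_fd <- vapply(ds$motion, function(p)
      mean(framewise_displacement(read_motion_params(p))), numeric(1))
  }
  list(name = ds$name, role = ds$role, volumes = vols, mask = mask,
       records = records, tr = tr, session_bounds = ds$session_bounds,
       affine = maskimg$affine, truth = NULL)
}

.stage <- function(stage, dataset, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", stage, "' failed on dataset '", dataset,
         "': ", conditionMessage(e), call. = FALSE))
}

#' Demographic balance table
#'
#' Welch t on age and Yates chi-squared on sex between HC and SZ. A
#' single-sex dataset skips the sex test with a note instead of failing.
#'
#' @param records Subject records data frame (columns `group`, `sex`,
#'   `age`).
#' @return Data frame with one row per test: variable, statistic, df, p,
#'   note.
#' @export
demographic_balance <- function(records) {
  hc <- records[records$group == "HC", ]
  sz <- records[records$group == "SZ", ]
  w <- welch_t(hc$age, sz$age)
  out <- data.frame(variable = "age", statistic = w$t, df = w$df, p = w$p,
                    note = "Welch t", stringsAsFactors = FALSE)
  if (length(unique(records$sex)) < 2) {
    out <- rbind(out, data.frame(variable = "sex", statistic = NA_real_,
                                 df = NA_real_, p = NA_real_,
                                 note = "skipped: single-sex dataset"))
  } else {
    tab <- table(factor(records$group, c("HC", "SZ")),
                 factor(records$sex, c("M", "F")))
    cs <- chi2_2x2(tab)
    out <- rbind(out, data.frame(variable = "sex", statistic = cs$chi2,
                                 df = 1, p = cs$p,
                                 note = "Yates chi-squared"))
  }
  out
}

# ROI-level Welch/g/Bonferroni table for one dataset over a set of ROIs.
.roi_comparisons <- function(roi_values, records, m) {
  do.call(rbind, lapply(names(roi_values), function(rn) {
    v <- roi_values[[rn]]
    a <- v[records$group == "HC"]
    b <- v[records$group == "SZ"]
    cbind(roi = rn, n_hc = length(a), n_sz = length(b),
          mean_hc = mean(a), sd_hc = stats::sd(a),
          mean_sz = mean(b), sd_sz = stats::sd(b),
          compare_groups(a, b, m = m))
  }))
}

#' Run the full pipeline
#'
#' Stages, in order: (1) per-subject INT maps for every dataset; (2)
#' voxel-wise t-map and cluster extraction on the discovery dataset,
#' clusters frozen as ROIs; (3) ROI mean extraction for every subject of
#' every dataset; (4) pre-matching ROI-level group comparisons on the
#' replication datasets (the discovery dataset is excluded to avoid
#' double-dipping, and its table is labelled accordingly); (5) FD matching
#' per dataset and post-matching reanalysis on kept subjects of all
#' datasets, discovery included; (6) FD-INT correlations per group, pre and
#' post matching; (7) symptom correlations (patients), sex ANCOVAs and
#' medication-dose main effects. Results are written under `out_dir` as
#' TSV/JSON plus NIfTI statistic maps, with a provenance block (config
#' hash, seed, package version) and an exclusions log.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory.
#' @param force Recompute even if a report with the same config hash exists
#'   (default `TRUE`; set `FALSE` to reuse a cached run).
#' @return A list of class `study_report` (also serialised to
#'   `report.json`).
#' @export
run_pipeline <- function(config, out_dir, force = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg_json <- file.path(out_dir, "config.json")
  jsonlite::write_json(.config_digest_payload(config), cfg_json,
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  cfg_hash <- unname(tools::md5sum(cfg_json))
  report_path <- file.path(out_dir, "report.json")
  if (!force && file.exists(report_path)) {
    old <- jsonlite::read_json(report_path)
    if (identical(old$provenance$config_hash, cfg_hash)) {
      message("reusing cached pipeline run (config hash ", cfg_hash, ")")
      return(invisible(structure(old, class = "study_report")))
    }
  }
  exclusions <- character(0)
  log_excl <- function(...) exclusions <<- c(exclusions, paste0(...))

  datasets <- lapply(config$datasets, function(ds)
    .stage("load", ds$name, .load_dataset(ds, config$seed)))
  names(datasets) <- vapply(datasets, `[[`, character(1), "name")
  disc <- names(datasets)[vapply(datasets, function(d)
    d$role == "discovery", logical(1))]

  # stage 1: INT maps
  for (nm in names(datasets)) {
    d <- datasets[[nm]]
    datasets[[nm]]$int_maps <- .stage("int_maps", nm, lapply(
      seq_along(d$volumes), function(s) {
        m <- suppressMessages(int_map(d$volumes[[s]], d$mask, d$tr,
                                      d$session_bounds, affine = d$affine))
        if (m$n_degenerate > 0)
          log_excl(nm, "/", d$records$subject_id[s], ": ",
                   m$n_degenerate, " degenerate voxel(s)")
        m
      }))
    datasets[[nm]]$volumes <- NULL   # free the 4D data
  }

  # stage 2: discovery t-map and frozen ROIs
  dd <- datasets[[disc]]
  stat <- .stage("voxelwise", disc, voxelwise_ttest(
    dd$int_maps[dd$records$group == "HC"],
    dd$int_maps[dd$records$group == "SZ"],
    variant = config$ttest_variant))
  clus <- .stage("clusters", disc, extract_clusters(
    stat, p_thresh = config$p_thresh, direction = "a_gt_b",
    connectivity = config$connectivity,
    min_cluster_size = config$min_cluster_size))
  rois <- clus$rois[seq_len(min(length(clus$rois), config$max_rois))]
  m_bonf <- if (is.null(config$bonferroni_m)) max(1, length(rois))
            else config$bonferroni_m

  write_nifti(ifelse(is.na(stat$t), 0, stat$t),
              file.path(out_dir, "discovery_tmap.nii.gz"),
              affine = dd$affine)
  write_nifti(ifelse(is.na(stat$p), 1, stat$p),
              file.path(out_dir, "discovery_pmap.nii.gz"),
              affine = dd$affine)
  write_nifti(clus$labels, file.path(out_dir, "discovery_roi_labels.nii.gz"),
              affine = dd$affine, datatype = 4L)
  utils::write.table(clus$clusters,
                     file.path(out_dir, "discovery_clusters.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  # stage 3: ROI means everywhere
  for (nm in names(datasets)) {
    d <- datasets[[nm]]
    datasets[[nm]]$roi_values <- .stage("roi_means", nm, {
      rv <- lapply(rois, function(r) vapply(d$int_maps, roi_mean, numeric(1),
                                            roi = r))
      names(rv) <- vapply(rois, `[[`, character(1), "name")
      rv
    })
    tab <- cbind(subject_id = d$records$subject_id,
                 as.data.frame(datasets[[nm]]$roi_values))
    utils::write.table(tab,
                       file.path(out_dir, paste0(nm, "_roi_int.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  # stage 4: pre-matching ROI comparisons (discovery excluded)
  pre <- list()
  for (nm in names(datasets)) {
    if (nm == disc) next
    pre[[nm]] <- .stage("roi_comparisons_pre", nm, cbind(
      dataset = nm, .roi_comparisons(datasets[[nm]]$roi_values,
                                     datasets[[nm]]$records, m_bonf)))
  }
  log_excl(disc, ": excluded from pre-matching ROI comparisons ",
           "(double-dipping guard: ROIs were discovered on this dataset)")

  # stage 5: FD matching and post-matching reanalysis (all datasets)
  fd_results <- list()
  post <- list()
  for (nm in names(datasets)) {
    d <- datasets[[nm]]
    rec <- d$records
    fdres <- .stage("fd_match", nm, fd_match(
      rec[rec$group == "HC", c("subject_id", "mean_fd")],
      rec[rec$group == "SZ", c("subject_id", "mean_fd")],
      alpha = config$alpha_fd, min_group = config$fd_min_group))
    fd_results[[nm]] <- fdres
    for (id in c(fdres$removed_hc, fdres$removed_sz))
      log_excl(nm, "/", id, ": removed by FD matching (mean FD ",
               signif(rec$mean_fd[rec$subject_id == id], 3), " mm)")
    keep <- rec$subject_id %in% c(fdres$kept_hc, fdres$kept_sz)
    datasets[[nm]]$kept <- keep
    rv_kept <- lapply(d$roi_values, function(v) v[keep])
    post[[nm]] <- .stage("roi_comparisons_post", nm, cbind(
      dataset = nm, .roi_comparisons(rv_kept, rec[keep, ], m_bonf)))
  }

  # stage 6: FD-INT correlations, pre and post matching
  fd_int <- do.call(rbind, lapply(names(datasets), function(nm) {
    d <- datasets[[nm]]
    do.call(rbind, lapply(names(d$roi_values), function(rn) {
      do.call(rbind, lapply(c("HC", "SZ"), function(g) {
        do.call(rbind, lapply(c("pre", "post"), function(stage) {
          sel <- d$records$group == g
          if (stage == "post") sel <- sel & d$kept
          ct <- pearson_r(d$records$mean_fd[sel], d$roi_values[[rn]][sel])
          data.frame(dataset = nm, roi = rn, group = g, stage = stage,
                     n = ct$n, r = ct$r, p = ct$p,
                     p_bonf = bonferroni(ct$p, m_bonf))
        }))
      }))
    }))
  }))

  # stage 7: symptom correlations, sex ANCOVA, medication main effect
  known <- c("subject_id", "group", "sex", "age", "mean_fd", "cpz")
  symptom_tab <- NULL
  ancova_tab <- NULL
  cpz_tab <- NULL
  balance <- do.call(rbind, lapply(names(datasets), function(nm)
    cbind(dataset = nm, demographic_balance(datasets[[nm]]$records))))
  for (nm in names(datasets)) {
    d <- datasets[[nm]]
    symptoms <- setdiff(names(d$records), known)
    sz <- d$records$group == "SZ"
    for (rn in names(d$roi_values)) {
      for (sc in symptoms) {
        sv <- d$records[[sc]][sz]
        if (sum(is.finite(sv)) < 3) next
        ct <- pearson_r(sv, d$roi_values[[rn]][sz])
        symptom_tab <- rbind(symptom_tab, data.frame(
          dataset = nm, roi = rn, symptom = sc, n = ct$n, r = ct$r,
          p = ct$p, p_bonf = bonferroni(ct$p, m_bonf)))
      }
      if (length(unique(d$records$sex)) > 1) {
        me <- linear_main_effects(
          d$roi_values[[rn]],
          d$records[, c("group", "sex"), drop = FALSE])
        ancova_tab <- rbind(ancova_tab,
                            cbind(dataset = nm, roi = rn, me))
      } else {
        log_excl(nm, ": sex ANCOVA skipped (single-sex dataset)")
      }
      if (any(is.finite(d$records$cpz[sz]))) {
        me <- linear_main_effects(
          d$roi_values[[rn]][sz],
          data.frame(cpz = d$records$cpz[sz]))
        cpz_tab <- rbind(cpz_tab, cbind(dataset = nm, roi = rn, me))
      }
    }
    n_miss <- sum(vapply(symptoms, function(sc)
      sum(!is.finite(d$records[[sc]][sz])), numeric(1)))
    if (n_miss > 0)
      log_excl(nm, ": ", n_miss,
               " missing symptom score(s) dropped pairwise")
  }

  wt <- function(x, f) if (!is.null(x))
    utils::write.table(x, file.path(out_dir, f), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  pre_tab <- do.call(rbind, pre)
  post_tab <- do.call(rbind, post)
  wt(pre_tab, "roi_comparisons_pre_matching.tsv")
  wt(post_tab, "roi_comparisons_post_matching.tsv")
  wt(fd_int, "fd_int_correlations.tsv")
  wt(symptom_tab, "symptom_correlations.tsv")
  wt(ancova_tab, "sex_ancova.tsv")
  wt(cpz_tab, "cpz_main_effects.tsv")
  wt(balance, "demographic_balance.tsv")
  writeLines(exclusions, file.path(out_dir, "exclusions.log"))
  jsonlite::write_json(
    lapply(fd_results, unclass),
    file.path(out_dir, "fd_match.json"), auto_unbox = TRUE, pretty = TRUE,
    digits = NA)

  report <- structure(list(
    clusters = clus$clusters, rois = rois,
    comparisons_pre = pre_tab, comparisons_post = post_tab,
    fd_match = fd_results, fd_int_correlations = fd_int,
    symptom_correlations = symptom_tab, sex_ancova = ancova_tab,
    cpz_main_effects = cpz_tab, balance = balance,
    exclusions = exclusions,
    truth = lapply(datasets, `[[`, "truth"),
    provenance = list(config_hash = cfg_hash, seed = config$seed,
                      package_version =
                        as.character(utils::packageVersion("intpipe")),
                      r_version = as.character(getRversion()))),
    class = "study_report")
  jsonlite::write_json(
    list(provenance = report$provenance,
         n_clusters = nrow(clus$clusters),
         rois = vapply(rois, `[[`, character(1), "name"),
         exclusions = exclusions),
    report_path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(report)
}

# Stable, serialisable view of the config for hashing (drops in-memory
# arrays but keeps everything that determines the run).
.config_digest_payload <- function(config) {
  ds <- lapply(config$datasets, function(d) {
    s <- d$synthetic_spec
    list(name = d$name, role = d$role,
         volumes = d$volumes, mask = d$mask, records = d$records,
         motion = d$motion, tr = d$tr, session_bounds = d$session_bounds,
         synthetic = if (is.null(s)) NULL else {
           s$mask <- sum(s$mask)   # summarise the array
           pr <- lapply(s$planted_regions, function(r)
             list(n = length(r$voxels), first = r$voxels[1],
                  phi_control = r$phi_control,
                  phi_patient = r$phi_patient))
           s$planted_regions <- pr
           unclass(s)
         })
  })
  c(list(datasets = ds),
    unclass(config)[setdiff(names(unclass(config)), "datasets")])
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("<study_report> %d discovery cluster(s), %d ROI(s)\n",
              nrow(x$clusters), length(x$rois)))
  invisible(x)
}
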