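# One-call orchestration: simulate -> disconnectome -> PLS -> clusters ->
# battery correlation -> cohort stats, with per-stage content-hash caching
# and a machine-readable JSON report. Stage inputs and outputs are ordinary
# files, so any stage can be re-run or inspected on its own.

#' Build a pipeline run configuration
#'
#' All analysis parameters and seeds in one list; the resolved configuration
#' is echoed into the run report so no default is silent.
#'
#' @param seed master seed; every stochastic component derives its own
#'   sub-seed from it.
#' @param n_subjects cohort size (default 102).
#' @param n_perm,n_boot PLS resample counts (default 1000 each).
#' @param threshold cluster-forming pseudo-z threshold (default 3, strict).
#' @param connectivity cluster connectivity: 6, 18 or 26 (default 26).
#' @param cutoff cognitive-impairment cutoff (default 26).
#' @param min_size_vox minimum cluster size (default 1).
#' @param step streamline resampling step in mm (default: half voxel edge).
#' @param behavior_columns behavioral variables entering the PLS, in
#'   contrast order.
#' @param moca_contrast index of the cognition contrast among the columns.
#' @param cluster_tail which bootstrap-ratio tail defines the reported
#'   clusters ("negative": disconnection associated with lower scores).
#' @param spec,eff phantom and effect specifications for simulation.
#' @param on_target_fraction,radius_range lesion-placement parameters.
#' @return List of class \code{run_config}.
#' @export
run_config <- function(seed = 1, n_subjects = 102, n_perm = 1000,
                       n_boot = 1000, threshold = 3, connectivity = 26,
                       cutoff = 26, min_size_vox = 1, step = NULL,
                       behavior_columns = c("female", "age", "moca"),
                       moca_contrast = 3, cluster_tail = "negative",
                       spec = phantom_spec(), eff = effect_spec(),
                       on_target_fraction = 0.35, radius_range = c(2, 10)) {
  structure(list(seed = seed, n_subjects = n_subjects, n_perm = n_perm,
                 n_boot = n_boot, threshold = threshold,
                 connectivity = connectivity, cutoff = cutoff,
                 min_size_vox = min_size_vox, step = step,
                 behavior_columns = behavior_columns,
                 moca_contrast = moca_contrast, cluster_tail = cluster_tail,
                 spec = spec, eff = eff,
                 on_target_fraction = on_target_fraction,
                 radius_range = radius_range),
            class = "run_config")
}

md5_string <- function(s) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(s, f)
  unname(tools::md5sum(f))
}

hash_files <- function(paths) paste(unname(tools::md5sum(paths)),
                                    collapse = ",")

# TRUE if the stage's recorded input hash matches and all outputs exist
stage_cached <- function(out_dir, name, hash, outputs) {
  f <- file.path(out_dir, ".cache", paste0(name, ".hash"))
  file.exists(f) && identical(readLines(f, warn = FALSE)[1], hash) &&
    all(file.exists(outputs))
}

stage_record <- function(out_dir, name, hash) {
  d <- file.path(out_dir, ".cache")
  dir.create(d, showWarnings = FALSE, recursive = TRUE)
  writeLines(hash, file.path(d, paste0(name, ".hash")))
}

stage_log <- function(name, cached, t0, inputs_hash) {
  message(sprintf("[%s] %s (%.1f s, inputs %s)", name,
                  if (cached) "cached" else "done",
                  as.numeric(Sys.time()) - t0, substr(inputs_hash, 1, 8)))
}

serialize_config <- function(cfg) {
  paste(utils::capture.output(utils::str(cfg, digits.d = 15)), collapse = "\n")
}

#' Run the full pipeline
#'
#' Executes simulate, disconnectome, pls, clusters, correlate and stats in
#' order under \code{out_dir}, skipping stages whose inputs (content hash)
#' are unchanged from a previous run, and writes \code{report.json}
#' aggregating the PLS summary, cluster table, battery correlations, cohort
#' statistics and, for simulated cohorts, recovery diagnostics against the
#' generator's ground truth. The report contains no paths or timestamps, so
#' identical configurations yield byte-identical reports.
#'
#' @param config a \code{run_config}.
#' @param out_dir output directory for all stage products.
#' @param force re-run all stages ignoring the cache.
#' @return The report, invisibly (also written to
#'   \code{file.path(out_dir, "report.json")}).
#' @export
run_all <- function(config = run_config(), out_dir, force = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg_str <- serialize_config(config)

  ## stage: simulate -----------------------------------------------------
  t0 <- as.numeric(Sys.time())
  cohort_dir <- file.path(out_dir, "cohort")
  sim_hash <- md5_string(paste("simulate", cfg_str))
  sim_outputs <- file.path(cohort_dir, "manifest.json")
  cached <- !force && stage_cached(out_dir, "simulate", sim_hash, sim_outputs)
  if (!cached) {
    sim <- tryCatch(
      simulate_cohort(seed = config$seed, spec = config$spec,
                      eff = config$eff, n_subjects = config$n_subjects,
                      on_target_fraction = config$on_target_fraction,
                      radius_range = config$radius_range,
                      step = config$step),
      error = function(e) stop("stage simulate: ", conditionMessage(e)))
    write_cohort(cohort_dir, sim)
    stage_record(out_dir, "simulate", sim_hash)
  }
  stage_log("simulate", cached, t0, sim_hash)
  behavior <- utils::read.table(file.path(cohort_dir, "behavior.tsv"),
                                sep = "\t", header = TRUE,
                                stringsAsFactors = FALSE)
  fp_vol <- read_volume(file.path(cohort_dir, "target_footprint.nii"))
  grid <- image_volume(array(0, dim(fp_vol$data)), fp_vol$affine)
  step <- config$step %||% default_step(grid)

  ## stage: disconnectome ------------------------------------------------
  t0 <- as.numeric(Sys.time())
  maps_dir <- file.path(out_dir, "maps")
  dir.create(maps_dir, showWarnings = FALSE)
  lesion_files <- sort(list.files(file.path(cohort_dir, "lesions"),
                                  full.names = TRUE))
  control_files <- sort(list.files(file.path(cohort_dir, "controls"),
                                   full.names = TRUE))
  disc_hash <- md5_string(paste("disconnectome", step,
                                hash_files(c(lesion_files, control_files))))
  subject_ids <- sub("_lesion\\.nii$", "", basename(lesion_files))
  map_files <- file.path(maps_dir, paste0(subject_ids, "_disconnectome.nii"))
  cached <- !force && stage_cached(out_dir, "disconnectome", disc_hash,
                                   map_files)
  if (!cached) {
    read_errors <- character()
    lesions <- vector("list", length(lesion_files))
    for (i in seq_along(lesion_files)) {
      res <- tryCatch(lesion_mask(read_volume(lesion_files[i]),
                                  subject_ids[i]),
                      error = function(e) e)
      if (inherits(res, "error"))
        read_errors[subject_ids[i]] <- conditionMessage(res)
      else lesions[[i]] <- res
    }
    if (length(read_errors))
      stop("stage disconnectome failed for subject(s): ",
           paste(names(read_errors), collapse = ", "))
    controls <- lapply(control_files, read_tractogram)
    batch <- suppressWarnings(
      disconnectome_batch(lesions, controls, grid, step))
    if (length(batch$errors))
      stop("stage disconnectome failed for subject(s): ",
           paste(names(batch$errors), collapse = ", "))
    for (i in seq_along(batch$maps))
      write_volume(batch$maps[[i]]$volume, map_files[i], datatype = "float")
    stage_record(out_dir, "disconnectome", disc_hash)
  }
  stage_log("disconnectome", cached, t0, disc_hash)

  ## stage: pls ----------------------------------------------------------
  t0 <- as.numeric(Sys.time())
  pls_dir <- file.path(out_dir, "pls")
  dir.create(pls_dir, showWarnings = FALSE)
  n_controls <- length(control_files)
  pls_hash <- md5_string(paste("pls", hash_files(map_files),
                               hash_files(file.path(cohort_dir,
                                                    "behavior.tsv")),
                               paste(config$behavior_columns, collapse = ","),
                               config$n_perm, config$n_boot, config$seed))
  cols <- config$behavior_columns
  pls_outputs <- c(file.path(pls_dir, paste0("bsr_", cols, ".nii")),
                   file.path(pls_dir, paste0("salience_", cols, ".nii")),
                   file.path(pls_dir, "brain_scores.tsv"),
                   file.path(pls_dir, "pls_summary.json"))
  cached <- !force && stage_cached(out_dir, "pls", pls_hash, pls_outputs)
  if (!cached) {
    maps <- lapply(seq_along(map_files), function(i) {
      vol <- read_volume(map_files[i])
      new_disconnectome_map(vol, subject_ids[i], n_controls)
    })
    pls <- tryCatch(
      pls_brain_behavior(maps, behavior, columns = cols,
                         n_perm = config$n_perm, n_boot = config$n_boot,
                         seed = config$seed),
      error = function(e) stop("stage pls: ", conditionMessage(e)))
    for (k in seq_along(cols)) {
      write_volume(salience_to_volume(pls$bsr[, k], pls$mask_index, grid),
                   file.path(pls_dir, paste0("bsr_", cols[k], ".nii")),
                   datatype = "float")
      write_volume(salience_to_volume(pls$salience[, k], pls$mask_index,
                                      grid),
                   file.path(pls_dir, paste0("salience_", cols[k], ".nii")),
                   datatype = "float")
    }
    scores <- data.frame(subject_id = behavior$subject_id[pls$subjects_used],
                         pls$brain_scores)
    names(scores)[-1] <- paste0("score_", cols)
    utils::write.table(scores, file.path(pls_dir, "brain_scores.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
      list(columns = cols, strength = pls$strength, perm_p = pls$perm_p,
           n = pls$n, n_perm = pls$n_perm, n_boot = pls$n_boot,
           n_redraws = pls$n_redraws, seed = pls$seed,
           mask_size = length(pls$mask_index)),
      file.path(pls_dir, "pls_summary.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
    stage_record(out_dir, "pls", pls_hash)
  }
  stage_log("pls", cached, t0, pls_hash)
  pls_summary <- jsonlite::read_json(file.path(pls_dir, "pls_summary.json"),
                                     simplifyVector = TRUE)

  ## stage: clusters -----------------------------------------------------
  t0 <- as.numeric(Sys.time())
  clus_dir <- file.path(out_dir, "clusters")
  dir.create(clus_dir, showWarnings = FALSE)
  moca_col <- cols[config$moca_contrast]
  bsr_file <- file.path(pls_dir, paste0("bsr_", moca_col, ".nii"))
  clus_hash <- md5_string(paste("clusters", hash_files(bsr_file),
                                config$threshold, config$connectivity,
                                config$min_size_vox, config$cluster_tail))
  clus_outputs <- c(file.path(clus_dir, "clusters.tsv"),
                    file.path(clus_dir, "clusters_other_tail.tsv"),
                    file.path(clus_dir, "cluster_labels.nii"))
  cached <- !force && stage_cached(out_dir, "clusters", clus_hash,
                                   clus_outputs)
  if (!cached) {
    bsr_vol <- read_volume(bsr_file)
    other <- if (config$cluster_tail == "negative") "positive" else "negative"
    main <- extract_clusters(bsr_vol, config$threshold, config$connectivity,
                             config$min_size_vox, tail = config$cluster_tail)
    alt <- extract_clusters(bsr_vol, config$threshold, config$connectivity,
                            config$min_size_vox, tail = other)
    utils::write.table(main$table, file.path(clus_dir, "clusters.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(alt$table,
                       file.path(clus_dir, "clusters_other_tail.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_volume(main$labels, file.path(clus_dir, "cluster_labels.nii"),
                 datatype = "float")
    stage_record(out_dir, "clusters", clus_hash)
  }
  stage_log("clusters", cached, t0, clus_hash)

  ## stage: correlate ----------------------------------------------------
  t0 <- as.numeric(Sys.time())
  corr_file <- file.path(clus_dir, "battery_correlations.tsv")
  values_file <- file.path(clus_dir, "cluster_values.tsv")
  corr_hash <- md5_string(paste("correlate", clus_hash,
                                hash_files(map_files),
                                hash_files(file.path(pls_dir,
                                                     "brain_scores.tsv"))))
  cached <- !force && stage_cached(out_dir, "correlate", corr_hash,
                                   c(corr_file, values_file))
  battery_cols <- names(config$eff$battery_loadings)
  battery_cols <- intersect(battery_cols, names(behavior))
  cluster_tab <- utils::read.table(file.path(clus_dir, "clusters.tsv"),
                                   sep = "\t", header = TRUE)
  scores <- utils::read.table(file.path(pls_dir, "brain_scores.tsv"),
                              sep = "\t", header = TRUE)
  if (!cached) {
    if (nrow(cluster_tab) > 0 && length(battery_cols) > 0) {
      labels <- read_volume(file.path(clus_dir, "cluster_labels.nii"))
      labels$data <- array(as.integer(round(labels$data)),
                           dim(labels$data))
      maps <- lapply(seq_along(map_files), function(i) {
        vol <- read_volume(map_files[i])
        new_disconnectome_map(vol, subject_ids[i], n_controls)
      })
      cv <- cluster_disconnectivity(maps, labels)
      extra <- data.frame(
        moca = behavior$moca,
        brain_score = scores[[paste0("score_", moca_col)]][
          match(behavior$subject_id, scores$subject_id)])
      cw <- correlate_with_battery(cv, behavior[, battery_cols,
                                                drop = FALSE], extra)
      long <- expand.grid(predictor = rownames(cw$r),
                          measure = colnames(cw$r),
                          stringsAsFactors = FALSE)
      long$r <- as.vector(cw$r)
      long$n <- as.vector(cw$n)
      long$reason <- as.vector(cw$reason)
      utils::write.table(long, corr_file, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      vals <- data.frame(subject_id = subject_ids, cv)
      utils::write.table(vals, values_file, sep = "\t", quote = FALSE,
                         row.names = FALSE)
    } else {
      utils::write.table(
        data.frame(predictor = character(), measure = character(),
                   r = numeric(), n = integer(), reason = character()),
        corr_file, sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(data.frame(subject_id = subject_ids), values_file,
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    stage_record(out_dir, "correlate", corr_hash)
  }
  stage_log("correlate", cached, t0, corr_hash)
  correlations <- utils::read.table(corr_file, sep = "\t", header = TRUE,
                                    stringsAsFactors = FALSE)
  if (nrow(correlations) && "reason" %in% names(correlations))
    correlations$reason[is.na(correlations$reason)] <- ""

  ## stage: stats --------------------------------------------------------
  t0 <- as.numeric(Sys.time())
  stats_file <- file.path(out_dir, "stats_report.json")
  stats_hash <- md5_string(paste("stats",
                                 hash_files(file.path(cohort_dir,
                                                      "behavior.tsv")),
                                 hash_files(file.path(pls_dir,
                                                      "brain_scores.tsv")),
                                 config$cutoff))
  cached <- !force && stage_cached(out_dir, "stats", stats_hash, stats_file)
  if (!cached) {
    tab <- behavior
    tab$brain_score <- scores[[paste0("score_", moca_col)]][
      match(tab$subject_id, scores$subject_id)]
    group_fit <- fit_group_model(tab)
    load_fit <- fit_lesionload_model(tab)
    sens <- outlier_sensitivity(tab)
    bs <- brainscore_lesion_assoc(tab)
    imp <- impairment_rate(tab, config$cutoff)
    fit_json <- function(f) list(
      coefficients = as.list(f$coefficients), t = as.list(f$t),
      p = as.list(f$p), F = f$F, F_p = f$F_p, r_squared = f$r_squared,
      df_residual = f$df_residual, n = f$n, degenerate = f$degenerate)
    jsonlite::write_json(
      list(group_model = fit_json(group_fit),
           lesionload_model = fit_json(load_fit),
           outlier_sensitivity = list(
             flagged = as.list(sens$flagged),
             with = fit_json(sens$with), without = fit_json(sens$without)),
           brainscore_lesion = list(
             with = fit_json(bs$with), without = fit_json(bs$without)),
           impairment = imp),
      stats_file, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    stage_record(out_dir, "stats", stats_hash)
  }
  stage_log("stats", cached, t0, stats_hash)
  stats_report <- jsonlite::read_json(stats_file, simplifyVector = TRUE)

  ## report --------------------------------------------------------------
  recovery <- NULL
  gt_file <- file.path(cohort_dir, "ground_truth.json")
  if (file.exists(gt_file)) {
    fp <- read_volume(file.path(cohort_dir, "target_footprint.nii"))
    bsr_vol <- read_volume(bsr_file)
    # recovered footprint: the suprathreshold voxels of the tail carrying
    # the planted effect (negative on the correlation scale by default)
    supra <- if (config$cluster_tail == "negative")
      bsr_vol$data < -config$threshold else bsr_vol$data > config$threshold
    truthv <- fp$data != 0
    inter <- sum(supra & truthv)
    dice <- if (sum(supra) + sum(truthv) > 0)
      2 * inter / (sum(supra) + sum(truthv)) else 0
    cr <- correlations[correlations$reason == "" &
                         grepl("^cluster_", correlations$predictor), ]
    recovery <- list(
      dice_bsr_vs_footprint = dice,
      n_suprathreshold_voxels = sum(supra),
      footprint_voxels = sum(truthv),
      n_battery_correlations = nrow(cr),
      n_negative_battery_correlations = sum(cr$r < 0))
  }
  report <- list(
    package_version = as.character(utils::packageVersion("disconnectr")),
    config = list(seed = config$seed, n_subjects = config$n_subjects,
                  n_perm = config$n_perm, n_boot = config$n_boot,
                  threshold = config$threshold,
                  connectivity = config$connectivity,
                  cutoff = config$cutoff,
                  min_size_vox = config$min_size_vox,
                  step = step, behavior_columns = config$behavior_columns,
                  moca_contrast = config$moca_contrast,
                  cluster_tail = config$cluster_tail,
                  on_target_fraction = config$on_target_fraction,
                  radius_range = config$radius_range),
    pls = pls_summary,
    clusters = cluster_tab,
    correlations = correlations,
    cohort_stats = stats_report,
    recovery = recovery)
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}
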