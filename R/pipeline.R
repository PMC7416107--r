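#' Run the full analysis pipeline on one or two simulated datasets
#'
#' Chains the stages simulate-output loading, GLM beta estimation, ROI
#' decoding, permutation/bootstrap inference, group statistics and (optional)
#' searchlight mapping, writing tables and a provenance log under
#' `config$out_dir`. With two dataset directories (one per group) the
#' between-group statistics (Mann-Whitney, mixed ANOVA, non-parametric
#' interaction, group-difference searchlight) are included.
#'
#' Each stage writes its outputs before the next starts and a progress marker
#' (`pipeline_state.json`) records the last completed stage, so a failed run
#' can be diagnosed and resumed from its inputs.
#'
#' @param config A [pipeline_config()]; `data_dir` may be a character vector
#'   of one or two dataset directories produced by [simulate_cohort()].
#' @return Invisibly, a list with the collected result tables.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dirs <- config$data_dir
  stopifnot(length(dirs) >= 1, length(dirs) <= 2)
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  write_config(config, file.path(out, "config.yaml"))
  cfg_hash <- unname(tools::md5sum(file.path(out, "config.yaml")))
  state <- function(stage)
    jsonlite::write_json(list(last_completed_stage = stage,
                              config_hash = cfg_hash, seed = config$seed),
                         file.path(out, "pipeline_state.json"),
                         auto_unbox = TRUE)

  groups <- lapply(dirs, load_cohort_data, config = config)
  state("load")

  # --- decode + subject permutation nulls ---------------------------------
  fold_rows <- list(); acc_rows <- list(); nulls <- list()
  for (gi in seq_along(groups)) {
    gd <- groups[[gi]]
    for (si in seq_along(gd$subjects)) {
      sub <- gd$subjects[[si]]
      sid <- paste0(gd$name, "_", sub$id)
      betas <- lapply(seq_along(sub$bold), function(r) {
        des <- build_design(sub$schedules[[r]],
                            highpass_cutoff_s = config$highpass_cutoff_s)
        estimate_block_betas(sub$bold[[r]], des, mask = gd$atlas$labels != 0)
      })
      dec <- decode_all_rois(betas, gd$atlas, rois = config$rois,
                             cost = config$svm_cost, seed = config$seed,
                             subject = sid)
      acc_rows[[sid]] <- cbind(group = gd$name, dec$table)
      fold_rows[[sid]] <- do.call(rbind, lapply(config$rois, function(rg) {
        fp <- dec$results[[rg]]$fold_pair_accuracy
        data.frame(group = gd$name, subject = sid, roi = rg,
                   fold = rep(seq_len(nrow(fp)), ncol(fp)),
                   pair = rep(colnames(fp), each = nrow(fp)),
                   accuracy = as.vector(fp))
      }))
      labels <- lapply(betas, function(b) b$condition)
      sched <- perm_schedule(labels, config$n_perm,
                             seed = config$seed + 131L * si + 7919L * gi)
      nulls[[sid]] <- lapply(config$rois, function(rg)
        subject_null(betas, roi_mask(gd$atlas, rg), schedule = sched,
                     cost = config$svm_cost, subject = sid, roi = rg))
      names(nulls[[sid]]) <- config$rois
      groups[[gi]]$subjects[[si]]$betas <- betas
    }
  }
  acc_table <- do.call(rbind, acc_rows); rownames(acc_table) <- NULL
  utils::write.csv(acc_table, file.path(out, "decoding_accuracy.csv"),
                   row.names = FALSE)
  utils::write.csv(do.call(rbind, fold_rows),
                   file.path(out, "decoding_fold_pair.csv"), row.names = FALSE)
  null_rows <- do.call(rbind, lapply(names(nulls), function(sid)
    do.call(rbind, lapply(nulls[[sid]], function(nd)
      data.frame(subject = sid, roi = nd$roi, seed = nd$seed,
                 perm = seq_len(nd$n_perm), accuracy = nd$null)))))
  utils::write.csv(null_rows, file.path(out, "null_distributions.csv"),
                   row.names = FALSE)
  state("decode")

  # --- group inference -----------------------------------------------------
  infer_rows <- list()
  for (gd_i in seq_along(groups)) {
    gname <- groups[[gd_i]]$name
    sids <- grep(paste0("^", gname, "_"), names(nulls), value = TRUE)
    gres <- lapply(config$rois, function(rg)
      group_permutation_p(lapply(nulls[sids], `[[`, rg), roi = rg))
    names(gres) <- config$rois
    st_family <- intersect(c("V1", "V2", "V3"), config$rois)
    st <- if (length(st_family) > 0)
      single_threshold_correct(gres[st_family]) else NULL
    ecc_rois <- intersect(atlas_region_names()[1:9], config$rois)
    fdr <- if (length(ecc_rois) > 0)
      fdr_bh(vapply(gres[ecc_rois], function(g) g$p_uncorrected, numeric(1)),
             q = config$fdr_q) else NULL
    boot <- if ("EVC" %in% config$rois && length(sids) >= 2)
      bootstrap_vs_chance(acc_table$mean_accuracy[
        acc_table$group == gname & acc_table$roi == "EVC"],
        n_boot = config$n_boot, seed = config$seed) else NULL
    infer_rows[[gname]] <- data.frame(
      group = gname, roi = config$rois,
      mean_accuracy = vapply(gres, function(g) g$mean_real, numeric(1)),
      p_perm = vapply(gres, function(g) g$p_uncorrected, numeric(1)),
      p_single_threshold = vapply(config$rois, function(rg)
        if (!is.null(st) && rg %in% st$roi)
          st$p_corrected[st$roi == rg] else NA_real_, numeric(1)),
      p_fdr = vapply(config$rois, function(rg)
        if (!is.null(fdr) && rg %in% ecc_rois)
          fdr$adjusted[match(rg, ecc_rois)] else NA_real_, numeric(1)))
    if (!is.null(boot))
      jsonlite::write_json(
        list(group = gname, roi = "EVC", mean = boot$mean,
             ci = boot$ci, p = boot$p, n_boot = boot$n_boot),
        file.path(out, paste0("bootstrap_evc_", gname, ".json")),
        auto_unbox = TRUE, digits = NA)
  }
  inference <- do.call(rbind, infer_rows); rownames(inference) <- NULL
  utils::write.csv(inference, file.path(out, "group_inference.csv"),
                   row.names = FALSE)
  state("infer")

  # --- group statistics ----------------------------------------------------
  stats_out <- list()
  ecc_long <- ecc_accuracy_table(acc_table)
  for (gname in unique(ecc_long$group)) {
    gl <- ecc_long[ecc_long$group == gname, ]
    an <- rm_anova(gl)
    ecc_mat <- with(stats::aggregate(accuracy ~ subject + eccentricity,
                                     gl, mean),
                    tapply(accuracy, list(subject, eccentricity), mean))
    ecc_mat <- ecc_mat[, c("fovea", "periphery", "far_periphery")]
    stats_out[[gname]] <- list(
      rm_anova = lapply(an[names(an) != "ss"], unclass),
      friedman = unclass(friedman(ecc_mat)))
  }
  if (length(groups) == 2) {
    gnames <- vapply(groups, `[[`, "", "name")
    pick <- function(roi, gname)
      acc_table$mean_accuracy[acc_table$group == gname & acc_table$roi == roi]
    stats_out$between <- list(
      mann_whitney = lapply(c("EVC", "AC", "MC"), function(rg)
        unclass(mann_whitney(pick(rg, gnames[1]), pick(rg, gnames[2])))),
      mixed_anova = local({
        ma <- mixed_anova(ecc_long)
        lapply(ma[setdiff(names(ma), "ss")], unclass)
      }),
      interaction = unclass(interaction_nonparam(
        acc_table$mean_accuracy[acc_table$roi == "AC"],
        acc_table$mean_accuracy[acc_table$roi == "EVC"],
        acc_table$group[acc_table$roi == "AC"])))
  }
  jsonlite::write_json(stats_out, file.path(out, "group_stats.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  state("stats")

  # --- searchlight (optional) ---------------------------------------------
  if (isTRUE(config$searchlight)) {
    sl_maps <- list()
    for (gd in groups) {
      mask <- gd$atlas$labels != 0
      sl_maps[[gd$name]] <- lapply(gd$subjects, function(sub)
        run_searchlight(sub$betas, mask, side = config$searchlight_side,
                        cost = config$svm_cost)$accuracy)
    }
    g1 <- sl_maps[[1]]
    gv <- group_vs_chance_map(g1, voxel_p = config$searchlight_voxel_p,
                              alpha = config$alpha, seed = config$seed)
    utils::write.csv(gv$clusters, file.path(out, "searchlight_clusters.csv"),
                     row.names = FALSE)
    write_volume(ifelse(is.na(gv$t), 0, gv$t),
                 file.path(out, "searchlight_group_t.nii"))
    if (length(sl_maps) == 2) {
      gdm <- group_difference_map(sl_maps[[1]], sl_maps[[2]],
                                  voxel_p = config$searchlight_voxel_p,
                                  alpha = config$alpha, seed = config$seed)
      utils::write.csv(gdm$clusters,
                       file.path(out, "searchlight_group_diff_clusters.csv"),
                       row.names = FALSE)
    }
    state("searchlight")
  }

  # --- report --------------------------------------------------------------
  report <- list(config_hash = cfg_hash, seed = config$seed,
                 groups = lapply(groups, function(g)
                   list(name = g$name, n_subjects = length(g$subjects))),
                 inference = inference, stats = stats_out)
  jsonlite::write_json(report, file.path(out, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  state("report")
  invisible(list(accuracy = acc_table, inference = inference,
                 stats = stats_out))
}

# reshape the per-ROI accuracy table into subject x area x eccentricity rows
ecc_accuracy_table <- function(acc_table) {
  ecc <- acc_table[grepl("^V[123]_", acc_table$roi), ]
  parts <- strsplit(ecc$roi, "_")
  data.frame(group = ecc$group, subject = ecc$subject,
             area = vapply(parts, `[[`, "", 1),
             eccentricity = factor(vapply(parts, function(p)
               paste(p[-1], collapse = "_"), ""),
               levels = c("fovea", "periphery", "far_periphery")),
             accuracy = ecc$mean_accuracy, stringsAsFactors = FALSE)
}

# load a simulate_cohort() dataset directory
load_cohort_data <- function(dir, config) {
  manifest_path <- file.path(dir, "manifest.json")
  if (!file.exists(manifest_path)) stop("no manifest.json in ", dir)
  manifest <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  if (manifest$subjects[[1]]$n_runs < 2)
    stop("leave-one-run-out decoding impossible: dataset has < 2 runs")
  atlas <- read_atlas(file.path(dir, "atlas.nii"),
                      file.path(dir, "atlas_lut.json"))
  subjects <- lapply(names(manifest$subjects), function(sid) {
    sub_dir <- file.path(dir, sid)
    bold_files <- sort(list.files(sub_dir, "run-[0-9]+_bold\\.nii",
                                  full.names = TRUE))
    ev_files <- sort(list.files(sub_dir, "run-[0-9]+_events\\.tsv",
                                full.names = TRUE))
    stopifnot(length(bold_files) == length(ev_files), length(bold_files) >= 2)
    bold <- lapply(bold_files, read_bold)
    schedules <- lapply(seq_along(ev_files), function(r) {
      acq <- acquisition_spec(tr_seconds = manifest$tr_seconds,
                              n_volumes = dim(bold[[r]])[4],
                              grid_shape = dim(bold[[r]])[1:3])
      read_events(ev_files[r], acq, run_id = r)
    })
    list(id = sid, bold = bold, schedules = schedules)
  })
  list(name = manifest$group, atlas = atlas, subjects = subjects,
       manifest = manifest)
}
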