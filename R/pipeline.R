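# End-to-end orchestration: simulate -> (glm) -> decode -> group -> report,
# with per-stage seed sub-streams derived from one master seed and a manifest
# of every artifact written. Rerunning with the same configuration reproduces
# identical artifacts.

#' Pipeline configuration
#'
#' @param outdir output directory.
#' @param seed master seed; all stages derive named sub-streams from it.
#' @param n_subjects cohort size.
#' @param mode `"beta"` (render beta series directly) or `"bold"` (render BOLD
#'   runs and estimate the beta series by [fit_glm()]).
#' @param level decoded label level(s): subset of `c("category",
#'   "subcategory")`.
#' @param radius searchlight radius (voxels).
#' @param n_background background analysis centers.
#' @param n_perm group permutations.
#' @param fwhm_mm group smoothing FWHM (mm).
#' @param workers searchlight workers.
#' @param noise_sd generator noise SD.
#' @param costs SVM cost candidates.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(outdir = "results/pipeline", seed = 1L,
                            n_subjects = 12L, mode = c("beta", "bold"),
                            level = "category", radius = 2, n_background = 8L,
                            n_perm = 1000L, fwhm_mm = 6, workers = 1L,
                            noise_sd = 1, costs = c(0.1, 1, 10)) {
  mode <- match.arg(mode)
  stopifnot(all(level %in% c("category", "subcategory")))
  structure(list(outdir = outdir, seed = as.integer(seed),
                 n_subjects = as.integer(n_subjects), mode = mode,
                 level = level, radius = radius,
                 n_background = as.integer(n_background),
                 n_perm = as.integer(n_perm), fwhm_mm = fwhm_mm,
                 workers = as.integer(workers), noise_sd = noise_sd,
                 costs = costs),
            class = "pipeline_config")
}

# Hash of the scientific configuration (output location excluded, so moving a
# run does not change its identity).
config_hash <- function(config) {
  cfg <- unclass(config)
  cfg$outdir <- NULL
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeBin(serialize(cfg, NULL, version = 2L), tmp)
  substr(unname(tools::md5sum(tmp)), 1, 12)
}

#' Run the synthetic-cohort pipeline end to end
#'
#' Executes the requested stages in order, writes every artifact under
#' `config$outdir` (cohort TSV, per-subject events TSV and beta-series NIfTI,
#' accuracy maps, group masks and cluster table, ground-truth JSON) and
#' returns a manifest listing each artifact with its MD5 hash.
#'
#' @param config a [pipeline_config()].
#' @param geometry,regions generator geometry and ground-truth regions
#'   (defaults: the standard 20 x 24 x 20 grid and four-region layout).
#' @param keep_betas also write per-subject beta-series NIfTIs (default FALSE;
#'   they are the largest artifacts).
#' @return the manifest, invisibly (also written as `manifest.json`).
#' @export
run_pipeline <- function(config = pipeline_config(),
                         geometry = volume_geometry(),
                         regions = default_regions(geometry),
                         keep_betas = FALSE) {
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed
  scheme <- category_scheme()
  stimuli <- build_stimulus_set(scheme)
  bank <- build_pattern_bank(geometry, regions, scheme,
                             seed = derive_seed(seed, "bank"))
  per_group <- config$n_subjects %/% 3L
  cohort <- sample_cohort(config$n_subjects,
                          c(novice = per_group, middle = per_group,
                            expert = config$n_subjects - 2L * per_group),
                          seed = derive_seed(seed, "cohort"))
  centers <- analysis_centers(geometry, regions,
                              n_background = config$n_background, seed = seed)
  paths <- character(0)
  put <- function(p) { paths[[length(paths) + 1L]] <<- p; p }

  put(write_cohort_tsv(cohort, file.path(config$outdir, "cohort.tsv")))
  put(write_ground_truth(regions, seed, file.path(config$outdir, "ground_truth.json"),
                         extra = list(config_hash = config_hash(config))))
  put(write_map_nifti(geometry$mask, geometry, file.path(config$outdir, "mask.nii")))
  put(write_map_nifti(centers, geometry, file.path(config$outdir, "centers.nii")))

  acc_maps <- list()
  behav <- list()
  for (i in seq_len(config$n_subjects)) {
    sid <- cohort$subject_id[i]
    schedule <- make_schedule(stimuli, seed = derive_seed(seed, "schedule", i))
    put(write_events_tsv(schedule, file.path(config$outdir,
                                             sprintf("%s_events.tsv", sid))))
    betas <- if (config$mode == "beta") {
      render_beta_series(cohort$expertise[i], schedule, bank, geometry, regions,
                         noise_sd = config$noise_sd,
                         seed = derive_seed(seed, "betas", i), subject_id = sid)
    } else {
      bold <- render_bold_runs(cohort$expertise[i], schedule, bank, geometry,
                               regions, noise_sd = config$noise_sd,
                               seed = derive_seed(seed, "bold", i),
                               subject_id = sid)
      fit_glm(bold, schedule)
    }
    if (keep_betas)
      put(write_beta_nifti(betas, file.path(config$outdir,
                                            sprintf("%s_betas.nii", sid))))
    for (lv in config$level) {
      cfg <- decoding_config(costs = config$costs, level = lv,
                             workers = config$workers)
      amap <- decode_whole_brain(betas, radius = config$radius, config = cfg,
                                 centers = which(centers, arr.ind = TRUE))
      acc_maps[[lv]] <- c(acc_maps[[lv]], list(amap$acc))
      put(write_map_nifti(replace(amap$acc, is.na(amap$acc), NaN), geometry,
                          file.path(config$outdir,
                                    sprintf("%s_accuracy_%s.nii", sid, lv))))
    }
    for (lv in config$level) {
      resp <- simulate_behavior(cohort$expertise[i], schedule, task = lv,
                                scheme = scheme,
                                seed = derive_seed(seed, "behavior", i))
      behav[[lv]] <- c(behav[[lv]], performance(resp$outcome))
    }
    message(sprintf("[pipeline] %s done (%d/%d)", sid, i, config$n_subjects))
  }

  group_out <- list()
  for (lv in config$level) {
    chance <- chance_level(as.numeric(table(stimuli[[lv]])))
    gcfg <- group_config(fwhm_mm = config$fwhm_mm, voxel_mm = geometry$voxel_mm,
                         n_perm = config$n_perm,
                         seed = derive_seed(seed, "group", lv))
    grp <- group_analysis(acc_maps[[lv]], centers, chance,
                          unlist(behav[[lv]]), config = gcfg)
    group_out[[lv]] <- grp
    t_arr <- replace(grp$t_map, is.na(grp$t_map), NaN)
    r_arr <- replace(grp$r_map, is.na(grp$r_map), NaN)
    put(write_map_nifti(t_arr, geometry, file.path(config$outdir, sprintf("group_t_%s.nii", lv))))
    put(write_map_nifti(r_arr, geometry, file.path(config$outdir, sprintf("group_r_%s.nii", lv))))
    # one-sided -log10(p) of the accuracy t-map (uncorrected), for viewers
    p_arr <- -log10(stats::pt(t_arr, df = grp$df, lower.tail = FALSE))
    p_arr[!is.finite(p_arr)] <- NaN
    put(write_map_nifti(p_arr, geometry,
                        file.path(config$outdir, sprintf("group_neglog10p_%s.nii", lv))))
    put(write_map_nifti(grp$accuracy_mask, geometry,
                        file.path(config$outdir, sprintf("group_accuracy_mask_%s.nii", lv))))
    put(write_map_nifti(grp$correlation_mask, geometry,
                        file.path(config$outdir, sprintf("group_correlation_mask_%s.nii", lv))))
    put(write_map_nifti(grp$conjunction_mask, geometry,
                        file.path(config$outdir, sprintf("group_conjunction_mask_%s.nii", lv))))
    tab_path <- file.path(config$outdir, sprintf("cluster_table_%s.tsv", lv))
    utils::write.table(grp$cluster_table, tab_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    put(tab_path)
  }

  manifest <- list(
    config = unclass(config), config_hash = config_hash(config),
    artifacts = data.frame(path = unlist(paths),
                           md5 = unname(tools::md5sum(unlist(paths))),
                           stringsAsFactors = FALSE))
  jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(c(manifest, list(group = group_out)))
}

#' Render orthogonal-slice PNGs of a 3-D map
#'
#' A minimal QC visualization: mid-volume axial, coronal and sagittal slices.
#' @param map numeric 3-D array.
#' @param path output PNG path.
#' @param main plot title.
#' @export
report_slices <- function(map, path, main = "") {
  grDevices::png(path, width = 900, height = 320)
  op <- graphics::par(mfrow = c(1, 3), mar = c(1, 1, 3, 1))
  on.exit({ graphics::par(op); grDevices::dev.off() })
  d <- dim(map)
  sl <- list(map[ceiling(d[1] / 2), , ], map[, ceiling(d[2] / 2), ],
             map[, , ceiling(d[3] / 2)])
  ttl <- c("sagittal", "coronal", "axial")
  for (i in 1:3)
    graphics::image(sl[[i]], axes = FALSE, col = grDevices::hcl.colors(64, "Inferno"),
                    main = paste(main, ttl[i]))
  invisible(path)
}
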