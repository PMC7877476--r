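# Parameter-recovery harness: run the full pipeline on a synthetic cohort with
# known ground truth and measure how well the group-level significance maps
# recover the planted regions and their expertise dissociation.

# 6-connected dilation of a voxel set, once per `steps`, clipped to the grid.
dilate_voxels <- function(voxels, dim, steps = 1L,
                          offsets = connectivity_offsets(6L)) {
  out <- voxels
  for (s in seq_len(steps)) {
    nb <- out[rep(seq_len(nrow(out)), each = nrow(offsets)), , drop = FALSE] +
      offsets[rep(seq_len(nrow(offsets)), times = nrow(out)), , drop = FALSE]
    out <- unique(rbind(out, nb))
    ok <- out[, 1] >= 1L & out[, 2] >= 1L & out[, 3] >= 1L &
      out[, 1] <= dim[1] & out[, 2] <= dim[2] & out[, 3] <= dim[3]
    out <- out[ok, , drop = FALSE]
  }
  out
}

# Minkowski dilation of a voxel set by an offset ball (e.g. the searchlight
# sphere), used to build the ground-truth target for conjunction recovery.
dilate_by_offsets <- function(voxels, offsets, dim) {
  nb <- voxels[rep(seq_len(nrow(voxels)), each = nrow(offsets)), , drop = FALSE] +
    offsets[rep(seq_len(nrow(offsets)), times = nrow(voxels)), , drop = FALSE]
  nb <- unique(nb)
  ok <- nb[, 1] >= 1L & nb[, 2] >= 1L & nb[, 3] >= 1L &
    nb[, 1] <= dim[1] & nb[, 2] <= dim[2] & nb[, 3] <= dim[3]
  nb[ok, , drop = FALSE]
}

voxels_to_mask <- function(voxels, dim) {
  m <- array(FALSE, dim)
  m[voxels] <- TRUE
  m
}

#' Analysis-center mask for region-focused searchlight runs
#'
#' Searchlight decoding costs ~0.2-1.5 s per center (nested cost selection over
#' 216 trials), so desk-scale runs restrict the centers to the scientifically
#' relevant set: every voxel of the expertise-coupled region cores, an
#' alternating (checkerboard) sample of the control regions (uncoupled and
#' null), and a few background voxels away from every region. All group-level
#' statistics, thresholds and recovery metrics are computed over this evaluated
#' set.
#'
#' @param geometry a [volume_geometry()].
#' @param regions list of [region_spec()].
#' @param control_stride keep control-region voxels whose coordinate-sum parity
#'   is even (`2L`, default) or all of them (`1L`).
#' @param n_background background centers sampled outside all regions
#'   (default 8).
#' @param seed seed for the background sample.
#' @return logical 3-D array of centers.
#' @export
analysis_centers <- function(geometry, regions = default_regions(geometry),
                             control_stride = 2L, n_background = 8L, seed = 1L) {
  d <- geometry$dim
  m <- array(FALSE, d)
  excluded <- array(FALSE, d)
  for (r in regions) {
    vox <- r$voxels
    if (!r$expertise_coupling && control_stride > 1L)
      vox <- vox[rowSums(vox) %% control_stride == 0L, , drop = FALSE]
    m[vox] <- TRUE
    excluded[dilate_voxels(r$voxels, d, steps = 2L)] <- TRUE
  }
  m <- m & geometry$mask
  if (n_background > 0L) {
    pool <- which(geometry$mask & !excluded)
    bg <- with_seed(derive_seed(seed, "background"),
                    sample(pool, min(n_background, length(pool))))
    m[bg] <- TRUE
  }
  m
}

# Fraction of a region's *evaluated* voxels inside a significance mask.
region_coverage <- function(sig_mask, region, centers) {
  vox <- region$voxels[centers[region$voxels], , drop = FALSE]
  if (nrow(vox) == 0L) return(NA_real_)
  mean(sig_mask[vox])
}

#' Run the synthetic-cohort recovery experiment end to end
#'
#' Samples a cohort, renders per-subject beta series with the planted region
#' structure, decodes the requested label level with the searchlight over the
#' analysis centers, runs the group analysis against simulated behavioral
#' performance, and scores recovery: coverage of each region core by the
#' accuracy and correlation significance masks, and the Dice overlap between
#' the conjunction mask and the expertise-coupled ground truth dilated by the
#' searchlight radius. Coverage and Dice are computed over the evaluated
#' centers (a conjunction can only recover voxels the searchlight visited).
#'
#' @param n_subjects cohort size (default 12; 4 per expertise group).
#' @param seed master seed; every stage derives a named sub-stream from it.
#' @param radius searchlight radius in voxels (default 2 at this grid scale).
#' @param level decoded label level (default `"category"`).
#' @param n_perm group-analysis permutations (default 1000).
#' @param n_background background analysis centers (default 8).
#' @param noise_sd beta-series noise SD (default 1).
#' @param geometry,regions generator geometry and ground-truth regions.
#' @param progress print one line per subject.
#' @return list: `group` ([group_analysis()] result), `metrics` (coverages,
#'   Dice, conjunction fraction), `cohort`, `centers`, `truth_dilated`,
#'   `acc_maps`.
#' @export
run_expertise_recovery <- function(n_subjects = 12L, seed = 1L, radius = 2,
                                   level = "category", n_perm = 1000L,
                                   n_background = 8L, noise_sd = 1,
                                   geometry = volume_geometry(),
                                   regions = default_regions(geometry),
                                   progress = FALSE) {
  per_group <- n_subjects %/% 3L
  sizes <- c(novice = per_group, middle = per_group,
             expert = n_subjects - 2L * per_group)
  cohort <- sample_cohort(n_subjects, sizes, seed = derive_seed(seed, "cohort"))
  scheme <- category_scheme()
  stimuli <- build_stimulus_set(scheme)
  bank <- build_pattern_bank(geometry, regions, scheme,
                             seed = derive_seed(seed, "bank"))
  centers <- analysis_centers(geometry, regions, n_background = n_background,
                              seed = seed)
  cfg <- decoding_config(level = level)
  acc_maps <- vector("list", n_subjects)
  behav <- numeric(n_subjects)
  for (i in seq_len(n_subjects)) {
    schedule <- make_schedule(stimuli, seed = derive_seed(seed, "schedule", i))
    betas <- render_beta_series(cohort$expertise[i], schedule, bank, geometry,
                                regions, noise_sd = noise_sd,
                                seed = derive_seed(seed, "betas", i),
                                subject_id = cohort$subject_id[i])
    amap <- decode_whole_brain(betas, radius = radius, config = cfg,
                               centers = which(centers, arr.ind = TRUE))
    acc_maps[[i]] <- amap$acc
    resp <- simulate_behavior(cohort$expertise[i], schedule, task = level,
                              scheme = scheme,
                              seed = derive_seed(seed, "behavior", i))
    behav[i] <- performance(resp$outcome)
    if (progress)
      message(sprintf("%s decoded: mean accuracy %.3f (chance %.3f)",
                      cohort$subject_id[i], mean(amap$acc, na.rm = TRUE),
                      amap$chance))
  }
  chance <- chance_level(as.numeric(table(stimuli[[level]])))
  gcfg <- group_config(n_perm = n_perm, voxel_mm = geometry$voxel_mm,
                       seed = derive_seed(seed, "group"))
  grp <- group_analysis(acc_maps, centers, chance, behav, config = gcfg)

  coupled <- Filter(function(r) r$expertise_coupling, regions)
  truth_vox <- do.call(rbind, lapply(coupled, function(r)
    dilate_by_offsets(r$voxels, sphere_offsets(radius), geometry$dim)))
  truth <- voxels_to_mask(unique(truth_vox), geometry$dim)
  metrics <- list(
    accuracy_coverage = vapply(regions, function(r)
      region_coverage(grp$accuracy_mask, r, centers), numeric(1)),
    correlation_coverage = vapply(regions, function(r)
      region_coverage(grp$correlation_mask, r, centers), numeric(1)),
    conjunction_dice = dice(grp$conjunction_mask, truth & centers),
    conjunction_fraction = grp$conjunction_fraction,
    behavior = behav)
  list(group = grp, metrics = metrics, cohort = cohort, centers = centers,
       truth_dilated = truth, acc_maps = acc_maps, chance = chance)
}
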