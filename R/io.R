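# Disk formats: 4-D NIfTI beta series with label sidecar TSV, 3-D NIfTI masks
# and statistic maps, cohort TSV, ground-truth JSON.

as_nifti_with_pixdim <- function(arr, geometry) {
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- c(geometry$voxel_mm,
                           rep(1, length(dim(arr)) - 3L))[seq_along(dim(arr))]
  img
}

#' Write a beta series as 4-D NIfTI plus a sidecar label TSV
#'
#' Voxels outside the mask are written as NaN. The sidecar has one row per
#' trial: `trial`, `run`, `stimulus_id`, `category`, `subcategory`.
#'
#' @param betas a [beta_series()].
#' @param nii_path output `.nii.gz` (or `.nii`) path.
#' @param tsv_path sidecar path; default replaces the extension with `.tsv`.
#' @return `nii_path`, invisibly.
#' @export
write_beta_nifti <- function(betas, nii_path,
                             tsv_path = sub("\\.nii(\\.gz)?$", ".tsv", nii_path)) {
  g <- betas$geometry
  arr <- array(NaN, c(g$dim, nrow(betas$data)))
  mask_idx <- which(g$mask)
  nvox <- prod(g$dim)
  for (tix in seq_len(nrow(betas$data)))
    arr[(tix - 1L) * nvox + mask_idx] <- betas$data[tix, ]
  RNifti::writeNifti(as_nifti_with_pixdim(arr, g), nii_path)
  utils::write.table(
    cbind(trial_index = seq_len(nrow(betas$trials)), betas$trials),
    tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(nii_path)
}

#' Read a beta series written by [write_beta_nifti()]
#'
#' @param nii_path 4-D NIfTI path.
#' @param mask_path 3-D NIfTI mask path (nonzero = in mask).
#' @param tsv_path sidecar label TSV.
#' @param subject_id optional label.
#' @return a [beta_series()].
#' @export
read_beta_nifti <- function(nii_path, mask_path, tsv_path, subject_id = NA_character_) {
  arr <- as.array(RNifti::readNifti(nii_path))
  msk_img <- RNifti::readNifti(mask_path)
  mask <- as.array(msk_img) != 0
  vox <- RNifti::pixdim(msk_img)[1:3]
  g <- volume_geometry(dim = dim(mask), voxel_mm = vox, mask = mask)
  labs <- utils::read.table(tsv_path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
  n_trial <- dim(arr)[4]
  mask_idx <- which(mask)
  data <- t(vapply(seq_len(n_trial), function(tix) arr[, , , tix][mask_idx],
                   numeric(length(mask_idx))))
  beta_series(data, g, trials = labs, subject_id = subject_id)
}

#' Write a 3-D map (or mask) as NIfTI
#' @param map numeric or logical 3-D array.
#' @param geometry a [volume_geometry()] (for voxel size).
#' @param path output path.
#' @export
write_map_nifti <- function(map, geometry, path) {
  RNifti::writeNifti(as_nifti_with_pixdim(map * 1, geometry), path)
  invisible(path)
}

#' Write the cohort table as TSV
#' @param cohort cohort data.frame (optionally with behavioral columns).
#' @param path output path.
#' @export
write_cohort_tsv <- function(cohort, path) {
  utils::write.table(cohort, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write the generator's ground truth as JSON
#'
#' Region definitions, informative levels, gains and the master seed, for
#' parameter-recovery checks against analysis output.
#' @param regions list of [region_spec()].
#' @param seed master seed.
#' @param path output path.
#' @param extra optional named list appended verbatim.
#' @export
write_ground_truth <- function(regions, seed, path, extra = list()) {
  gt <- list(
    seed = seed,
    regions = lapply(regions, function(r)
      list(name = r$name, informative_level = r$informative_level,
           expertise_coupling = r$expertise_coupling, base_gain = r$base_gain,
           coupling_gain = r$coupling_gain,
           voxels = unname(apply(r$voxels, 1, paste, collapse = ",")))))
  jsonlite::write_json(c(gt, extra), path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
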