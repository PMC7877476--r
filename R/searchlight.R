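# Searchlight geometry: sphere offsets (strict radius inequality, which
# uniquely reproduces the 251-voxel sphere at radius 4), center enumeration,
# and per-sphere feature extraction from a beta series.

#' Integer offsets of a searchlight sphere
#'
#' All integer 3-vectors `d` with squared norm strictly below `radius^2`, in
#' lexicographic order. At radius 4 this yields 251 offsets (the closed ball
#' would give 257); at radius 2, 27; at radius 1, only the origin.
#'
#' @param radius sphere radius in voxel units (>= 1).
#' @return integer matrix K x 3.
#' @export
sphere_offsets <- function(radius = 4) {
  if (radius < 1) stop("configuration error: radius must be >= 1", call. = FALSE)
  r <- ceiling(radius) - 1L
  g <- expand.grid(dk = -r:r, dj = -r:r, di = -r:r)
  keep <- g$di^2 + g$dj^2 + g$dk^2 < radius^2
  out <- as.matrix(g[keep, c("di", "dj", "dk")])
  dimnames(out) <- NULL
  storage.mode(out) <- "integer"
  out
}

#' Enumerate searchlight centers
#'
#' Every in-mask voxel exactly once, in deterministic column-major order.
#'
#' @param mask logical 3-D array.
#' @return integer matrix n x 3 of voxel indices.
#' @export
iterate_centers <- function(mask) {
  if (!any(mask)) stop("structural error: empty mask", call. = FALSE)
  out <- which(mask, arr.ind = TRUE)
  dimnames(out) <- NULL
  out
}

#' Extract the searchlight feature matrix at a center
#'
#' Rows are trials, columns the sphere voxels that fall inside both the grid
#' and the mask (others are dropped); the retained voxel count is attached as
#' attribute `n_voxels`.
#'
#' @param betas a [beta_series()].
#' @param center integer 3-vector (must be inside the mask).
#' @param offsets offset matrix from [sphere_offsets()].
#' @return numeric matrix trials x retained voxels.
#' @export
extract_features <- function(betas, center, offsets) {
  coords <- sweep(offsets, 2L, as.integer(center), "+")
  d <- betas$geometry$dim
  ok <- coords[, 1] >= 1L & coords[, 1] <= d[1] &
    coords[, 2] >= 1L & coords[, 2] <= d[2] &
    coords[, 3] >= 1L & coords[, 3] <= d[3]
  cols <- betas$lookup[coords[ok, , drop = FALSE]]
  cols <- cols[!is.na(cols)]
  if (length(cols) == 0L)
    stop("structural error: no in-mask voxels in sphere at center (",
         paste(center, collapse = ","), ")", call. = FALSE)
  out <- betas$data[, cols, drop = FALSE]
  attr(out, "n_voxels") <- length(cols)
  out
}
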