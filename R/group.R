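# Second-level inference over subject accuracy maps: Gaussian smoothing,
# one-sample t against chance, Pearson correlation with behavior, familywise
# error control by max-statistic permutation (sign flips for the t-test, score
# permutation for the correlation), cluster-extent inference at a
# cluster-forming threshold, and the conjunction of the two significance maps.
# Max-statistic permutation is exact under exchangeability and replaces the
# random-field-theory thresholds used by classical neuroimaging toolboxes.

#' Group-analysis configuration
#'
#' @param fwhm_mm smoothing kernel full-width at half maximum in mm (default 6).
#' @param voxel_mm voxel size in mm (3-vector, default 2).
#' @param voxel_alpha familywise alpha for the voxel-level accuracy test
#'   (default 0.05).
#' @param forming_p one-sided cluster-forming voxel p (default 0.001).
#' @param cluster_alpha familywise alpha for cluster extent (default 0.05).
#' @param connectivity 6, 18 or 26 (default 18).
#' @param n_perm permutations (default 1000).
#' @param seed permutation seed.
#' @export
group_config <- function(fwhm_mm = 6, voxel_mm = c(2, 2, 2), voxel_alpha = 0.05,
                         forming_p = 0.001, cluster_alpha = 0.05,
                         connectivity = 18L, n_perm = 1000L, seed = 1L) {
  stopifnot(voxel_alpha > 0, voxel_alpha <= 1, forming_p > 0, forming_p < 1,
            cluster_alpha > 0, cluster_alpha <= 1, fwhm_mm >= 0)
  if (!connectivity %in% c(6L, 18L, 26L))
    stop("configuration error: connectivity must be 6, 18 or 26", call. = FALSE)
  structure(list(fwhm_mm = fwhm_mm, voxel_mm = voxel_mm,
                 voxel_alpha = voxel_alpha, forming_p = forming_p,
                 cluster_alpha = cluster_alpha,
                 connectivity = as.integer(connectivity),
                 n_perm = as.integer(n_perm), seed = as.integer(seed)),
            class = "group_config")
}

gaussian_kernel_1d <- function(sigma_vox) {
  r <- max(1L, ceiling(4 * sigma_vox))
  w <- stats::dnorm(-r:r, sd = sigma_vox)
  w / sum(w)
}

conv_axis <- function(arr, w, axis) {
  d <- dim(arr)
  K <- matrix(0, d[axis], d[axis])
  r <- (length(w) - 1L) / 2L
  for (o in -r:r) {
    i <- seq_len(d[axis])
    j <- i + o
    ok <- j >= 1L & j <= d[axis]
    K[cbind(i[ok], j[ok])] <- w[o + r + 1L]
  }
  if (axis == 1L) {
    array(K %*% matrix(arr, d[1], d[2] * d[3]), d)
  } else if (axis == 2L) {
    p <- aperm(arr, c(2, 1, 3))
    aperm(array(K %*% matrix(p, d[2], d[1] * d[3]), d[c(2, 1, 3)]), c(2, 1, 3))
  } else {
    array(matrix(arr, d[1] * d[2], d[3]) %*% t(K), d)
  }
}

#' Smooth a 3-D map with a separable Gaussian kernel
#'
#' `sigma = fwhm / (2 * sqrt(2 * log(2)))` per axis, converted to voxel units
#' (1.274 voxels for 6 mm FWHM at 2 mm voxels). `fwhm_mm = 0` returns the
#' input unchanged. Without a mask, values are convolved over the full grid
#' (non-finite entries as 0). With a mask, the kernel is renormalized over the
#' in-mask voxels — each output value is the Gaussian-weighted average of the
#' available neighbors — so map values are not dragged toward zero at mask
#' edges, and the result is NA outside the mask.
#'
#' @param map numeric 3-D array.
#' @param fwhm_mm kernel FWHM in mm.
#' @param voxel_mm voxel size in mm (3-vector).
#' @param mask optional logical array of evaluated voxels.
#' @return smoothed array.
#' @export
smooth_map <- function(map, fwhm_mm = 6, voxel_mm = c(2, 2, 2), mask = NULL) {
  if (fwhm_mm == 0) return(map)
  sigma <- fwhm_mm / (2 * sqrt(2 * log(2))) / voxel_mm
  out <- map
  out[!is.finite(out)] <- 0
  if (!is.null(mask)) out[!mask] <- 0
  for (a in 1:3) out <- conv_axis(out, gaussian_kernel_1d(sigma[a]), a)
  if (!is.null(mask)) {
    w <- mask * 1
    for (a in 1:3) w <- conv_axis(w, gaussian_kernel_1d(sigma[a]), a)
    out <- out / w
    out[!mask] <- NA_real_
  }
  out
}

# Stack a list of subject arrays into subjects x voxels over `mask`.
stack_maps <- function(maps, mask) {
  do.call(rbind, lapply(maps, function(m) m[mask]))
}

#' One-sample t-map against a null value
#'
#' Per voxel, `t = (mean - null) / (SD / sqrt(n))` with `df = n - 1`; voxels
#' with zero variance across subjects are returned as NA (count reported via
#' attribute `n_zero_var`).
#'
#' @param y subjects x voxels matrix.
#' @param null null value (e.g. the chance level).
#' @return list: `t` (vector), `df`.
#' @export
one_sample_t_map <- function(y, null = 0) {
  n <- nrow(y)
  if (n < 3L) stop("need >= 3 subjects for a t-map", call. = FALSE)
  m <- colMeans(y)
  v <- (colSums(y^2) - n * m^2) / (n - 1)
  v[v < 0] <- 0  # guard rounding
  tval <- (m - null) / sqrt(v / n)
  tval[v == 0] <- NA_real_
  structure(list(t = tval, df = n - 1L), n_zero_var = sum(v == 0))
}

#' Pearson correlation map between subject maps and a behavioral score
#'
#' @param y subjects x voxels matrix.
#' @param scores numeric vector, one per subject; must not be constant.
#' @return vector of per-voxel r (NA where the voxel is constant).
#' @export
correlation_map <- function(y, scores) {
  n <- nrow(y)
  if (n < 4L) stop("need >= 4 subjects for a correlation map", call. = FALSE)
  if (stats::sd(scores) == 0)
    stop("configuration error: behavioral scores are constant", call. = FALSE)
  ys <- scale(y)  # columns to mean 0, sd 1; constant columns -> NaN
  ss <- as.numeric(scale(scores))
  r <- as.numeric(crossprod(ss, ys)) / (n - 1)
  r[!is.finite(r)] <- NA_real_
  clamp(r, -1, 1)  # guard floating-point spill past +-1
}

#' Convert a correlation to its t statistic
#'
#' `t = r * sqrt(n - 2) / sqrt(1 - r^2)` on `n - 2` degrees of freedom;
#' `|r| = 1` returns an infinite sentinel with a warning.
#' @param r correlation(s).
#' @param n sample size (>= 3).
#' @return t value(s).
#' @export
r_to_t <- function(r, n) {
  if (n < 3L) stop("need n >= 3", call. = FALSE)
  out <- ifelse(abs(r) >= 1, sign(r) * Inf, r * sqrt(n - 2) / sqrt(1 - r^2))
  if (any(abs(r) >= 1, na.rm = TRUE))
    warning("|r| = 1: returning infinite t")
  out
}

# Permutation statistic engines. Both return the observed statistic vector and
# an n_perm x voxels matrix of permuted statistics, deterministically from the
# seed and invariant to subject order (signs/permutations are drawn per
# permutation, not per subject identity).
perm_t_stats <- function(y, null, n_perm, seed) {
  n <- nrow(y)
  x <- y - null
  ss <- colSums(x^2)  # invariant under sign flips
  obs <- one_sample_t_map(y, null)
  S <- with_seed(seed, matrix(sample(c(-1, 1), n_perm * n, replace = TRUE),
                              n_perm, n))
  m <- (S %*% x) / n
  v <- sweep(-n * m^2, 2L, ss, "+") / (n - 1)
  v[v < 0] <- 0
  tmat <- m / sqrt(sweep(v, 2L, rep(n, ncol(v)), "/"))
  tmat[!is.finite(tmat)] <- NA_real_
  list(obs = obs$t, perm = tmat, df = obs$df)
}

perm_r_stats <- function(y, scores, n_perm, seed) {
  n <- nrow(y)
  ys <- scale(y)
  ss <- as.numeric(scale(scores))
  obs <- correlation_map(y, scores)
  P <- with_seed(seed, t(replicate(n_perm, ss[sample.int(n)])))
  rmat <- clamp((P %*% ys) / (n - 1), -1, 1)
  rmat[!is.finite(rmat)] <- NA_real_
  list(obs = obs, perm = rmat, df = n - 2L)
}

max_stat_threshold <- function(perm, alpha) {
  if (alpha >= 1) return(-Inf)
  maxs <- apply(perm, 1L, max, na.rm = TRUE)
  sort(maxs)[ceiling((1 - alpha) * length(maxs))]
}

#' Voxel-level FWE threshold by max-statistic permutation
#'
#' For the accuracy test (`scores = NULL`), subject deviations from `null` are
#' randomly sign-flipped; for the correlation test, `scores` are permuted. The
#' threshold is the `(1 - alpha)` quantile of the permutation distribution of
#' the map-wise maximum statistic; the significance mask is `observed >=
#' threshold` (one-sided).
#'
#' @param y subjects x voxels matrix.
#' @param null null value for the one-sample t-test (ignored when `scores`
#'   given).
#' @param scores behavioral scores; when non-NULL the statistic is Pearson r.
#' @param alpha familywise alpha.
#' @param n_perm permutations (error below 20, warning below 100).
#' @param seed integer seed.
#' @return list: `stat` (observed vector), `threshold`, `mask` (logical
#'   vector), `max_dist`, `type`.
#' @export
voxel_fwe <- function(y, null = 0, scores = NULL, alpha = 0.05,
                      n_perm = 1000L, seed = 1L) {
  if (n_perm < 20L) stop("n_perm < 20 gives a meaningless threshold", call. = FALSE)
  if (n_perm < 100L) warning("n_perm < 100: threshold will be coarse")
  eng <- if (is.null(scores)) perm_t_stats(y, null, n_perm, seed)
  else perm_r_stats(y, scores, n_perm, seed)
  thr <- max_stat_threshold(eng$perm, alpha)
  mask <- !is.na(eng$obs) & eng$obs >= thr
  list(stat = eng$obs, threshold = thr, mask = mask,
       max_dist = apply(eng$perm, 1L, max, na.rm = TRUE),
       type = if (is.null(scores)) "t" else "r")
}

connectivity_offsets <- function(connectivity) {
  g <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  nrm <- rowSums(g^2)
  keep <- switch(as.character(connectivity),
                 "6" = nrm == 1, "18" = nrm >= 1 & nrm <= 2, "26" = nrm >= 1)
  g[keep, , drop = FALSE]
}

#' Label connected components of a logical 3-D mask
#'
#' @param mask logical 3-D array.
#' @param connectivity 6 (faces), 18 (faces + edges, the neuroimaging default)
#'   or 26 (+ corners).
#' @return integer array of component labels (0 = background), with attribute
#'   `sizes` (voxel extent per component, decreasing).
#' @export
label_clusters <- function(mask, connectivity = 18L) {
  d <- dim(mask)
  offs <- connectivity_offsets(connectivity)
  labels <- array(0L, d)
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0L) {
    attr(labels, "sizes") <- integer(0)
    return(labels)
  }
  cur <- 0L
  for (s in seq_len(nrow(idx))) {
    if (labels[idx[s, , drop = FALSE]] != 0L) next
    cur <- cur + 1L
    queue <- idx[s, , drop = FALSE]
    labels[queue] <- cur
    while (nrow(queue) > 0L) {
      nb <- queue[rep(seq_len(nrow(queue)), each = nrow(offs)), , drop = FALSE] +
        offs[rep(seq_len(nrow(offs)), times = nrow(queue)), , drop = FALSE]
      ok <- nb[, 1] >= 1L & nb[, 1] <= d[1] & nb[, 2] >= 1L & nb[, 2] <= d[2] &
        nb[, 3] >= 1L & nb[, 3] <= d[3]
      nb <- nb[ok, , drop = FALSE]
      new <- nb[mask[nb] & labels[nb] == 0L, , drop = FALSE]
      if (nrow(new) > 0L) {
        new <- unique(new)
        labels[new] <- cur
      }
      queue <- new
    }
  }
  attr(labels, "sizes") <- sort(tabulate(labels[labels > 0L], nbins = cur),
                                decreasing = TRUE)
  labels
}

max_cluster_extent <- function(stat_vec, threshold, mask, connectivity) {
  supra <- array(FALSE, dim(mask))
  supra[mask] <- !is.na(stat_vec) & stat_vec >= threshold
  sizes <- attr(label_clusters(supra, connectivity), "sizes")
  if (length(sizes) == 0L) 0L else max(sizes)
}

#' Cluster-extent FWE inference
#'
#' Thresholds the observed statistic map at the one-sided cluster-forming
#' level, labels supra-threshold voxels into connected components, and compares
#' each extent with the permutation distribution of the maximum extent (from
#' the same sign-flip or score-permutation engine as [voxel_fwe()]). An empty
#' table (no supra-threshold voxels) is a valid result.
#'
#' @inheritParams voxel_fwe
#' @param mask logical 3-D array locating the voxel columns of `y`.
#' @param forming_p one-sided cluster-forming voxel p (default 0.001). For the
#'   correlation test the r-map is converted to t on `n - 2` df to apply it.
#' @param connectivity 6, 18 or 26.
#' @return list: `table` (cluster_id, peak indices, peak_t, peak_r, extent,
#'   p_fwe), `mask` (logical array of significant clusters), `forming_threshold`
#'   (in t units), `max_extent_dist`, `labels`.
#' @export
cluster_fwe <- function(y, mask, null = 0, scores = NULL, forming_p = 0.001,
                        alpha = 0.05, connectivity = 18L, n_perm = 1000L,
                        seed = 1L) {
  if (n_perm < 20L) stop("n_perm < 20 gives a meaningless threshold", call. = FALSE)
  is_corr <- !is.null(scores)
  eng <- if (is_corr) perm_r_stats(y, scores, n_perm, seed)
  else perm_t_stats(y, null, n_perm, seed)
  t_u <- stats::qt(1 - forming_p, df = eng$df)
  # threshold permuted maps on the same scale as the observed statistic
  u <- if (is_corr) t_u / sqrt(t_u^2 + eng$df) else t_u

  null_max <- vapply(seq_len(n_perm), function(b)
    max_cluster_extent(eng$perm[b, ], u, mask, connectivity), integer(1))

  supra <- array(FALSE, dim(mask))
  supra[mask] <- !is.na(eng$obs) & eng$obs >= u
  labels <- label_clusters(supra, connectivity)
  n_cl <- max(labels)
  sizes <- if (n_cl > 0L) tabulate(labels[labels > 0L], nbins = n_cl) else integer(0)
  stat_arr <- array(NA_real_, dim(mask))
  stat_arr[mask] <- eng$obs
  tab <- NULL
  sig <- array(FALSE, dim(mask))
  if (length(sizes) > 0L) {
    rows <- lapply(seq_along(sizes), function(cl) {
      vox <- which(labels == cl, arr.ind = TRUE)
      stats_cl <- stat_arr[vox]
      peak <- vox[which.max(stats_cl), ]
      peak_stat <- max(stats_cl)
      p_fwe <- (1 + sum(null_max >= sizes[cl])) / (n_perm + 1)
      data.frame(cluster_id = cl, peak_i = peak[1], peak_j = peak[2],
                 peak_k = peak[3],
                 peak_t = if (is_corr) r_to_t(peak_stat, nrow(y)) else peak_stat,
                 peak_r = if (is_corr) peak_stat else NA_real_,
                 extent = sizes[cl], p_fwe = p_fwe)
    })
    tab <- do.call(rbind, rows)
    tab <- tab[order(-tab$extent), ]
    tab$significant <- tab$p_fwe <= alpha
    for (cl in tab$cluster_id[tab$significant]) sig[labels == cl] <- TRUE
  } else {
    tab <- data.frame(cluster_id = integer(0), peak_i = integer(0),
                      peak_j = integer(0), peak_k = integer(0),
                      peak_t = numeric(0), peak_r = numeric(0),
                      extent = integer(0), p_fwe = numeric(0),
                      significant = logical(0))
  }
  list(table = tab, mask = sig, forming_threshold = t_u,
       max_extent_dist = null_max, labels = labels)
}

#' Conjunction of two significance masks
#'
#' Voxel-wise AND, with the surviving fraction relative to the total number of
#' searchlight centers.
#'
#' @param mask_a,mask_b logical arrays of identical dimension.
#' @param total_centers denominator for the surviving fraction.
#' @return list: `mask`, `n`, `fraction`.
#' @export
conjunction <- function(mask_a, mask_b, total_centers) {
  if (!identical(dim(mask_a), dim(mask_b)))
    stop("structural error: conjunction masks must share geometry", call. = FALSE)
  m <- mask_a & mask_b
  list(mask = m, n = sum(m), fraction = sum(m) / total_centers)
}

#' Full second-level analysis of subject accuracy maps
#'
#' Smooths each subject's accuracy map (6 mm FWHM by default), tests
#' accuracy > chance voxel-wise at voxel-level FWE, maps the accuracy-behavior
#' Pearson correlation with cluster-extent FWE at the cluster-forming
#' threshold, and intersects the two significance masks. First-level maps are
#' never smoothed; smoothing happens here, before all second-level tests.
#'
#' @param acc_maps list of per-subject 3-D accuracy arrays (NA outside the
#'   evaluated centers).
#' @param mask logical array of evaluated searchlight centers.
#' @param chance chance accuracy under the label scheme.
#' @param scores behavioral score per subject (same order as `acc_maps`).
#' @param config a [group_config()].
#' @return object of class `group_result`.
#' @export
group_analysis <- function(acc_maps, mask, chance, scores,
                           config = group_config()) {
  stopifnot(length(acc_maps) == length(scores))
  sm <- lapply(acc_maps, smooth_map, fwhm_mm = config$fwhm_mm,
               voxel_mm = config$voxel_mm, mask = mask)
  y <- stack_maps(sm, mask)
  vox <- voxel_fwe(y, null = chance, alpha = config$voxel_alpha,
                   n_perm = config$n_perm, seed = derive_seed(config$seed, "voxel"))
  acc_mask <- array(FALSE, dim(mask)); acc_mask[mask] <- vox$mask
  clu <- cluster_fwe(y, mask, scores = scores, forming_p = config$forming_p,
                     alpha = config$cluster_alpha,
                     connectivity = config$connectivity, n_perm = config$n_perm,
                     seed = derive_seed(config$seed, "cluster"))
  conj <- conjunction(acc_mask, clu$mask, total_centers = sum(mask))
  t_arr <- array(NA_real_, dim(mask)); t_arr[mask] <- vox$stat
  r_arr <- array(NA_real_, dim(mask)); r_arr[mask] <- correlation_map(y, scores)
  structure(
    list(t_map = t_arr, r_map = r_arr, df = length(acc_maps) - 1L,
         accuracy_mask = acc_mask, accuracy_threshold = vox$threshold,
         correlation_mask = clu$mask, cluster_table = clu$table,
         forming_threshold = clu$forming_threshold,
         conjunction_mask = conj$mask, conjunction_fraction = conj$fraction,
         chance = chance, n_subjects = length(acc_maps), config = config),
    class = "group_result")
}

#' @export
print.group_result <- function(x, ...) {
  cat(sprintf("Group analysis over %d subjects (chance %.4f)\n", x$n_subjects, x$chance))
  cat(sprintf("  accuracy > chance: %d voxels at voxel-FWE threshold t >= %.2f\n",
              sum(x$accuracy_mask), x$accuracy_threshold))
  cat(sprintf("  correlation: %d significant cluster(s), %d voxels\n",
              sum(x$cluster_table$significant), sum(x$correlation_mask)))
  cat(sprintf("  conjunction: %d centers (%.2f%%)\n", sum(x$conjunction_mask),
              100 * x$conjunction_fraction))
  invisible(x)
}
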