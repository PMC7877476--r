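# Synthetic multi-subject cohort with known ground truth: multivoxel class
# information embedded in designated regions at expertise-coupled amplitude,
# expertise-coupled behavior, and nuisance structure (drift, motion, noise).
# Emulates the statistical structure the searchlight analysis assumes; it is a
# ground-truth generator, not a biophysical simulator.

#' Volume geometry: grid, voxel size and brain mask
#'
#' The default is a small 20 x 24 x 20 grid at 2 mm isotropic voxels with an
#' ellipsoidal "brain" mask of ~4300 voxels, sized so that the full pipeline
#' runs at desk scale; real-brain dimensions are configuration only.
#'
#' @param dim integer 3-vector of grid dimensions.
#' @param voxel_mm numeric 3-vector of voxel size in mm.
#' @param mask optional logical 3-D array; default is an inscribed ellipsoid.
#' @return object of class `volume_geometry`.
#' @export
volume_geometry <- function(dim = c(20L, 24L, 20L), voxel_mm = c(2, 2, 2),
                            mask = NULL) {
  dim <- as.integer(dim)
  stopifnot(length(dim) == 3L, all(dim > 0), length(voxel_mm) == 3L)
  if (is.null(mask)) {
    ctr <- (dim + 1) / 2
    semi <- (dim - 1) / 2
    g <- expand.grid(i = seq_len(dim[1]), j = seq_len(dim[2]), k = seq_len(dim[3]))
    inside <- ((g$i - ctr[1]) / semi[1])^2 + ((g$j - ctr[2]) / semi[2])^2 +
      ((g$k - ctr[3]) / semi[3])^2 <= 1
    mask <- array(inside, dim)
  }
  if (!is.logical(mask) || !identical(dim(mask), dim))
    stop("mask must be a logical array matching `dim`", call. = FALSE)
  if (!any(mask)) stop("mask must be nonempty", call. = FALSE)
  structure(list(dim = dim, voxel_mm = as.numeric(voxel_mm), mask = mask),
            class = "volume_geometry")
}

#' Define an informative (or null) region
#'
#' @param name region label.
#' @param voxels integer matrix (n x 3) of voxel indices.
#' @param informative_level one of `"category"`, `"subcategory"`, `"both"`,
#'   `"none"`.
#' @param expertise_coupling logical; does signal gain grow with expertise?
#' @param base_gain signal amplitude at expertise 0 (arbitrary units, relative
#'   to unit noise SD).
#' @param coupling_gain additional amplitude per unit expertise.
#' @return object of class `region_spec`.
#' @export
region_spec <- function(name, voxels, informative_level = "category",
                        expertise_coupling = FALSE, base_gain = 0.5,
                        coupling_gain = 0) {
  informative_level <- match.arg(informative_level,
                                 c("category", "subcategory", "both", "none"))
  voxels <- as.matrix(voxels)
  stopifnot(ncol(voxels) == 3L)
  structure(list(name = name, voxels = voxels,
                 informative_level = informative_level,
                 expertise_coupling = isTRUE(expertise_coupling),
                 base_gain = base_gain, coupling_gain = coupling_gain),
            class = "region_spec")
}

#' Voxel index matrix of an axis-aligned box
#' @param i,j,k index ranges along each axis.
#' @return integer matrix n x 3.
#' @export
cube_voxels <- function(i, j, k) {
  out <- as.matrix(expand.grid(i = i, j = j, k = k))
  storage.mode(out) <- "integer"
  out
}

#' Default ground-truth regions
#'
#' Four disjoint 3 x 3 x 3 regions inside the default mask, encoding the
#' dissociation the analysis is designed to recover:
#' * `frontal_like` — category-informative, expertise-coupled;
#' * `temporal_like` — category- and subcategory-informative, expertise-coupled;
#' * `visual_like` — category-informative at fixed gain (decodable in everyone,
#'   uncorrelated with expertise, the early-visual control);
#' * `null_region` — no signal.
#'
#' @param geometry a [volume_geometry()].
#' @return named list of [region_spec()] objects.
#' @export
default_regions <- function(geometry = volume_geometry()) {
  regs <- list(
    frontal_like = region_spec("frontal_like", cube_voxels(8:10, 19:21, 10:12),
                               "category", TRUE, base_gain = 0.2, coupling_gain = 1.0),
    temporal_like = region_spec("temporal_like", cube_voxels(4:6, 10:12, 8:10),
                                "both", TRUE, base_gain = 0.2, coupling_gain = 1.0),
    visual_like = region_spec("visual_like", cube_voxels(9:11, 4:6, 9:11),
                              "category", FALSE, base_gain = 0.9, coupling_gain = 0),
    null_region = region_spec("null_region", cube_voxels(14:16, 13:15, 12:14),
                              "none", FALSE, base_gain = 0, coupling_gain = 0))
  validate_regions(regs, geometry)
  regs
}

validate_regions <- function(regions, geometry) {
  seen <- character(0)
  for (r in regions) {
    key <- apply(r$voxels, 1, paste, collapse = ",")
    if (any(key %in% seen))
      stop("region voxel sets must be disjoint (", r$name, ")", call. = FALSE)
    seen <- c(seen, key)
    if (any(r$voxels < 1L) || any(t(r$voxels) > geometry$dim))
      stop("region ", r$name, " extends outside the grid", call. = FALSE)
    if (!all(geometry$mask[r$voxels]))
      stop("region ", r$name, " extends outside the mask", call. = FALSE)
  }
  invisible(regions)
}

#' Sample a cohort of subject expertise profiles
#'
#' Expertise is a latent score in \[0, 1\] drawn per group from truncated
#' normals whose means are ordered novice < middle < expert; a competition-style
#' rating is an affine readout (novices are non-rate-holders, rating `NA`).
#'
#' @param n_subjects cohort size (default 30).
#' @param group_sizes named counts for novice/middle/expert (default 10 each).
#' @param seed integer seed.
#' @param group_means,group_sds expertise distribution per group. Defaults are
#'   calibrated so that simulated category-task accuracy averages ~76% over the
#'   default cohort (see [simulate_behavior()]).
#' @return data.frame: `subject_id`, `group`, `expertise`, `rating`.
#' @export
sample_cohort <- function(n_subjects = 30L,
                          group_sizes = c(novice = 10L, middle = 10L, expert = 10L),
                          seed = 1L,
                          group_means = c(novice = 0.54, middle = 0.71, expert = 0.85),
                          group_sds = c(novice = 0.10, middle = 0.08, expert = 0.06)) {
  if (n_subjects < 2L)
    stop("configuration error: need at least 2 subjects for correlation analyses",
         call. = FALSE)
  if (sum(group_sizes) != n_subjects)
    stop("configuration error: group_sizes must sum to n_subjects", call. = FALSE)
  groups <- rep(names(group_sizes), times = group_sizes)
  with_seed(seed, {
    expertise <- clamp(stats::rnorm(n_subjects, group_means[groups], group_sds[groups]),
                       0.05, 0.98)
  })
  rating <- ifelse(groups == "novice", NA_real_,
                   round(pmax(0, 3500 * (expertise - 0.45))))
  data.frame(subject_id = sprintf("sub-%02d", seq_len(n_subjects)),
             group = groups, expertise = expertise, rating = rating,
             stringsAsFactors = FALSE)
}

#' Simulate per-trial behavioral responses
#'
#' A linear psychometric map with lapses: the subject answers with probability
#' `1 - lapse` (unanswered otherwise) and, when answering, is correct with
#' probability `chance + (ceiling - chance) * expertise`, where `chance` is the
#' per-trial guessing rate (1/4 on the category task; 1/choices on the
#' subcategory task, where choices = subcategories of the trial's category).
#'
#' @param expertise scalar in \[0, 1\].
#' @param schedule a `stimulus_schedule`.
#' @param task `"category"` (4AFC) or `"subcategory"` (forced choice among the
#'   trial category's subcategories).
#' @param scheme the [category_scheme()] (needed for subcategory choice counts).
#' @param ceiling asymptotic accuracy at expertise 1. Defaults (1.0 category,
#'   0.80 subcategory) are calibrated to the published group means (~76% and
#'   ~66%).
#' @param lapse probability of an unanswered trial.
#' @param seed integer seed.
#' @return data.frame: `run`, `trial`, `category`, `subcategory`, `chance`,
#'   `outcome` (factor: correct/incorrect/unanswered).
#' @export
simulate_behavior <- function(expertise, schedule, task = c("category", "subcategory"),
                              scheme = category_scheme(),
                              ceiling = if (task == "category") 1.0 else 0.80,
                              lapse = 0.02, seed = 1L) {
  task <- match.arg(task)
  e <- schedule$entries
  if (task == "category") {
    chance <- rep(1 / length(scheme$categories), nrow(e))
  } else {
    n_choices <- table(factor(scheme$parent, levels = scheme$categories))
    chance <- 1 / as.numeric(n_choices[e$category])
  }
  if (any(ceiling < chance))
    stop("configuration error: ceiling below chance", call. = FALSE)
  p_correct <- chance + (ceiling - chance) * expertise
  with_seed(seed, {
    answered <- stats::runif(nrow(e)) >= lapse
    correct <- answered & (stats::runif(nrow(e)) < p_correct)
  })
  outcome <- ifelse(!answered, "unanswered", ifelse(correct, "correct", "incorrect"))
  data.frame(run = e$run, trial = e$trial, category = e$category,
             subcategory = e$subcategory, chance = chance,
             outcome = factor(outcome, levels = c("correct", "incorrect", "unanswered")),
             stringsAsFactors = FALSE)
}

#' Build the bank of region-by-class multivoxel patterns
#'
#' One pattern vector per (region, class label). Patterns are zero-mean across
#' the region's voxels — class information is carried by the pattern, not by
#' mean signal — and unit L2 norm, so region gain has a fixed meaning in units
#' of noise SD.
#'
#' @param geometry a [volume_geometry()].
#' @param regions list of [region_spec()].
#' @param scheme a [category_scheme()].
#' @param seed integer seed.
#' @param subject_perturb per-subject pattern perturbation magnitude as a
#'   fraction of the pattern norm (default 0.2).
#' @return object of class `pattern_bank`.
#' @export
build_pattern_bank <- function(geometry, regions, scheme = category_scheme(),
                               seed = 1L, subject_perturb = 0.2) {
  validate_regions(regions, geometry)
  mk_patterns <- function(n_class, n_vox) {
    P <- matrix(stats::rnorm(n_class * n_vox), n_class, n_vox)
    P <- P - rowMeans(P)
    P / sqrt(rowSums(P^2))
  }
  banks <- with_seed(seed, {
    lapply(regions, function(r) {
      n_vox <- nrow(r$voxels)
      out <- list()
      if (r$informative_level %in% c("category", "both"))
        out$category <- mk_patterns(length(scheme$categories), n_vox)
      if (r$informative_level %in% c("subcategory", "both"))
        out$subcategory <- mk_patterns(length(scheme$subcategories), n_vox)
      out
    })
  })
  names(banks) <- vapply(regions, `[[`, character(1), "name")
  structure(list(patterns = banks, scheme = scheme, seed = as.integer(seed),
                 subject_perturb = subject_perturb),
            class = "pattern_bank")
}

# Subject-specific version of a pattern matrix: add a zero-mean random
# direction scaled to `frac` of each pattern's norm. Keeps patterns zero-mean.
perturb_patterns <- function(P, frac) {
  if (frac == 0) return(P)
  Z <- matrix(stats::rnorm(length(P)), nrow(P), ncol(P))
  Z <- Z - rowMeans(Z)
  Z <- Z / sqrt(rowSums(Z^2))
  P + frac * sqrt(rowSums(P^2)) * Z
}

region_gain <- function(region, expertise) {
  if (region$expertise_coupling)
    region$base_gain + region$coupling_gain * expertise
  else region$base_gain
}

# Trial-by-voxel signal amplitudes (no noise) for one subject over the in-mask
# voxel columns of `geometry`. Shared by the beta-series and BOLD renderers so
# both paths carry identical class information.
signal_amplitudes <- function(expertise, schedule, bank, geometry, regions,
                              subject_seed) {
  e <- schedule$entries
  n_trial <- nrow(e)
  mask_idx <- which(geometry$mask)
  lookup <- array(NA_integer_, geometry$dim)
  lookup[mask_idx] <- seq_along(mask_idx)
  A <- matrix(0, n_trial, length(mask_idx))
  scheme <- bank$scheme
  with_seed(subject_seed, {
    for (r in regions) {
      if (r$informative_level == "none") next
      cols <- lookup[r$voxels]
      g <- region_gain(r, expertise)
      pats <- bank$patterns[[r$name]]
      if (!is.null(pats$category)) {
        P <- perturb_patterns(pats$category, bank$subject_perturb)
        cls <- match(e$category, scheme$categories)
        A[, cols] <- A[, cols] + g * P[cls, , drop = FALSE]
      }
      if (!is.null(pats$subcategory)) {
        P <- perturb_patterns(pats$subcategory, bank$subject_perturb)
        cls <- match(e$subcategory, scheme$subcategories)
        A[, cols] <- A[, cols] + g * P[cls, , drop = FALSE]
      }
    }
  })
  A
}

#' Construct a beta-series container
#'
#' Trial-wise beta maps stored as a trials x in-mask-voxels matrix with the
#' trial labels and geometry needed downstream.
#'
#' @param data numeric matrix, trials x in-mask voxels (column order =
#'   column-major order of `which(geometry$mask)`).
#' @param geometry a [volume_geometry()].
#' @param trials data.frame with at least `run`, `category`, `subcategory`.
#' @param subject_id optional label.
#' @return object of class `beta_series`.
#' @export
beta_series <- function(data, geometry, trials, subject_id = NA_character_) {
  mask_idx <- which(geometry$mask)
  stopifnot(ncol(data) == length(mask_idx), nrow(data) == nrow(trials))
  if (!all(is.finite(data)))
    stop("beta series contains non-finite values inside the mask", call. = FALSE)
  lookup <- array(NA_integer_, geometry$dim)
  lookup[mask_idx] <- seq_along(mask_idx)
  structure(list(data = data, geometry = geometry, trials = trials,
                 lookup = lookup, subject_id = subject_id),
            class = "beta_series")
}

#' Render a subject's trial-wise beta series directly
#'
#' `beta[trial, voxel] = sum over regions of gain(expertise) * pattern(region,
#' class(trial))[voxel] + N(0, noise_sd^2)`. This is the fast generative path
#' standing at the point where first-level GLM output enters the analysis (the
#' modeled path is [render_bold_runs()] + [fit_glm()]).
#'
#' @param expertise scalar in \[0, 1\].
#' @param schedule a `stimulus_schedule`.
#' @param bank a [build_pattern_bank()] result.
#' @param geometry,regions as elsewhere.
#' @param noise_sd i.i.d. Gaussian noise SD per voxel and trial (> 0).
#' @param seed integer seed (drives the subject's pattern perturbation too).
#' @param subject_id optional label.
#' @return a [beta_series()] with one volume per task trial (216 by default).
#' @export
render_beta_series <- function(expertise, schedule, bank, geometry, regions,
                               noise_sd = 1, seed = 1L,
                               subject_id = NA_character_) {
  if (noise_sd <= 0)
    stop("configuration error: noise_sd must be positive", call. = FALSE)
  A <- signal_amplitudes(expertise, schedule, bank, geometry, regions,
                         subject_seed = derive_seed(seed, "patterns"))
  with_seed(derive_seed(seed, "noise"), {
    A <- A + matrix(stats::rnorm(length(A), sd = noise_sd), nrow(A), ncol(A))
  })
  e <- schedule$entries
  beta_series(A, geometry,
              trials = e[, c("run", "trial", "stimulus_id", "category", "subcategory")],
              subject_id = subject_id)
}

#' Render a subject's BOLD runs
#'
#' Per run, the voxel time series is the sum of HRF-convolved 10-s code-phase
#' boxcars weighted by the trial amplitudes of the beta model, a slow cosine
#' drift, motion-correlated nuisance signal, and i.i.d. Gaussian noise. Each
#' run starts with one 16-s dummy trial (8 volumes at TR 2 s) carrying no task
#' signal, matching the volumes discarded before GLM fitting.
#'
#' @inheritParams render_beta_series
#' @param tr repetition time in seconds (default 2).
#' @param drift_amp amplitude of the low-frequency drift (0 disables).
#' @param motion_amp amplitude scale of the motion-coupled nuisance (0 disables;
#'   motion parameters are still generated).
#' @return object of class `bold_runs`: per-run time x voxel matrices, per-run
#'   motion parameter tables (6 columns), `tr`, `n_dummy_volumes`.
#' @export
render_bold_runs <- function(expertise, schedule, bank, geometry, regions,
                             noise_sd = 1, tr = 2, drift_amp = 2, motion_amp = 0.5,
                             seed = 1L, subject_id = NA_character_) {
  if (noise_sd < 0) stop("configuration error: noise_sd must be >= 0", call. = FALSE)
  if (schedule$trial_length_s %% tr != 0)
    stop("structural error: TR must divide the 16-s trial length", call. = FALSE)
  A <- signal_amplitudes(expertise, schedule, bank, geometry, regions,
                         subject_seed = derive_seed(seed, "patterns"))
  n_vox <- ncol(A)
  run_secs <- run_duration_seconds(schedule)
  n_vol <- as.integer(run_secs / tr)
  n_dummy_vol <- as.integer(schedule$dummy_trials_per_run *
                              schedule$trial_length_s / tr)
  runs <- vector("list", schedule$n_runs)
  motion <- vector("list", schedule$n_runs)
  for (r in seq_len(schedule$n_runs)) {
    e <- schedule$entries[schedule$entries$run == r, ]
    X <- trial_regressors(onsets = e$onset + e$fixation_s,
                          duration = e$code_s[1], n_volumes = n_vol, tr = tr)
    Y <- X %*% A[schedule$entries$run == r, , drop = FALSE]
    with_seed(derive_seed(seed, "run", r), {
      if (drift_amp > 0) {
        tsec <- (seq_len(n_vol) - 1) * tr
        dr <- vapply(1:3, function(k) cos(2 * pi * k * tsec / run_secs), numeric(n_vol))
        Y <- Y + (dr %*% matrix(stats::rnorm(3 * n_vox, sd = drift_amp), 3, n_vox))
      }
      M <- apply(matrix(stats::rnorm(n_vol * 6, sd = 0.05), n_vol, 6), 2, cumsum)
      if (motion_amp > 0)
        Y <- Y + M %*% matrix(stats::rnorm(6 * n_vox, sd = motion_amp), 6, n_vox)
      if (noise_sd > 0)
        Y <- Y + matrix(stats::rnorm(n_vol * n_vox, sd = noise_sd), n_vol, n_vox)
    })
    runs[[r]] <- Y
    motion[[r]] <- M
  }
  structure(list(runs = runs, motion = motion, tr = tr,
                 n_dummy_volumes = n_dummy_vol, geometry = geometry,
                 subject_id = subject_id),
            class = "bold_runs")
}
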