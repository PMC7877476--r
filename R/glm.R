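# Trial-wise (least-squares-all) GLM: one HRF-convolved code-phase regressor
# per trial in a single per-run model, plus motion, discrete-cosine drift and
# constant columns; ordinary least squares per in-mask voxel.

#' GLM configuration
#'
#' @param highpass_cutoff_s high-pass cutoff period in seconds (default 128);
#'   implemented as discrete-cosine drift regressors inside the GLM.
#' @param peak_delay,undershoot_delay,ratio canonical double-gamma HRF
#'   parameters (defaults 6, 16, 1/6).
#' @param include_motion include the 6 motion parameters as nuisance columns.
#' @param n_dummy_volumes leading volumes discarded per run before design
#'   construction (default 8 at TR 2 s = the 16-s dummy trial).
#' @param dt fine time grid for HRF convolution (seconds).
#' @return list of class `glm_config`.
#' @export
glm_config <- function(highpass_cutoff_s = 128, peak_delay = 6,
                       undershoot_delay = 16, ratio = 1 / 6,
                       include_motion = TRUE, n_dummy_volumes = 8L, dt = 0.1) {
  structure(list(highpass_cutoff_s = highpass_cutoff_s, peak_delay = peak_delay,
                 undershoot_delay = undershoot_delay, ratio = ratio,
                 include_motion = include_motion,
                 n_dummy_volumes = as.integer(n_dummy_volumes), dt = dt),
            class = "glm_config")
}

# Double-gamma HRF density (unnormalized), zero at t = 0, peak near
# `peak_delay` s, late undershoot scaled by `ratio`.
hrf_shape <- function(t, peak_delay = 6, undershoot_delay = 16, ratio = 1 / 6) {
  stats::dgamma(t, shape = peak_delay, rate = 1) -
    ratio * stats::dgamma(t, shape = undershoot_delay, rate = 1)
}

#' Canonical double-gamma HRF sampled at the TR
#'
#' @param tr sampling interval in seconds (> 0).
#' @param duration kernel length in seconds (default 32; must be >= 10 to avoid
#'   truncating the response).
#' @param peak_delay,undershoot_delay,ratio shape parameters.
#' @return numeric kernel sampled at `0, tr, 2 tr, ...`, scaled to unit peak.
#' @examples
#' h <- canonical_hrf(2)
#' h[1]    # 0 at t = 0
#' max(h)  # 1 by normalization
#' @export
canonical_hrf <- function(tr, duration = 32, peak_delay = 6,
                          undershoot_delay = 16, ratio = 1 / 6) {
  if (tr <= 0) stop("configuration error: tr must be positive", call. = FALSE)
  if (duration < 10)
    stop("configuration error: HRF duration < 10 s truncates the kernel",
         call. = FALSE)
  t <- seq(0, duration, by = tr)
  h <- hrf_shape(t, peak_delay, undershoot_delay, ratio)
  h / max(h)
}

#' Discrete-cosine drift basis
#'
#' Returns the `floor(2 * n_volumes * tr / cutoff)` lowest-frequency DCT
#' regressors, i.e. all components with period above the cutoff; columns are
#' mutually orthonormal. Zero columns is a valid result.
#'
#' @param n_volumes number of time points.
#' @param tr repetition time in seconds.
#' @param cutoff cutoff period in seconds (must exceed `2 * tr`).
#' @return matrix `n_volumes` x K (possibly K = 0).
#' @export
dct_drift_basis <- function(n_volumes, tr, cutoff = 128) {
  if (cutoff <= 2 * tr)
    stop("configuration error: cutoff must exceed 2 * tr", call. = FALSE)
  K <- floor(2 * n_volumes * tr / cutoff)
  t <- seq_len(n_volumes) - 1
  if (K < 1) return(matrix(numeric(0), n_volumes, 0))
  B <- vapply(seq_len(K),
              function(k) sqrt(2 / n_volumes) * cos(pi * (2 * t + 1) * k / (2 * n_volumes)),
              numeric(n_volumes))
  colnames(B) <- sprintf("dct%02d", seq_len(K))
  B
}

# One HRF-convolved boxcar regressor per onset, computed on a fine grid and
# sampled at volume acquisition times; each column scaled to unit peak so beta
# estimates read as response amplitudes.
trial_regressors <- function(onsets, duration, n_volumes, tr, dt = 0.1,
                             hrf_pars = list()) {
  t_end <- n_volumes * tr
  if (any(onsets < 0) || any(onsets + duration > t_end))
    stop("structural error: trial onset/offset beyond run bounds", call. = FALSE)
  n_fine <- ceiling(t_end / dt) + 1L
  t_fine <- (seq_len(n_fine) - 1) * dt
  h <- do.call(hrf_shape, c(list(t = seq(0, 32, by = dt)), hrf_pars))
  vol_idx <- round((seq_len(n_volumes) - 1) * tr / dt) + 1L
  X <- vapply(onsets, function(on) {
    box <- as.numeric(t_fine >= on & t_fine < on + duration)
    conv <- stats::convolve(box, rev(h), type = "open")[seq_len(n_fine)] * dt
    reg <- conv[vol_idx]
    reg / max(conv)
  }, numeric(n_volumes))
  colnames(X) <- sprintf("trial_%03d", seq_along(onsets))
  X
}

#' Build a per-run design matrix
#'
#' One unit-peak HRF-convolved 10-s boxcar per trial, locked to the code-phase
#' onset (fixation and response phases are not modeled), 6 motion columns when
#' supplied, DCT drift columns, and a constant. Onsets are shifted by the
#' duration of the discarded dummy volumes.
#'
#' @param run_entries schedule entries for one run (rows of
#'   `schedule$entries`).
#' @param n_volumes retained volumes in the run (after dummy discard).
#' @param tr repetition time in seconds.
#' @param motion optional matrix `n_volumes` x 6 of realignment parameters.
#' @param config a [glm_config()].
#' @return list with `X` (design matrix), `parts` (column index list:
#'   trial/motion/drift/constant).
#' @export
build_design_matrix <- function(run_entries, n_volumes, tr, motion = NULL,
                                config = glm_config()) {
  dummy_shift <- config$n_dummy_volumes * tr
  onsets <- run_entries$onset + run_entries$fixation_s - dummy_shift
  Xt <- trial_regressors(onsets, duration = run_entries$code_s[1],
                         n_volumes = n_volumes, tr = tr, dt = config$dt,
                         hrf_pars = list(peak_delay = config$peak_delay,
                                         undershoot_delay = config$undershoot_delay,
                                         ratio = config$ratio))
  parts <- list(trial = seq_len(ncol(Xt)))
  X <- Xt
  if (!is.null(motion)) {
    motion <- as.matrix(motion)
    if (nrow(motion) != n_volumes || ncol(motion) != 6L)
      stop("structural error: motion table must be n_volumes x 6", call. = FALSE)
    colnames(motion) <- sprintf("motion%d", 1:6)
    parts$motion <- ncol(X) + seq_len(6L)
    X <- cbind(X, motion)
  }
  D <- dct_drift_basis(n_volumes, tr, config$highpass_cutoff_s)
  if (ncol(D) > 0) {
    parts$drift <- ncol(X) + seq_len(ncol(D))
    X <- cbind(X, D)
  }
  parts$constant <- ncol(X) + 1L
  X <- cbind(X, constant = 1)
  list(X = X, parts = parts)
}

#' Fit the trial-wise GLM to BOLD runs
#'
#' Discards the leading dummy volumes of each run, builds the per-run design,
#' and estimates per-voxel OLS coefficients; the trial-column coefficients,
#' concatenated across runs in schedule order, form the beta series (216
#' volumes for the default design).
#'
#' @param bold a [render_bold_runs()] object (or compatible list with `runs`,
#'   `motion`, `tr`, `n_dummy_volumes`, `geometry`).
#' @param schedule the `stimulus_schedule` the runs were acquired under.
#' @param config a [glm_config()].
#' @return a [beta_series()].
#' @export
fit_glm <- function(bold, schedule, config = glm_config()) {
  betas <- vector("list", schedule$n_runs)
  for (r in seq_len(schedule$n_runs)) {
    Y <- bold$runs[[r]]
    keep <- (config$n_dummy_volumes + 1L):nrow(Y)
    Y <- Y[keep, , drop = FALSE]
    motion <- if (config$include_motion && !is.null(bold$motion))
      as.matrix(bold$motion[[r]])[keep, , drop = FALSE] else NULL
    des <- build_design_matrix(schedule$entries[schedule$entries$run == r, ],
                               n_volumes = nrow(Y), tr = bold$tr,
                               motion = motion, config = config)
    qrX <- qr(des$X)
    if (qrX$rank < ncol(des$X)) {
      bad <- colnames(des$X)[qrX$pivot[(qrX$rank + 1L):ncol(des$X)]]
      stop("rank-deficient design in run ", r, "; collinear columns: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    coef <- qr.coef(qrX, Y)
    betas[[r]] <- coef[des$parts$trial, , drop = FALSE]
  }
  e <- schedule$entries
  beta_series(do.call(rbind, betas), bold$geometry,
              trials = e[, c("run", "trial", "stimulus_id", "category", "subcategory")],
              subject_id = bold$subject_id %||% NA_character_)
}
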