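# Shared fixtures, built in code: default scheme/schedule, a tiny geometry
# with one informative region, and helpers for separable toy decoding sets.

default_scheme <- category_scheme()
default_stimuli <- build_stimulus_set(default_scheme)
default_schedule <- make_schedule(default_stimuli, seed = 42L)

tiny_geometry <- function(dim = c(6L, 6L, 6L)) {
  volume_geometry(dim = dim, mask = array(TRUE, dim))
}

tiny_region <- function(geometry, level = "category", coupled = TRUE,
                        base = 0.5, coupling = 1) {
  list(sig = region_spec("sig", cube_voxels(2:4, 2:4, 2:4), level, coupled,
                         base_gain = base, coupling_gain = coupling))
}

# Linearly separable toy set: `n_runs` runs x `per_run` trials, `k` classes,
# orthogonal class means scaled by `sep`, plus optional noise.
toy_problem <- function(n_runs = 3L, per_run = 8L, k = 2L, p = 4L, sep = 4,
                        noise = 0.2, seed = 1L) {
  set.seed(seed)
  n <- n_runs * per_run
  y <- factor(rep(seq_len(k), length.out = n))
  centers <- matrix(0, k, p)
  for (i in seq_len(k)) centers[i, ((i - 1) %% p) + 1] <- sep
  x <- centers[as.integer(y), , drop = FALSE] +
    matrix(rnorm(n * p, sd = noise), n, p)
  list(x = x, y = y, runs = rep(seq_len(n_runs), each = per_run))
}

# Naive reference for leave-one-run-out CV with nested cost selection:
# straight loops, no memoization, same solver settings. Used as the
# independent oracle for cv_accuracy / select_cost.
reference_cv <- function(x, y, runs, config) {
  y <- as.factor(y)
  run_ids <- unique(runs)
  preds <- factor(rep(NA_character_, length(y)), levels = levels(y))
  for (r in run_ids) {
    train <- runs != r
    if (length(config$costs) == 1L) {
      C <- config$costs
    } else {
      inner_runs <- setdiff(run_ids, r)
      best_acc <- -1; C <- NA_real_
      for (cand in config$costs) {
        corr <- 0L; tot <- 0L
        for (ir in inner_runs) {
          itr <- train & runs != ir
          ite <- runs == ir
          sc <- fit_scaler(x[itr, , drop = FALSE])
          xtr <- apply_scaler(sc, x[itr, , drop = FALSE], config$clip)
          xte <- apply_scaler(sc, x[ite, , drop = FALSE], config$clip)
          w <- if (config$class_weights) class_cost_weights(y[itr]) else NULL
          fit <- e1071::svm(xtr, y[itr], scale = FALSE, kernel = "linear",
                            cost = cand, class.weights = w,
                            tolerance = config$tolerance)
          pr <- predict(fit, xte)
          corr <- corr + sum(pr == y[ite]); tot <- tot + sum(ite)
        }
        if (corr / tot > best_acc) { best_acc <- corr / tot; C <- cand }
      }
    }
    sc <- fit_scaler(x[train, , drop = FALSE])
    xtr <- apply_scaler(sc, x[train, , drop = FALSE], config$clip)
    xte <- apply_scaler(sc, x[!train, , drop = FALSE], config$clip)
    w <- if (config$class_weights) class_cost_weights(y[train]) else NULL
    fit <- e1071::svm(xtr, y[train], scale = FALSE, kernel = "linear",
                      cost = C, class.weights = w, tolerance = config$tolerance)
    preds[!train] <- predict(fit, xte)
  }
  list(pred = preds, accuracy = mean(preds == y))
}
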