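# Leave-one-run-out linear-SVM decoding with the published preprocessing:
# train-only z-scaling with [-3, 3] outlier clipping, cost selection over
# {0.1, 1, 10} by nested leave-one-run-out cross-validation, inverse-frequency
# class weights for the imbalanced subcategory problem, and the
# frequency-proportional chance convention (sum of squared class proportions).

#' Decoding configuration
#'
#' @param costs SVM cost candidates for the nested grid search (default
#'   `c(0.1, 1, 10)`).
#' @param clip scaled-signal cutoffs (default `c(-3, 3)`); values outside are
#'   set to the nearest limit.
#' @param level `"category"` or `"subcategory"`; decides the default for
#'   `class_weights`.
#' @param class_weights use inverse-frequency misclassification cost weights
#'   (default: on for subcategory, off for category).
#' @param tolerance libsvm termination tolerance. The default 0.05 is coarser
#'   than the solver's 0.001 because fold accuracies are quantized at 1/36,
#'   far above solver precision; it roughly halves searchlight runtime.
#' @param workers parallel workers for [decode_whole_brain()] (forked; results
#'   are identical for any worker count).
#' @return list of class `decoding_config`.
#' @export
decoding_config <- function(costs = c(0.1, 1, 10), clip = c(-3, 3),
                            level = c("category", "subcategory"),
                            class_weights = NULL, tolerance = 0.05,
                            workers = 1L) {
  level <- match.arg(level)
  if (any(costs <= 0)) stop("configuration error: costs must be positive", call. = FALSE)
  if (!(clip[1] < 0 && clip[2] > 0))
    stop("configuration error: clip bounds must straddle 0", call. = FALSE)
  structure(list(costs = sort(costs), clip = clip, level = level,
                 class_weights = class_weights %||% (level == "subcategory"),
                 tolerance = tolerance, workers = as.integer(workers)),
            class = "decoding_config")
}

#' Chance level for frequency-proportional guessing
#'
#' `sum(p_i^2)` over class proportions: the expected accuracy of a guesser that
#' draws labels with the training frequencies. Reproduces both published
#' values: 25% for four balanced categories and 9.72% (= 504/5184) for the
#' ten-of-6 plus one-of-12 subcategory distribution.
#'
#' @param counts positive class counts.
#' @return expected accuracy in (0, 1\].
#' @export
chance_level <- function(counts) {
  if (length(counts) == 0L || any(counts <= 0))
    stop("configuration error: counts must be positive and nonempty", call. = FALSE)
  p <- counts / sum(counts)
  sum(p^2)
}

#' Fit the train-only feature scaler
#'
#' Per-column mean and SD estimated on training rows only.
#' @param x training feature matrix.
#' @return list of class `feature_scaler`.
#' @export
fit_scaler <- function(x) {
  if (nrow(x) < 2L)
    stop("configuration error: need >= 2 training rows to fit a scaler", call. = FALSE)
  structure(list(center = colMeans(x), scale = apply(x, 2L, stats::sd)),
            class = "feature_scaler")
}

#' Apply a fitted scaler with outlier clipping
#'
#' `(x - train mean) / train SD`, then clipped into `clip`; columns with zero
#' training variance map to 0.
#' @param scaler a [fit_scaler()] result.
#' @param x feature matrix (training or test rows).
#' @param clip lower/upper cutoffs (default `c(-3, 3)`).
#' @return scaled, clipped matrix.
#' @export
apply_scaler <- function(scaler, x, clip = c(-3, 3)) {
  z <- sweep(x, 2L, scaler$center, "-")
  ok <- scaler$scale > 0
  z[, ok] <- sweep(z[, ok, drop = FALSE], 2L, scaler$scale[ok], "/")
  z[, !ok] <- 0
  clamp(z, clip[1], clip[2])
}

#' Inverse-frequency class cost weights
#'
#' Weight proportional to 1/frequency, normalized to mean 1 so the cost grid
#' keeps its meaning; errors if a class of the label factor is absent.
#' @param labels factor of training labels.
#' @return named numeric weights, one per class, mean 1.
#' @export
class_cost_weights <- function(labels) {
  labels <- as.factor(labels)
  counts <- table(labels)
  if (length(counts) < 2L)
    stop("configuration error: need >= 2 classes to weight", call. = FALSE)
  if (any(counts == 0))
    stop("cannot weight unseen class(es): ",
         paste(names(counts)[counts == 0], collapse = ", "), call. = FALSE)
  w <- 1 / as.numeric(counts)
  w <- w / mean(w)
  names(w) <- names(counts)
  w
}

svm_fit <- function(x, y, cost, weights = NULL, tolerance = 0.05) {
  e1071::svm(x = x, y = y, scale = FALSE, kernel = "linear", cost = cost,
             class.weights = weights, tolerance = tolerance)
}

# Fit + predict for one (train, test) split at one cost, with train-only
# scaling and optional class weights.
fold_predict <- function(x, y, train, test, cost, config) {
  sc <- fit_scaler(x[train, , drop = FALSE])
  xtr <- apply_scaler(sc, x[train, , drop = FALSE], config$clip)
  xte <- apply_scaler(sc, x[test, , drop = FALSE], config$clip)
  w <- if (config$class_weights) class_cost_weights(y[train]) else NULL
  fit <- svm_fit(xtr, y[train], cost, w, config$tolerance)
  stats::predict(fit, xte)
}

#' Select the SVM cost by nested leave-one-run-out cross-validation
#'
#' For each candidate, an inner leave-one-run-out loop over the training runs
#' (with its own train-only scaling per inner fold) measures pooled accuracy;
#' the candidate with the highest inner accuracy wins, ties going to the
#' smallest cost.
#'
#' @param x training features (raw, unscaled).
#' @param y training labels (factor).
#' @param runs training run labels.
#' @param config a [decoding_config()].
#' @return the selected cost.
#' @export
select_cost <- function(x, y, runs, config = decoding_config()) {
  costs <- config$costs
  if (length(costs) == 1L) return(costs)
  inner_runs <- unique(runs)
  if (length(inner_runs) < 2L)
    stop("cannot run nested cross-validation with a single training run",
         call. = FALSE)
  acc <- vapply(costs, function(C) {
    correct <- 0L; total <- 0L
    for (ir in inner_runs) {
      train <- runs != ir; test <- runs == ir
      pred <- fold_predict(x, y, train, test, C, config)
      correct <- correct + sum(pred == y[test])
      total <- total + sum(test)
    }
    correct / total
  }, numeric(1))
  costs[which.max(acc)]
}

#' Leave-one-run-out cross-validated decoding accuracy
#'
#' Each run serves once as the test set. Per outer fold: scaler fitted on the
#' training rows and applied (with clipping) to both partitions; cost selected
#' by nested leave-one-run-out over the training runs; linear-kernel SVM
#' (libsvm one-vs-one multiclass) trained, optionally with inverse-frequency
#' class weights; test run predicted. Accuracy is pooled correct/total over
#' all folds. Inner-loop models are memoized over unordered run pairs (the
#' training set for outer fold r, inner fold s is runs minus \{r, s\}, which is
#' symmetric), an exact equivalence that roughly halves the fit count.
#'
#' @param x feature matrix, trials x voxels.
#' @param y labels (coerced to factor).
#' @param runs run label per trial.
#' @param config a [decoding_config()].
#' @return object of class `decoding_result`: `accuracy`, `chance`,
#'   `fold_accuracy`, `selected_cost` (per fold), `confusion`.
#' @export
cv_accuracy <- function(x, y, runs, config = decoding_config()) {
  y <- as.factor(y)
  run_ids <- unique(runs)
  if (length(run_ids) < 2L)
    stop("need >= 2 runs for leave-one-run-out cross-validation", call. = FALSE)
  for (r in run_ids) {
    miss <- setdiff(levels(y), unique(as.character(y[runs != r])))
    if (length(miss) > 0L)
      stop("class(es) ", paste(miss, collapse = ", "),
           " missing from the training partition of fold (run ", r, ")",
           call. = FALSE)
  }
  nested <- length(config$costs) > 1L
  if (nested && length(run_ids) < 3L)
    stop("cannot run nested cross-validation with a single training run",
         call. = FALSE)

  # memoized inner-fold predictions: key = excluded run pair + cost
  inner_cache <- new.env(parent = emptyenv())
  inner_pred <- function(r_out, r_in, C) {
    key <- paste(sort(c(r_out, r_in))[1], sort(c(r_out, r_in))[2], C, sep = "|")
    hit <- inner_cache[[key]]
    if (is.null(hit)) {
      train <- runs != r_out & runs != r_in
      test <- runs == r_out | runs == r_in
      pred <- fold_predict(x, y, train, test, C, config)
      hit <- list(pred = pred, test_runs = runs[test])
      inner_cache[[key]] <- hit
    }
    hit$pred[hit$test_runs == r_in]
  }

  fold_acc <- numeric(length(run_ids))
  sel_cost <- numeric(length(run_ids))
  pred_all <- character(length(y))
  for (fi in seq_along(run_ids)) {
    r <- run_ids[fi]
    train <- runs != r; test <- runs == r
    C <- if (!nested) config$costs else {
      inner_runs <- setdiff(run_ids, r)
      acc <- vapply(config$costs, function(C) {
        correct <- 0L; total <- 0L
        for (ir in inner_runs) {
          pred <- inner_pred(r, ir, C)
          truth <- y[runs == ir]
          correct <- correct + sum(pred == truth)
          total <- total + length(truth)
        }
        correct / total
      }, numeric(1))
      config$costs[which.max(acc)]
    }
    pred <- fold_predict(x, y, train, test, C, config)
    pred_all[test] <- as.character(pred)
    fold_acc[fi] <- mean(pred == y[test])
    sel_cost[fi] <- C
  }
  pred_all <- factor(pred_all, levels = levels(y))
  structure(
    list(accuracy = mean(pred_all == y),
         chance = chance_level(as.numeric(table(y))),
         fold_accuracy = fold_acc, selected_cost = sel_cost,
         confusion = table(predicted = pred_all, truth = y),
         n_trials = length(y)),
    class = "decoding_result")
}

#' @export
print.decoding_result <- function(x, ...) {
  cat(sprintf("Leave-one-run-out decoding: accuracy %.3f (chance %.3f, %d trials, %d folds)\n",
              x$accuracy, x$chance, x$n_trials, length(x$fold_accuracy)))
  invisible(x)
}

#' Whole-brain (or masked) searchlight decoding for one subject
#'
#' Runs [cv_accuracy()] on the sphere features at every requested center. The
#' result does not depend on center order or worker count.
#'
#' @param betas a [beta_series()].
#' @param radius searchlight radius in voxel units (default 4).
#' @param config a [decoding_config()]; `config$level` picks the label column.
#' @param centers optional integer matrix n x 3 restricting the centers
#'   (default: every in-mask voxel via [iterate_centers()]).
#' @return object of class `accuracy_map`: 3-D array `acc` (NA outside the
#'   evaluated centers), `chance`, `level`, `radius`, `subject_id`,
#'   `n_sphere_voxels` per center.
#' @export
decode_whole_brain <- function(betas, radius = 4, config = decoding_config(),
                               centers = NULL) {
  centers <- centers %||% iterate_centers(betas$geometry$mask)
  offsets <- sphere_offsets(radius)
  y <- factor(betas$trials[[config$level]])
  runs <- betas$trials$run
  one_center <- function(i) {
    feat <- extract_features(betas, centers[i, ], offsets)
    res <- tryCatch(cv_accuracy(feat, y, runs, config), error = function(e)
      stop("searchlight center (", paste(centers[i, ], collapse = ","), "): ",
           conditionMessage(e), call. = FALSE))
    c(res$accuracy, attr(feat, "n_voxels"))
  }
  idx <- seq_len(nrow(centers))
  out <- if (config$workers > 1L)
    parallel::mclapply(idx, one_center, mc.cores = config$workers)
  else lapply(idx, one_center)
  out <- do.call(rbind, out)
  acc <- array(NA_real_, betas$geometry$dim)
  acc[centers] <- out[, 1]
  nvox <- array(NA_integer_, betas$geometry$dim)
  nvox[centers] <- as.integer(out[, 2])
  structure(list(acc = acc, chance = chance_level(as.numeric(table(y))),
                 level = config$level, radius = radius,
                 subject_id = betas$subject_id, centers = centers,
                 n_sphere_voxels = nvox),
            class = "accuracy_map")
}
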