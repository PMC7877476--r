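test_that("chance level is the sum of squared class proportions", {
  expect_equal(chance_level(rep(18, 4)), 0.25)
  expect_equal(round(chance_level(c(rep(6, 10), 12)), 4), 0.0972)
  expect_equal(chance_level(c(rep(6, 10), 12)), 504 / 5184)
  expect_equal(chance_level(72), 1.0)
  expect_error(chance_level(numeric(0)), "counts")
})

test_that("scaler standardizes on train only, clips, and zeroes degenerate voxels", {
  set.seed(1)
  x <- matrix(rnorm(40, mean = 5, sd = 3), 20, 2)
  x <- cbind(x, 7)  # constant voxel
  sc <- fit_scaler(x)
  z <- apply_scaler(sc, x)
  expect_lt(max(abs(colMeans(z[, 1:2]))), 1e-10)
  expect_lt(max(abs(apply(z[, 1:2], 2, sd) - 1)), 0.2)  # clipped tails may shrink SD
  z_unclipped <- sweep(sweep(x[, 1:2], 2, sc$center[1:2]), 2, sc$scale[1:2], "/")
  expect_lt(max(abs(colMeans(z_unclipped))), 1e-10)
  expect_lt(max(abs(apply(z_unclipped, 2, sd) - 1)), 1e-10)
  # test value far above the train mean clips to +3
  far <- matrix(sc$center + 5 * sc$scale, 1)
  expect_equal(as.vector(apply_scaler(sc, far))[1:2], c(3, 3))
  # constant training voxel maps to 0 whatever the test value
  expect_equal(apply_scaler(sc, matrix(c(0, 0, 1e6), 1))[3], 0)
  expect_error(fit_scaler(x[1, , drop = FALSE]), "2 training rows")
})

test_that("class weights are inverse-frequency with mean one", {
  bal <- factor(rep(c("a", "b", "c"), each = 5))
  expect_equal(unname(class_cost_weights(bal)), rep(1, 3))
  sub <- factor(rep(default_scheme$subcategories,
                    default_scheme$sizes[default_scheme$subcategories]))
  w <- class_cost_weights(sub)
  expect_equal(mean(w), 1)
  expect_equal(unname(w["linear_search"] / w["arithmetic"]), 0.5)
  set.seed(2)
  rand <- factor(sample(letters[1:4], 50, replace = TRUE))
  expect_equal(mean(class_cost_weights(rand)), 1)
  lev <- factor(c("a", "a", "b"), levels = c("a", "b", "c"))
  expect_error(class_cost_weights(lev), "unseen class")
})

test_that("cost selection follows the nested grid search with smallest-cost ties", {
  toy <- toy_problem(n_runs = 3L, per_run = 8L, seed = 3L)
  expect_equal(select_cost(toy$x, toy$y, toy$runs, decoding_config(costs = 1)), 1)
  # perfectly separable data: all candidates tie -> smallest cost wins
  sep <- toy_problem(n_runs = 3L, per_run = 8L, sep = 50, noise = 0.01, seed = 4L)
  expect_equal(select_cost(sep$x, sep$y, sep$runs, decoding_config()), 0.1)
  expect_error(select_cost(toy$x, toy$y, rep(1L, length(toy$y)), decoding_config()),
               "single training run")
  # matches an exhaustive independent evaluation
  noisy <- toy_problem(n_runs = 4L, per_run = 12L, k = 3L, sep = 0.8,
                       noise = 1, seed = 5L)
  cfg <- decoding_config()
  ref_acc <- vapply(cfg$costs, function(C) {
    corr <- 0L
    for (ir in unique(noisy$runs)) {
      tr <- noisy$runs != ir
      sc <- fit_scaler(noisy$x[tr, ])
      fit <- e1071::svm(apply_scaler(sc, noisy$x[tr, ]), noisy$y[tr],
                        scale = FALSE, kernel = "linear", cost = C,
                        tolerance = cfg$tolerance)
      corr <- corr + sum(predict(fit, apply_scaler(sc, noisy$x[!tr, ])) ==
                           noisy$y[!tr])
    }
    corr / length(noisy$y)
  }, numeric(1))
  expect_equal(select_cost(noisy$x, noisy$y, noisy$runs, cfg),
               cfg$costs[which.max(ref_acc)])
})

test_that("cv_accuracy is perfect on separable data and matches the naive reference", {
  sep <- toy_problem(n_runs = 2L, per_run = 4L, sep = 10, noise = 0.05, seed = 6L)
  cfg1 <- decoding_config(costs = 1)
  res <- cv_accuracy(sep$x, sep$y, sep$runs, cfg1)
  expect_equal(res$accuracy, 1.0)
  expect_equal(length(res$fold_accuracy), 2L)
  expect_equal(sum(res$confusion), length(sep$y))
  # 2-run toy: identical predictions to the independently coded loop
  ref <- reference_cv(sep$x, sep$y, sep$runs, cfg1)
  expect_equal(res$accuracy, ref$accuracy)
  # nested path on a noisy 4-run multiclass toy, with and without weights
  for (weights in c(FALSE, TRUE)) {
    noisy <- toy_problem(n_runs = 4L, per_run = 12L, k = 3L, sep = 1,
                         noise = 1, seed = 7L)
    cfg <- decoding_config(class_weights = weights)
    res_n <- cv_accuracy(noisy$x, noisy$y, noisy$runs, cfg)
    ref_n <- reference_cv(noisy$x, noisy$y, noisy$runs, cfg)
    expect_identical(res_n$accuracy, ref_n$accuracy)
    expect_identical(as.character(cv_accuracy(noisy$x, noisy$y, noisy$runs, cfg)$selected_cost),
                     as.character(res_n$selected_cost))  # rerun determinism
  }
})

test_that("permuted labels give chance-level accuracy on average", {
  set.seed(8)
  cfg <- decoding_config(costs = 1)
  accs <- replicate(60, {
    x <- matrix(rnorm(48 * 6), 48, 6)
    y <- factor(rep(1:4, length.out = 48))
    runs <- rep(1:4, each = 12)
    cv_accuracy(x, sample(y), runs, cfg)$accuracy
  })
  # mean accuracy within the 99% interval around chance for pooled trials
  se <- sqrt(0.25 * 0.75 / (48 * 60))
  expect_lt(abs(mean(accs) - 0.25), 2.58 * se * 3)  # conservative (fold dependence)
})

test_that("training-side artifacts are untouched by test-row corruption", {
  toy <- toy_problem(n_runs = 3L, per_run = 8L, seed = 9L)
  test_rows <- toy$runs == 2L
  sc_before <- fit_scaler(toy$x[!test_rows, ])
  x_corrupt <- toy$x
  x_corrupt[test_rows, ] <- 1e6
  sc_after <- fit_scaler(x_corrupt[!test_rows, ])
  expect_identical(sc_before, sc_after)
  cfg <- decoding_config(costs = 1)
  cost_before <- select_cost(toy$x[!test_rows, ], toy$y[!test_rows],
                             toy$runs[!test_rows], decoding_config())
  cost_after <- select_cost(x_corrupt[!test_rows, ], toy$y[!test_rows],
                            toy$runs[!test_rows], decoding_config())
  expect_identical(cost_before, cost_after)
})

test_that("class weights help minority classes on imbalanced separable data", {
  # 2 classes, 5:1 imbalance, moderate separation
  set.seed(10)
  n_runs <- 4L
  y <- factor(rep(c(rep("maj", 10), rep("min", 2)), n_runs))
  runs <- rep(seq_len(n_runs), each = 12)
  x <- matrix(rnorm(48 * 4, sd = 1.2), 48, 4)
  x[y == "min", 1] <- x[y == "min", 1] + 2.2
  res_w <- cv_accuracy(x, y, runs, decoding_config(costs = 1, class_weights = TRUE))
  res_u <- cv_accuracy(x, y, runs, decoding_config(costs = 1, class_weights = FALSE))
  min_acc <- function(res) res$confusion["min", "min"] / sum(res$confusion[, "min"])
  expect_gte(min_acc(res_w), min_acc(res_u))
})

test_that("cv_accuracy validates run structure and class presence", {
  toy <- toy_problem(seed = 11L)
  expect_error(cv_accuracy(toy$x, toy$y, rep(1L, length(toy$y)), decoding_config()),
               ">= 2 runs")
  y_bad <- toy$y
  y_bad[toy$runs != 1L] <- levels(toy$y)[1]  # class 2 only in run 1
  expect_error(cv_accuracy(toy$x, y_bad, toy$runs, decoding_config(costs = 1)),
               "missing from the training partition")
})

test_that("whole-brain decoding maps accuracy onto the evaluated centers", {
  g <- tiny_geometry()
  regs <- tiny_region(g, base = 1.2, coupling = 0, coupled = FALSE)
  bank <- build_pattern_bank(g, regs, default_scheme, seed = 12L)
  bs <- render_beta_series(0.5, default_schedule, bank, g, regs,
                           noise_sd = 1, seed = 13L)
  centers <- rbind(c(3L, 3L, 3L), c(6L, 6L, 6L))
  cfg <- decoding_config(costs = 1)
  amap <- decode_whole_brain(bs, radius = 2, config = cfg, centers = centers)
  expect_equal(sum(!is.na(amap$acc)), 2L)
  expect_equal(amap$chance, 0.25)
  # informative center beats chance clearly; corner center does not
  expect_gt(amap$acc[3, 3, 3], 0.25 + 3 * sqrt(0.25 * 0.75 / 216))
  # determinism and order invariance
  amap2 <- decode_whole_brain(bs, radius = 2, config = cfg,
                              centers = centers[2:1, ])
  expect_identical(amap$acc, amap2$acc)
})
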