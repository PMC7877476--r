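test_that("default cohort has 30 subjects in three ordered groups", {
  cohort <- sample_cohort(seed = 3L)
  expect_equal(nrow(cohort), 30L)
  expect_equal(as.vector(table(cohort$group)[c("novice", "middle", "expert")]),
               rep(10L, 3))
  means <- tapply(cohort$expertise, cohort$group, mean)
  expect_lt(means["novice"], means["middle"])
  expect_lt(means["middle"], means["expert"])
  expect_true(all(cohort$expertise >= 0 & cohort$expertise <= 1))
  expect_identical(cohort, sample_cohort(seed = 3L))
  expect_error(sample_cohort(1L, c(novice = 1L, middle = 0L, expert = 0L)),
               "at least 2 subjects")
})

test_that("behavior model hits its floor, ceiling and published calibration", {
  # floor: expertise 0, no lapses -> long-run accuracy at 4-choice chance
  resp0 <- simulate_behavior(0, default_schedule, "category", lapse = 0, seed = 1L)
  expect_lt(abs(performance(resp0$outcome) - 0.25), 0.06)  # ~2 binomial SE
  # ceiling: expertise 1, ceiling 1, no lapses -> perfect
  resp1 <- simulate_behavior(1, default_schedule, "category",
                             ceiling = 1, lapse = 0, seed = 1L)
  expect_equal(performance(resp1$outcome), 1.0)
  expect_error(simulate_behavior(0.5, default_schedule, "category", ceiling = 0.1),
               "ceiling below chance")
  # calibration: default cohort group mean accuracy ~76%
  cohort <- sample_cohort(seed = 11L)
  acc <- vapply(seq_len(nrow(cohort)), function(i) {
    performance(simulate_behavior(cohort$expertise[i], default_schedule,
                                  "category", seed = 100L + i)$outcome)
  }, numeric(1))
  expect_lt(abs(mean(acc) * 100 - 76.0), 5)
})

test_that("expertise ordering is recoverable from simulated behavior", {
  cohort <- sample_cohort(seed = 2L)
  acc <- vapply(seq_len(nrow(cohort)), function(i) {
    performance(simulate_behavior(cohort$expertise[i], default_schedule,
                                  "category", seed = 200L + i)$outcome)
  }, numeric(1))
  ct <- cor.test(cohort$expertise, acc, method = "spearman", exact = FALSE)
  expect_gt(ct$estimate, 0)
  expect_lt(ct$p.value, 0.01)
})

test_that("pattern bank patterns are zero-mean, unit-norm and distinct", {
  g <- tiny_geometry()
  regs <- tiny_region(g, level = "both")
  bank <- build_pattern_bank(g, regs, default_scheme, seed = 4L)
  P <- bank$patterns$sig$category
  expect_equal(dim(P), c(4L, 27L))
  expect_true(all(abs(rowMeans(P)) < 1e-10))
  expect_equal(unname(sqrt(rowSums(P^2))), rep(1, 4))
  expect_lt(max(abs(cor(t(P))[lower.tri(diag(4))])), 1)
  expect_equal(dim(bank$patterns$sig$subcategory), c(11L, 27L))
  expect_identical(bank, build_pattern_bank(g, regs, default_scheme, seed = 4L))
  bad <- list(region_spec("out", cube_voxels(5:7, 5:7, 5:7)))
  expect_error(build_pattern_bank(g, bad, default_scheme), "outside the grid")
})

test_that("beta renderer embeds class signal only where gain is nonzero", {
  g <- tiny_geometry()
  regs <- tiny_region(g, coupled = TRUE, base = 0, coupling = 1)
  bank <- build_pattern_bank(g, regs, default_scheme, seed = 5L)
  expect_error(render_beta_series(0.5, default_schedule, bank, g, regs,
                                  noise_sd = 0), "noise_sd")
  # expertise 0 with base gain 0: the region carries no class signal
  bs0 <- render_beta_series(0, default_schedule, bank, g, regs,
                            noise_sd = 1e-6, seed = 6L)
  reg_cols <- bs0$lookup[regs$sig$voxels]
  by_class <- stats::aggregate(bs0$data[, reg_cols[1]],
                               list(bs0$trials$category), mean)
  expect_lt(diff(range(by_class$x)), 1e-5)
  expect_equal(nrow(bs0$data), 216L)
  # coupled region at high expertise carries signal
  bs1 <- render_beta_series(1, default_schedule, bank, g, regs,
                            noise_sd = 1e-6, seed = 6L)
  by_class1 <- stats::aggregate(bs1$data[, reg_cols[1]],
                                list(bs1$trials$category), mean)
  expect_gt(diff(range(by_class1$x)), 0.01)
})

test_that("uncoupled-region decodability does not differ between expertise groups", {
  g <- tiny_geometry()
  regs <- tiny_region(g, coupled = FALSE, base = 0.9, coupling = 0)
  bank <- build_pattern_bank(g, regs, default_scheme, seed = 7L)
  off <- sphere_offsets(2)
  ctr <- c(3L, 3L, 3L)
  acc_for <- function(expertise, seed) {
    bs <- render_beta_series(expertise, default_schedule, bank, g, regs,
                             noise_sd = 1, seed = seed)
    f <- extract_features(bs, ctr, off)
    cv_accuracy(f, bs$trials$category, bs$trials$run,
                decoding_config(costs = 1))$accuracy
  }
  lo <- vapply(1:10, function(i) acc_for(0.2, 300L + i), numeric(1))
  hi <- vapply(1:10, function(i) acc_for(0.9, 400L + i), numeric(1))
  expect_gt(t.test(lo, hi)$p.value, 0.05)
  expect_gt(mean(c(lo, hi)), 0.25)  # but decodable in everyone
})

test_that("BOLD runs have the published volume counts and dummy structure", {
  g <- tiny_geometry(c(4L, 4L, 4L))
  regs <- tiny_region(g)
  regs$sig$voxels <- cube_voxels(1:2, 1:2, 1:2)
  bank <- build_pattern_bank(g, regs, default_scheme, seed = 8L)
  bold <- render_bold_runs(0.5, default_schedule, bank, g, regs, seed = 9L)
  expect_equal(length(bold$runs), 6L)
  expect_equal(nrow(bold$runs[[1]]), 296L)            # 592 s / 2 s
  expect_equal(bold$n_dummy_volumes, 8L)
  expect_equal(nrow(bold$runs[[1]]) - bold$n_dummy_volumes, 288L)  # 36 x 8
  expect_equal(dim(bold$motion[[1]]), c(296L, 6L))
  expect_true(all(vapply(bold$runs, function(r) all(is.finite(r)), logical(1))))
})
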