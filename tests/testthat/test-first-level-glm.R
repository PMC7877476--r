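glm_fixture <- function(noise_sd = 0, drift_amp = 0, motion_amp = 0,
                        expertise = 0.7, seed = 5L) {
  g <- tiny_geometry(c(4L, 4L, 4L))
  regs <- list(sig = region_spec("sig", cube_voxels(1:2, 1:2, 1:2),
                                 "category", TRUE, 0.5, 1))
  bank <- build_pattern_bank(g, regs, default_scheme, seed = 3L)
  bold <- render_bold_runs(expertise, default_schedule, bank, g, regs,
                           noise_sd = noise_sd, drift_amp = drift_amp,
                           motion_amp = motion_amp, seed = seed)
  amplitudes <- decodelight:::signal_amplitudes(
    expertise, default_schedule, bank, g, regs,
    subject_seed = derive_seed(seed, "patterns"))
  list(geometry = g, bold = bold, amplitudes = amplitudes)
}

test_that("canonical HRF has the standard double-gamma shape", {
  h <- canonical_hrf(2)
  expect_equal(h[1], 0)
  expect_equal(max(h), 1)
  t_dense <- seq(0, 32, by = 0.01)
  shape <- decodelight:::hrf_shape(t_dense)
  expect_equal(t_dense[which.max(shape)], 5, tolerance = 0.05)
  expect_lt(min(shape), 0)  # late undershoot
  expect_error(canonical_hrf(2, duration = 8), "duration")
  expect_error(canonical_hrf(0), "tr")
})

test_that("DCT drift basis has the SPM count and orthogonal columns", {
  B <- dct_drift_basis(288, 2, 128)
  expect_equal(ncol(B), 9L)  # floor(2*288*2/128)
  G <- crossprod(B)
  expect_lt(max(abs(G - diag(ncol(B)))), 1e-10)
  expect_equal(ncol(dct_drift_basis(10, 2, 1000)), 0L)
  expect_error(dct_drift_basis(288, 2, 3), "cutoff")
})

test_that("design matrix has the published column structure", {
  entries <- default_schedule$entries[default_schedule$entries$run == 1, ]
  motion <- matrix(rnorm(288 * 6), 288, 6)
  des <- build_design_matrix(entries, 288, 2, motion = motion)
  expect_equal(ncol(des$X), 52L)  # 36 trials + 6 motion + 9 drift + 1 constant
  expect_length(des$parts$trial, 36L)
  des_nm <- build_design_matrix(entries, 288, 2, motion = NULL)
  expect_equal(ncol(des_nm$X), 46L)
  # trial regressor support starts at the code-phase onset
  reg1 <- des$X[, 1]
  onset_vol <- (entries$onset[1] + entries$fixation_s[1] - 16) / 2
  expect_true(all(abs(reg1[seq_len(onset_vol)]) < 1e-12))
  # unit peak on the fine grid; TR sampling lands near but not on the maximum
  expect_gt(max(reg1), 0.95)
  expect_error(
    build_design_matrix(entries, 100, 2, motion = NULL),
    "beyond run bounds")
})

test_that("noiseless BOLD is recovered to numerical precision", {
  fx <- glm_fixture(noise_sd = 0, drift_amp = 0, motion_amp = 0)
  bs <- fit_glm(fx$bold, default_schedule)
  expect_equal(nrow(bs$data), 216L)
  rel_err <- max(abs(bs$data - fx$amplitudes)) / max(abs(fx$amplitudes))
  expect_lt(rel_err, 1e-8)
})

test_that("drift within the DCT span leaves trial betas unchanged", {
  fx <- glm_fixture(noise_sd = 0, drift_amp = 0, motion_amp = 0)
  bs_clean <- fit_glm(fx$bold, default_schedule)
  bold2 <- fx$bold
  # add a confound lying in the span of the retained-volume drift basis
  D <- dct_drift_basis(288, 2, 128)
  confound <- D %*% matrix(seq_len(ncol(D)), ncol(D), 1)
  for (r in seq_along(bold2$runs))
    bold2$runs[[r]][9:296, ] <- bold2$runs[[r]][9:296, ] +
      confound %*% matrix(1, 1, ncol(bold2$runs[[r]]))
  bs_drift <- fit_glm(bold2, default_schedule)
  expect_lt(max(abs(bs_drift$data - bs_clean$data)), 1e-8)
})

test_that("OLS residuals are orthogonal to the design", {
  entries <- default_schedule$entries[default_schedule$entries$run == 1, ]
  des <- build_design_matrix(entries, 288, 2, motion = NULL)
  set.seed(1)
  y <- scale(rnorm(288))
  beta <- qr.coef(qr(des$X), y)
  resid <- y - des$X %*% beta
  expect_lt(max(abs(crossprod(des$X, resid))), 1e-6)
})

test_that("beta recovery error decreases monotonically with SNR", {
  noise_levels <- c(4, 2, 1, 0.5)
  errs <- vapply(seq_along(noise_levels), function(i) {
    fx <- glm_fixture(noise_sd = noise_levels[i], seed = 50L + i)
    bs <- fit_glm(fx$bold, default_schedule)
    sqrt(mean((bs$data - fx$amplitudes)^2))
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
})

test_that("rank-deficient designs fail naming the collinear columns", {
  fx <- glm_fixture()
  bold2 <- fx$bold
  for (r in seq_along(bold2$motion)) bold2$motion[[r]][, 2] <- bold2$motion[[r]][, 1]
  expect_error(fit_glm(bold2, default_schedule), "collinear")
})
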