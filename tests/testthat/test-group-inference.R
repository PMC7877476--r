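test_that("Gaussian smoothing conserves mass and uses the right sigma", {
  imp <- array(0, c(21, 21, 21)); imp[11, 11, 11] <- 1
  sm <- smooth_map(imp, 6, c(2, 2, 2))
  expect_lt(abs(sum(sm) - 1), 1e-6)
  expect_identical(smooth_map(imp, 0), imp)
  # sigma: half-maximum at +-fwhm/2 along an axis
  prof <- sm[, 11, 11] / max(sm[, 11, 11])
  sigma <- 6 / (2 * sqrt(2 * log(2))) / 2
  expect_equal(sigma, 1.2740, tolerance = 1e-4)
  expect_equal(prof[11 + 1], exp(-1 / (2 * sigma^2)), tolerance = 1e-3)
})

test_that("masked smoothing averages over available voxels without edge bias", {
  m <- array(FALSE, c(11, 11, 11)); m[4:8, 4:8, 4:8] <- TRUE
  flat <- array(NA_real_, c(11, 11, 11)); flat[m] <- 0.4
  sm <- smooth_map(flat, 6, c(2, 2, 2), mask = m)
  expect_true(all(is.na(sm[!m])))
  expect_lt(max(abs(sm[m] - 0.4)), 1e-10)  # constant map stays constant
})

test_that("one-sample t-map matches direct computation and t.test", {
  r <- one_sample_t_map(matrix(c(0.30, 0.35, 0.25), 3, 1), 0.25)
  expect_equal(r$t, 1.732, tolerance = 1e-3)
  expect_equal(r$df, 2L)
  set.seed(1)
  y <- matrix(rnorm(12 * 1000, mean = 0.3, sd = 0.1), 12)
  tm <- one_sample_t_map(y, 0.25)
  ref <- vapply(seq_len(1000), function(v) t.test(y[, v], mu = 0.25)$statistic,
                numeric(1))
  expect_lt(max(abs(tm$t - ref)), 1e-10)
  expect_error(one_sample_t_map(y[1:2, ], 0), ">= 3 subjects")
})

test_that("correlation map matches cor() and r_to_t reproduces published peaks", {
  set.seed(2)
  y <- matrix(rnorm(30 * 500), 30)
  scores <- rnorm(30)
  r <- correlation_map(y, scores)
  expect_lt(max(abs(r - as.numeric(cor(scores, y)))), 1e-12)
  expect_true(all(abs(r) <= 1))
  # affine relation gives r = 1 everywhere
  y_affine <- matrix(scores, 30, 5) * 2 + 1
  expect_equal(correlation_map(y_affine, scores), rep(1, 5))
  expect_error(correlation_map(y, rep(1, 30)), "constant")
  # published Table-2-style conversions
  expect_equal(r_to_t(0.789, 30), 6.80, tolerance = 0.01)
  expect_equal(r_to_t(0.698, 30), 5.16, tolerance = 0.01)
  expect_equal(r_to_t(0, 10), 0)
  expect_warning(tinf <- r_to_t(1, 10), "infinite")
  expect_identical(tinf, Inf)
})

test_that("null correlation maps put ~5% of voxels past the nominal cutoff", {
  set.seed(3)
  n <- 30L
  y <- matrix(rnorm(n * 4000), n)
  r <- correlation_map(y, rnorm(n))
  crit <- qt(0.975, n - 2)
  frac <- mean(abs(r_to_t(r, n)) > crit)
  expect_lt(abs(frac - 0.05), 0.02)
})

test_that("voxel FWE threshold detects planted signal and honors alpha = 1", {
  set.seed(4)
  n <- 12L; V <- 600L
  y <- matrix(rnorm(n * V, mean = 0.25, sd = 0.05), n)
  signal <- 1:20
  y[, signal] <- y[, signal] + 0.25  # effect >> noise
  res <- voxel_fwe(y, null = 0.25, alpha = 0.05, n_perm = 500, seed = 5L)
  expect_true(all(res$mask[signal]))
  expect_lt(mean(res$mask[-signal]), 0.02)
  res_all <- voxel_fwe(y, null = 0.25, alpha = 1, n_perm = 500, seed = 5L)
  expect_true(all(res_all$mask))
  expect_error(voxel_fwe(y, n_perm = 10), "n_perm")
  expect_warning(voxel_fwe(y, null = 0.25, n_perm = 50, seed = 1L), "coarse")
})

test_that("permutation engines are seed-deterministic and order-invariant", {
  set.seed(6)
  n <- 10L
  y <- matrix(rnorm(n * 200), n)
  scores <- rnorm(n)
  a <- voxel_fwe(y, scores = scores, alpha = 0.05, n_perm = 200, seed = 7L)
  b <- voxel_fwe(y, scores = scores, alpha = 0.05, n_perm = 200, seed = 7L)
  expect_identical(a$threshold, b$threshold)
  expect_identical(a$mask, b$mask)
  # subject order: statistic field is permutation-equivariant, threshold close
  ord <- sample(n)
  c_ <- voxel_fwe(y[ord, ], scores = scores[ord], alpha = 0.05, n_perm = 200,
                  seed = 7L)
  expect_equal(c_$stat, a$stat, tolerance = 1e-12)
})

test_that("cluster labeling distinguishes 6/18/26 connectivity", {
  m <- array(FALSE, c(8, 8, 8))
  m[2:4, 2:4, 2:4] <- TRUE  # blob A
  m[5:7, 5:7, 5:7] <- TRUE  # blob B touching A only at the (4,4,4)-(5,5,5) corner
  lab18 <- label_clusters(m, 18L)
  expect_equal(length(attr(lab18, "sizes")), 2L)
  expect_equal(attr(lab18, "sizes"), c(27L, 27L))
  lab26 <- label_clusters(m, 26L)
  expect_equal(length(attr(lab26, "sizes")), 1L)
  # edge-touching blobs merge at 18 but not at 6
  m2 <- array(FALSE, c(8, 8, 8))
  m2[2:3, 2:3, 2] <- TRUE
  m2[4, 4, 2] <- FALSE
  m2[3, 4, 3] <- TRUE  # shares an edge with (3,3,2)? offset (0,1,1) -> 18-conn
  lab6 <- label_clusters(m2, 6L)
  lab18b <- label_clusters(m2, 18L)
  expect_gt(length(attr(lab6, "sizes")), length(attr(lab18b, "sizes")))
})

test_that("cluster FWE finds a planted blob and returns empty tables cleanly", {
  set.seed(8)
  dims <- c(10, 10, 10)
  mask <- array(TRUE, dims)
  n <- 12L
  y <- matrix(rnorm(n * prod(dims), sd = 0.05), n)
  blob <- array(FALSE, dims); blob[4:6, 4:6, 4:6] <- TRUE
  scores <- rnorm(n)
  y[, as.vector(blob)] <- y[, as.vector(blob)] +
    outer(scores, rep(0.5, sum(blob)))  # strong correlation in the blob
  res <- cluster_fwe(y, mask, scores = scores, forming_p = 0.001,
                     n_perm = 300, seed = 9L)
  expect_gte(sum(res$table$significant), 1L)
  top <- res$table[1, ]
  expect_equal(top$extent, 27L, tolerance = 3)
  expect_true(res$mask[5, 5, 5])
  # no supra-threshold voxels -> valid empty table
  y0 <- matrix(rnorm(n * prod(dims), sd = 1), n)
  res0 <- cluster_fwe(y0, mask, scores = scores, forming_p = 1e-6,
                      n_perm = 100, seed = 10L)
  expect_equal(nrow(res0$table), 0L)
  expect_false(any(res0$mask))
})

test_that("conjunction is the voxelwise AND with the stated fraction", {
  a <- array(FALSE, c(10, 10, 10)); a[1:5, , 1] <- TRUE
  b <- array(FALSE, c(10, 10, 10)); b[6:10, , 1] <- TRUE
  expect_equal(conjunction(a, b, 1000)$fraction, 0)
  m_120 <- array(FALSE, c(10, 10, 10)); m_120[, 1:2, 1:6] <- TRUE  # 120 voxels
  expect_equal(conjunction(m_120, m_120, 1000)$fraction, 0.12)
  expect_error(conjunction(a, array(TRUE, c(5, 5, 5)), 10), "geometry")
})

test_that("lowering alpha never grows a significance mask", {
  set.seed(11)
  n <- 10L
  y <- matrix(rnorm(n * 300, mean = 0.28, sd = 0.05), n)
  masks <- lapply(c(0.2, 0.05, 0.01), function(a)
    voxel_fwe(y, null = 0.25, alpha = a, n_perm = 300, seed = 12L)$mask)
  expect_true(all(masks[[2]] <= masks[[1]]))
  expect_true(all(masks[[3]] <= masks[[2]]))
})
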