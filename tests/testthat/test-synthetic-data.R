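# synthetic-data module: determinism, camera-noise calibration, scene
# ground truth, band-limited fixtures, pair-cycle tables.

test_that("identical params and seed give bit-identical outputs", {
  sp <- scene_params(n_frames = 3L, n_clusters = 2L, seed = 11L)
  s1 <- render_scene(sp); s2 <- render_scene(sp)
  expect_identical(s1$ser5p, s2$ser5p)
  expect_identical(s1$truth, s2$truth)

  np <- noise_params(50, 200, seed = 5L)
  expect_identical(apply_noise(matrix(3, 4, 4), np),
                   apply_noise(matrix(3, 4, 4), np))

  pt1 <- make_pair_table(pair_cycle_params(n_pairs = 8L, seed = 2L))
  pt2 <- make_pair_table(pair_cycle_params(n_pairs = 8L, seed = 2L))
  expect_identical(pt1$table, pt2$table)
  expect_equal(nrow(pt1$table), 8L)

  clean <- array(stats::runif(4 * 8 * 8, 0, 50), dim = c(4, 8, 8))
  a1 <- make_acquisition_set(clean, np)
  a2 <- make_acquisition_set(clean, np)
  expect_identical(a1$phase_a, a2$phase_a)
  expect_identical(a1$phase_b, a2$phase_b)
})

test_that("camera noise matches the Poisson-Gaussian model within 3 SE", {
  n <- 10000L
  clean <- array(20, dim = c(n, 1, 1))
  np <- noise_params(exposure_time_ms = 200, reference_exposure_ms = 200,
                     read_noise_sd = 3, gain = 2, offset = 100, seed = 9L)
  x <- as.vector(apply_noise(clean, np))
  mu <- np$gain * 20 + np$offset
  v <- np$gain^2 * 20 + np$read_noise_sd^2
  expect_lt(abs(mean(x) - mu), 3 * sqrt(v / n))
  # variance of sample variance ~ 2 v^2 / (n-1) for near-normal counts
  expect_lt(abs(stats::var(x) - v), 3 * sqrt(2 * v^2 / (n - 1)))

  # halving the exposure halves the expected signal above offset
  np2 <- noise_params(100, 200, read_noise_sd = 3, gain = 2,
                      offset = 100, seed = 10L)
  x2 <- as.vector(apply_noise(clean, np2))
  expect_lt(abs(mean(x2) - (np$gain * 10 + np$offset)),
            3 * sqrt((np$gain^2 * 10 + 9) / n))

  # degenerate cases and input validation
  z <- apply_noise(array(0, dim = c(5, 5, 1)),
                   noise_params(50, 200, read_noise_sd = 0, offset = 7))
  expect_true(all(z == 7))
  expect_error(apply_noise(matrix(-1, 2, 2), np), "non-negative")
})

test_that("rendered scene follows the configured cycle and lags", {
  sp <- scene_params(n_frames = 36L, n_clusters = 1L,
                     frame_interval_s = 1, seed = 3L)
  sc <- render_scene(sp)
  tr <- sc$truth[order(sc$truth$frame), ]
  # Ser2P true series equals the Ser5P series delayed by lag_ser2p
  lag_frames <- sp$lag_ser2p_s / sp$frame_interval_s
  n <- nrow(tr)
  expect_equal(tr$ser2p_true[(lag_frames + 1):n],
               tr$ser5p_true[1:(n - lag_frames)], tolerance = 1e-12)
  # shape driver lags Ser5P by lag_shape
  i_peak5 <- which.max(tr$ser5p_true)
  i_peak_u <- which.max(tr$shape_driver)
  expect_equal(((tr$t_s[i_peak_u] - tr$t_s[i_peak5]) %% sp$cycle_period_s),
               sp$lag_shape_s, tolerance = sp$frame_interval_s)
  # ground-truth labels are one connected component per cluster
  lab <- array(sc$labels[1, , , ], dim = sp$volume_shape)
  cc <- segment_clusters(array(1000 * (lab > 0), dim = dim(lab)),
                         smoothing_sigma = 0, min_volume_vox = 1)
  expect_equal(max(cc), 1L)
})

test_that("rendered masks reproduce configured shape within tolerance", {
  # spherical frames: elongation ~ 1
  sp <- scene_params(n_frames = 2L, n_clusters = 1L, elongation_max = 1,
                     bend_max = 0, cluster_radius_nm = 800, seed = 4L)
  sc <- render_scene(sp)
  co <- which(array(sc$labels[1, , , ], dim = sp$volume_shape) == 1L,
              arr.ind = TRUE)
  expect_lt(abs(elongation(co, sp$voxel_size_nm) - 1), 0.05)

  # elongated frames: measured elongation tracks the configured value
  sp2 <- scene_params(n_frames = 18L, n_clusters = 1L, bend_max = 0,
                      cluster_radius_nm = 500, frame_interval_s = 2,
                      seed = 4L)
  sc2 <- render_scene(sp2)
  tr <- sc2$truth
  fi <- tr$frame[which.max(tr$elongation_true)]
  co2 <- which(array(sc2$labels[fi, , , ], dim = sp2$volume_shape) == 1L,
               arr.ind = TRUE)
  expect_lt(abs(elongation(co2, sp2$voxel_size_nm) -
                  max(tr$elongation_true)) / max(tr$elongation_true),
            0.07)
})

test_that("cluster placement failure names the constraint", {
  expect_error(render_scene(scene_params(volume_shape = c(6L, 20L, 20L),
                                         n_frames = 2L)),
               "too small|overlap")
})

test_that("band-limited pair honors its contract", {
  # zero noise: identical images
  bp <- make_band_limited_pair(c(64, 64), 1 / 400, 100, snr = Inf,
                               seed = 1L)
  expect_identical(bp$img1, bp$img2)
  # spectrum zero above cutoff
  f <- stats::fft(bp$signal)
  n <- 64
  k <- c(0:(n / 2), -(n / 2 - 1):-1)
  fr <- sqrt(outer((k / (n * 100))^2, (k / (n * 100))^2, `+`))
  expect_lt(max(Mod(f)[fr > 1 / 400 + 1e-12]) / max(Mod(f)), 1e-10)
  # cutoff above Nyquist rejected
  expect_error(make_band_limited_pair(c(64, 64), 1 / 150, 100),
               "Nyquist")
})

test_that("acquisition sets have the stated phase-A/B structure", {
  clean <- array(stats::runif(2 * 16 * 16, 0, 50), dim = c(2, 16, 16))
  np <- noise_params(50, 200, seed = 2L)
  pb <- array(rep(clean, 3), dim = c(2, 16, 16, 3))
  pb <- aperm(pb, c(4, 1, 2, 3))
  set <- make_acquisition_set(clean, np, phase_b_clean = pb)
  expect_length(set$phase_a, 5L)  # 1 low + 2 high + 2 test per plane
  expect_equal(dim(set$phase_b)[1], 3L)
  expect_s3_class(set, "acquisition_set")
  # t_exp = t_ref: test images and references share noise statistics
  np_eq <- noise_params(200, 200, read_noise_sd = 2, seed = 3L)
  clean2 <- array(30, dim = c(1, 64, 64))
  set2 <- make_acquisition_set(clean2, np_eq)
  v_test <- stats::var(as.vector(set2$phase_a$test_1))
  v_ref <- stats::var(as.vector(set2$phase_a$high_quality_1))
  expect_lt(abs(v_test - v_ref) / v_ref, 0.15)
})

test_that("pair tables lie on the configured cycle", {
  # noise-free, two features 90 degrees apart: exact circle
  p <- pair_cycle_params(
    n_pairs = 50L, feature_amplitudes = c(a = 1, b = 1),
    feature_phase_offsets = c(a = 0, b = pi / 2),
    noise_sd = 0, baseline = 0, seed = 6L)
  pt <- make_pair_table(p)
  r2 <- pt$table$a^2 + pt$table$b^2
  expect_equal(r2, rep(1, 50), tolerance = 1e-10)
  expect_equal(pt$table$a, cos(pt$true_phase), tolerance = 1e-12)
  # degenerate offsets warn
  expect_warning(pair_cycle_params(
    feature_amplitudes = c(a = 1, b = 1),
    feature_phase_offsets = c(a = 1, b = 1)), "degenerate")
})
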