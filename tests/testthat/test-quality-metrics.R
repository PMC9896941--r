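# quality_metrics module: SSIM structural term, FRC, effective resolution,
# exposure sweep.

test_that("structural SSIM identities, symmetry and bounds hold", {
  set.seed(1)
  x <- matrix(stats::rnorm(30 * 30), 30)
  y <- matrix(stats::rnorm(30 * 30), 30)
  expect_equal(ssim_structural(x, x)$global_value, 1)
  expect_equal(ssim_structural(x, x + 17.3)$global_value, 1)
  sxy <- ssim_structural(x, y)
  expect_equal(sxy$global_value, ssim_structural(y, x)$global_value)
  expect_true(all(sxy$local_map >= -1 & sxy$local_map <= 1))
  expect_identical(dim(sxy$local_map), dim(x))
  expect_error(ssim_structural(x, y[1:10, 1:10]), "mismatch")
  expect_error(ssim_structural(x, y, window = 4), "odd")
})

test_that("3x3 worked case matches the direct covariance oracle", {
  x <- rbind(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9))
  y <- x[, 3:1]
  s <- ssim_structural(x, y, window = 3, c3 = 0)
  # center window is the full 3x3; oracle value frozen from hand
  # computation: cov = 48/9, var = 60/9 each -> 2*cov / (2*var) = 0.8
  expect_equal(s$local_map[2, 2], 0.8, tolerance = 1e-12)
  expect_equal(s$local_map[2, 2], oracle_ssim_window(x, y),
               tolerance = 1e-12)
})

test_that("FRC ring sums match the brute-force coordinate loop", {
  set.seed(7)
  for (n in c(6, 8)) {
    a <- matrix(stats::rnorm(n * n), n)
    b <- matrix(stats::rnorm(n * n), n)
    fc <- frc_curve(a, b, pixel_size_nm = 100, window_fn = "none")
    expect_equal(fc$correlations, oracle_frc(a, b), tolerance = 1e-12)
  }
})

test_that("FRC identities: self-correlation, symmetry, DC ring", {
  set.seed(2)
  a <- matrix(stats::runif(64 * 64, 10, 60), 64)
  b <- a + matrix(stats::rnorm(64 * 64), 64)
  expect_equal(frc_curve(a, a, 100)$correlations,
               rep(1, 33), tolerance = 1e-9)
  expect_equal(frc_curve(a, b, 100)$correlations,
               frc_curve(b, a, 100)$correlations, tolerance = 1e-12)
  fc <- frc_curve(a, b, 100)
  expect_equal(fc$correlations[1], 1, tolerance = 1e-6)  # DC ring
  expect_true(all(diff(fc$ring_frequencies) > 0))
  expect_lte(max(fc$ring_frequencies), 1 / 200 + 1e-12)
  expect_error(frc_curve(a * 0, a, 100), "all-zero")
  expect_warning(frc_curve(a[, 1:32], b[, 1:32], 100), "cropped")
})

test_that("effective resolution interpolates the first 1/7 crossing", {
  mk <- function(corr, freq, px = 100)
    structure(list(ring_frequencies = freq, correlations = corr,
                   threshold = 1 / 7, pixel_size_nm = px, n = 64,
                   bin_width = 1L), class = "frc_curve")
  # constant 1: unresolved sentinel with Nyquist bound 2 * pixel size
  r <- effective_resolution(mk(rep(1, 10), (0:9) / 6400))
  expect_equal(r$status, "unresolved-at-nyquist")
  expect_equal(r$value_nm, 200)
  # step from 1 to 0 between rings 3 and 4: hand interpolation
  freq <- (0:9) / 6400
  corr <- c(1, 1, 1, 1, 0, 0, 0, 0, 0, 0)
  f_cross <- freq[4] + (1 / 7 - 1) * (freq[5] - freq[4]) / (0 - 1)
  r2 <- effective_resolution(mk(corr, freq))
  expect_equal(r2$status, "resolved")
  expect_equal(r2$value_nm, 1 / f_cross, tolerance = 1e-12)
  # starting below threshold is unresolvable, not an error
  r3 <- effective_resolution(mk(c(0.1, 0.05, 0), freq[1:3]))
  expect_equal(r3$status, "unresolvable")
  expect_true(is.na(r3$value_nm))
})

test_that("white-noise pairs decorrelate and band limits are recovered", {
  # two independent white-noise images: ring mean within 3 SE of 0
  vals <- unlist(lapply(1:5, function(sd) {
    bp <- make_band_limited_pair(c(128, 128), 1 / 300, 100, snr = 0,
                                 seed = sd)
    frc_curve(bp$img1, bp$img2, 100, window_fn = "none")$correlations[-1]
  }))
  expect_lt(abs(mean(vals)), 3 * stats::sd(vals) / sqrt(length(vals)))

  # high-SNR band-limited pair: ~1 below cutoff, ~0 above
  bp <- make_band_limited_pair(c(256, 256), 1 / 400, 100, snr = 50,
                               seed = 3)
  fc <- frc_curve(bp$img1, bp$img2, 100, window_fn = "none")
  below <- fc$ring_frequencies < 1 / 400 - 2 / 25600
  above <- fc$ring_frequencies > 1 / 400 + 2 / 25600
  expect_gt(min(fc$correlations[below][-1]), 0.9)
  expect_lt(mean(abs(fc$correlations[above])), 0.1)
})

test_that("median resolution does not improve with more read noise", {
  sp <- scene_params(n_frames = 2L, seed = 8L)
  clean_plane <- render_scene(sp)$ser5p[1, 8, , ]
  res_at <- function(rn) {
    vapply(1:10, function(sd) {
      np <- noise_params(200, 200, read_noise_sd = rn, seed = sd)
      i1 <- apply_noise(clean_plane, np, seed = sd)
      i2 <- apply_noise(clean_plane, np, seed = sd + 1000L)
      r <- effective_resolution(frc_curve(i1, i2, 100))
      if (r$status == "unresolvable") Inf else r$value_nm
    }, 0)
  }
  expect_gte(stats::median(res_at(40)), stats::median(res_at(2)))
})

test_that("exposure sweep reports one row per level and handles identity", {
  sp <- scene_params(n_frames = 2L, seed = 12L)
  clean <- array(render_scene(sp)$ser5p[1, , , ], dim = sp$volume_shape)
  sets <- lapply(c(20, 100), function(texp)
    make_acquisition_set(clean, noise_params(texp, 200, seed = texp)))
  names(sets) <- c("20", "100")
  rep_id <- exposure_sweep_report(sets, denoiser_identity(), 100)
  expect_equal(nrow(rep_id), 2L)
  # identity denoiser: reconstructed trend equals the raw trend
  expect_equal(rep_id$resolution_reconstructed_nm,
               rep_id$resolution_raw_nm)
  expect_error(exposure_sweep_report(sets[1], denoiser_identity(), 100),
               ">= 2 exposure levels")
  # a broken position yields an NA row and a warning, sweep continues
  sets_bad <- c(sets, list(bad = "not a set"))
  expect_warning(rep2 <- exposure_sweep_report(sets_bad,
                                               denoiser_identity(), 100),
                 "failed")
  expect_equal(nrow(rep2), 3L)
  expect_equal(sum(is.na(rep2$resolution_raw_nm)), 1L)
})
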