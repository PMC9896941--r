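# fluctuation_analysis module: normalization, lagged correlation,
# bootstrap aggregation, extrema extraction.

test_that("track normalization is exact and affine-invariant", {
  z <- normalize_track(c(1, 2, 3))
  expect_equal(mean(z), 0)
  expect_equal(stats::sd(z), 1)
  x <- stats::rnorm(50)
  expect_equal(normalize_track(3.2 * x + 7), normalize_track(x),
               tolerance = 1e-12)
  expect_equal(normalize_track(normalize_track(x)), normalize_track(x),
               tolerance = 1e-12)
  expect_error(normalize_track(rep(2, 10)), "constant")
  expect_error(normalize_track(c(1, 2)), ">= 3")
})

test_that("lagged correlation finds constructed shifts and handles
          overlap", {
  x <- stats::rnorm(60)
  lc <- lagged_correlation(x, x, max_lag = 5)
  expect_equal(unname(lc["0"]), 1)
  # shifted sinusoid: argmax exactly at the shift
  t <- seq_len(400)
  a <- sin(2 * pi * t / 40)
  delta <- 4L
  b <- sin(2 * pi * (t - delta) / 40)
  lc2 <- lagged_correlation(a, b, max_lag = 10)
  expect_equal(as.integer(names(which.max(lc2))), delta)
  # independent white noise, 1e4 points: all |r| < 0.05
  set.seed(4)
  lc3 <- lagged_correlation(stats::rnorm(1e4), stats::rnorm(1e4),
                            max_lag = 5)
  expect_lt(max(abs(lc3)), 0.05)
  # insufficient overlap: NA, not zero
  lc4 <- lagged_correlation(stats::rnorm(5), stats::rnorm(5),
                            max_lag = 4)
  expect_true(is.na(lc4["4"]))
  expect_false(is.na(lc4["0"]))
})

test_that("bootstrap aggregation degenerate cases behave", {
  curve <- sin(seq(-1, 1, length.out = 11))
  same <- rbind(curve, curve, curve)
  agg <- aggregate_with_bootstrap(same, n_bootstrap = 200, seed = 1)
  expect_equal(agg$mean, curve, ignore_attr = TRUE)
  expect_equal(agg$ci_high - agg$ci_low, rep(0, 11),
               ignore_attr = TRUE)
  opp <- rbind(curve, -curve)
  expect_equal(aggregate_with_bootstrap(opp, 200, seed = 1)$mean,
               rep(0, 11), ignore_attr = TRUE)
  expect_error(aggregate_with_bootstrap(rbind(curve), 200), ">= 2")
  expect_warning(aggregate_with_bootstrap(same, n_bootstrap = 50),
                 "low")
  # ci_low <= mean <= ci_high pointwise
  set.seed(2)
  m <- matrix(stats::rnorm(8 * 11), 8)
  a2 <- aggregate_with_bootstrap(m, 300, seed = 3)
  expect_true(all(a2$ci_low <= a2$mean + 1e-12))
  expect_true(all(a2$ci_high >= a2$mean - 1e-12))
})

test_that("extrema extraction applies the smallest-|lag|-then-negative
          tie rule", {
  lags <- -3:3
  curve <- c(0, 0.5, 0, 1, 0, 0.5, 0)  # max unique at 0? no: at lag 0
  expect_equal(extract_extrema(c(0, 0, 0, 0, 1, 0, 0), lags)$max_lag, 1)
  # symmetric ties at +-2: negative wins
  tie <- c(0, 0.8, 0, 0.1, 0, 0.8, 0)
  expect_equal(extract_extrema(tie, lags)$max_lag, -2)
  expect_error(extract_extrema(rep(NA_real_, 7), lags), "all-missing")
})

test_that("anchored cross-correlation: unit anchor autocorrelation and
          affine invariance", {
  set.seed(11)
  mk_track <- function(id, scale = 1, shift = 0) {
    t <- seq_len(40)
    e <- sin(2 * pi * t / 18 + id) + 0.1 * stats::rnorm(40)
    data.frame(track_id = id, frame = t,
               elongation = e,
               ser5p_mean = scale * (sin(2 * pi * (t + 3) / 18 + id) +
                                       0.1 * stats::rnorm(40)) + shift)
  }
  tracks <- rbind(mk_track(1), mk_track(2), mk_track(3))
  xc <- cross_correlate_tracks(tracks,
                               signals = c("elongation", "ser5p_mean"),
                               anchor = "elongation",
                               frame_interval_s = 1, max_lag_s = 8,
                               n_bootstrap = 150, seed = 5)
  self <- xc$signals$elongation
  expect_equal(unname(self$mean[xc$lags_s == 0]), 1)
  expect_true(all(abs(self$curves[, xc$lags_s == 0] - 1) < 1e-12))
  expect_true(all(abs(xc$signals$ser5p_mean$mean) <= 1 + 1e-12))
  # per-track affine transforms leave curves unchanged
  tracks2 <- tracks
  tracks2$ser5p_mean <- ifelse(tracks2$track_id == 1,
                               5 * tracks2$ser5p_mean + 100,
                               tracks2$ser5p_mean)
  xc2 <- cross_correlate_tracks(tracks2,
                                signals = c("elongation", "ser5p_mean"),
                                anchor = "elongation",
                                frame_interval_s = 1, max_lag_s = 8,
                                n_bootstrap = 150, seed = 5)
  expect_equal(xc2$signals$ser5p_mean$mean, xc$signals$ser5p_mean$mean,
               tolerance = 1e-10)
})
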