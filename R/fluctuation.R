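# Time-shifted cross-correlation of cluster properties over tracks, with
# percentile-bootstrap confidence bands. Series are z-scored per track
# (Pearson correlation is then invariant to per-track affine intensity
# transforms), lags are restricted to the valid overlap, and the bootstrap
# resamples whole tracks so within-track autocorrelation is preserved.
# Sign convention: a positive lag means the signal's event FOLLOWS the
# anchor's.

#' Z-score a track series
#'
#' @param x numeric series, length >= 3, non-constant.
#' @return series with mean 0 and (sample) SD 1.
#' @export
normalize_track <- function(x) {
  if (length(x) < 3L) stopf("series length must be >= 3")
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) stopf("constant series cannot be normalized")
  (x - mean(x)) / s
}

#' Per-lag Pearson correlation of two equal-length series
#'
#' Value at lag k correlates anchor(t) with signal(t + k) over the
#' overlapping segment; lags whose overlap has fewer than `min_overlap`
#' points (or zero variance) are NA, not zero.
#'
#' @param anchor,signal equal-length numeric series from one track.
#' @param max_lag maximum |lag| in frames.
#' @param min_overlap minimum points per evaluated lag.
#' @return named numeric vector over lags -max_lag..max_lag.
#' @export
lagged_correlation <- function(anchor, signal, max_lag,
                               min_overlap = 3L) {
  n <- length(anchor)
  if (length(signal) != n) stopf("series length mismatch")
  assert_scalar_num(max_lag, "max_lag", lower = 0, integer = TRUE)
  lags <- -max_lag:max_lag
  vals <- vapply(lags, function(k) {
    t0 <- max(1L, 1L - k); t1 <- min(n, n - k)
    if (t1 - t0 + 1L < min_overlap) return(NA_real_)
    a <- anchor[t0:t1]; b <- signal[(t0 + k):(t1 + k)]
    if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
    stats::cor(a, b)
  }, 0)
  names(vals) <- lags
  vals
}

#' Mean cross-correlation curve with a percentile bootstrap band
#'
#' @param curves matrix, one row per track, one column per lag (NAs for
#'   lags without valid overlap are omitted from means).
#' @param n_bootstrap bootstrap resamples of whole tracks (>= 100 advised).
#' @param alpha two-sided band level (default 95% band).
#' @param seed integer seed for resampling.
#' @return list: `mean`, `ci_low`, `ci_high` (pointwise, clipped to
#'   contain the mean), `n_tracks`, `n_bootstrap`.
#' @export
aggregate_with_bootstrap <- function(curves, n_bootstrap = 1000L,
                                     alpha = 0.05, seed = 1L) {
  curves <- as.matrix(curves)
  n_tracks <- nrow(curves)
  if (n_tracks < 2L) stopf("need >= 2 tracks")
  if (n_bootstrap < 100L)
    warnf("n_bootstrap = %d is low; percentile bands will be coarse",
          n_bootstrap)
  m <- colMeans(curves, na.rm = TRUE)
  boot <- with_seed(seed, {
    vapply(seq_len(n_bootstrap), function(b) {
      colMeans(curves[sample.int(n_tracks, n_tracks, replace = TRUE), ,
                      drop = FALSE], na.rm = TRUE)
    }, m)
  })
  if (is.null(dim(boot))) boot <- matrix(boot, nrow = 1L)
  qs <- apply(boot, 1L, stats::quantile,
              probs = c(alpha / 2, 1 - alpha / 2), na.rm = TRUE)
  list(mean = m, ci_low = pmin(qs[1L, ], m), ci_high = pmax(qs[2L, ], m),
       n_tracks = n_tracks, n_bootstrap = as.integer(n_bootstrap))
}

#' Anchored cross-correlation analysis over tracks
#'
#' Builds per-track lagged correlation curves of each signal against the
#' anchor (default: elongation), then aggregates with a track bootstrap.
#' Tracks shorter than `min_length`, or constant in the anchor or signal,
#' are excluded with a message.
#'
#' @param tracks data.frame from [track_clusters()] with `track_id`,
#'   `frame`, and the signal columns.
#' @param signals character, columns to correlate against the anchor.
#' @param anchor anchor column name.
#' @param frame_interval_s seconds per frame (lag axis scaling).
#' @param max_lag_s maximum |lag| in seconds (default 30 s).
#' @param detrend remove a linear trend per series before correlating
#'   (off by default).
#' @param min_length minimum track length in frames.
#' @inheritParams aggregate_with_bootstrap
#' @return object of class `cross_correlation`: `lags_s`, per-signal
#'   `curves` (track x lag), `mean`, `ci_low`, `ci_high`, `n_tracks`.
#' @export
cross_correlate_tracks <- function(tracks, signals = c("ser5p_mean",
                                                       "ser2p_mean",
                                                       "solidity"),
                                   anchor = "elongation",
                                   frame_interval_s = 1,
                                   max_lag_s = 30, n_bootstrap = 1000L,
                                   alpha = 0.05, seed = 1L,
                                   detrend = FALSE, min_length = 10L) {
  stopifnot(all(c("track_id", "frame", anchor, signals) %in%
                  names(tracks)))
  max_lag <- as.integer(round(max_lag_s / frame_interval_s))
  prep <- function(x) {
    if (detrend) x <- stats::residuals(stats::lm(x ~ seq_along(x)))
    normalize_track(x)
  }
  ids <- unique(tracks$track_id)
  per_signal <- stats::setNames(
    lapply(signals, function(s) list()), signals)
  used <- 0L
  for (id in ids) {
    tr <- tracks[tracks$track_id == id, , drop = FALSE]
    tr <- tr[order(tr$frame), , drop = FALSE]
    if (nrow(tr) < min_length) next
    a <- tryCatch(prep(tr[[anchor]]), error = function(e) NULL)
    if (is.null(a)) {
      message("track ", id, " excluded: constant anchor series")
      next
    }
    any_used <- FALSE
    # a constant series drops this track for that signal only
    for (j in seq_along(signals)) {
      b <- tryCatch(prep(tr[[signals[j]]]), error = function(e) NULL)
      if (is.null(b)) {
        message("track ", id, " excluded for '", signals[j],
                "': constant series")
        next
      }
      any_used <- TRUE
      per_signal[[j]][[length(per_signal[[j]]) + 1L]] <-
        lagged_correlation(a, b, max_lag)
    }
    if (any_used) used <- used + 1L
  }
  n_per_signal <- lengths(per_signal)
  if (any(n_per_signal < 2L))
    stopf("fewer than 2 usable tracks for signal(s): %s",
          paste(signals[n_per_signal < 2L], collapse = ", "))
  lags_s <- (-max_lag:max_lag) * frame_interval_s
  res <- lapply(seq_along(signals), function(j) {
    cm <- do.call(rbind, per_signal[[j]])
    agg <- aggregate_with_bootstrap(cm, n_bootstrap, alpha,
                                    seed = derive_seed(seed, j))
    c(list(curves = cm), agg)
  })
  names(res) <- signals
  structure(list(anchor = anchor, lags_s = lags_s, signals = res,
                 n_tracks = used, frame_interval_s = frame_interval_s),
            class = "cross_correlation")
}

#' @export
print.cross_correlation <- function(x, ...) {
  cat(sprintf("Cross-correlation anchored on '%s' (%d tracks, lags %g..%g s)\n",
              x$anchor, x$n_tracks, min(x$lags_s), max(x$lags_s)))
  for (s in names(x$signals)) {
    ex <- extract_extrema(x$signals[[s]]$mean, x$lags_s)
    cat(sprintf("  %s: max at %+g s, min at %+g s\n", s,
                ex$max_lag, ex$min_lag))
  }
  invisible(x)
}

#' Lags of the global extrema of a mean correlation curve
#'
#' Ties are broken toward the smallest |lag|, then toward the negative lag.
#'
#' @param mean_curve numeric curve over lags (NAs allowed).
#' @param lags_s lag axis, same length.
#' @return list with `max_lag`, `min_lag` (seconds) and the curve values
#'   there.
#' @export
extract_extrema <- function(mean_curve, lags_s) {
  stopifnot(length(mean_curve) == length(lags_s))
  ok <- which(is.finite(mean_curve))
  if (length(ok) == 0L) stopf("all-missing curve")
  pick <- function(target) {
    cand <- ok[mean_curve[ok] == target]
    cand[order(abs(lags_s[cand]), lags_s[cand])][1L]
  }
  i_max <- pick(max(mean_curve[ok]))
  i_min <- pick(min(mean_curve[ok]))
  list(max_lag = lags_s[i_max], max_value = mean_curve[i_max],
       min_lag = lags_s[i_min], min_value = mean_curve[i_min])
}
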