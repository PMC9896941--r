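# Pseudo-time reconstruction from fixed-sample gene-cluster interaction
# pairs: nearest-cluster pairing, z-scored feature matrix, PCA, angle of
# the first two principal components via atan2, division by 2*pi into a
# periodic coordinate s in [0, 1). The coordinate is defined only up to
# circular rotation and reflection (the PCA sign/rotation gauge); recovery
# scoring is gauge-invariant via circular correlation.

#' Build gene-cluster interaction pairs
#'
#' One pair per gene focus: the Ser5P cluster of the same nucleus that is
#' closest in 3D physical space. Ties go to the lowest cluster id (logged);
#' foci in nuclei without any cluster are dropped with a logged count.
#'
#' @param foci data.frame: `nucleus_id`, `gene_id`, `z_nm`, `y_nm`,
#'   `x_nm`, plus any `gene_*` intensity columns to carry along.
#' @param clusters data.frame: `nucleus_id`, `cluster_id`, `z_nm`, `y_nm`,
#'   `x_nm`, plus feature columns (e.g. `ser5p_mean`, `ser2p_mean`,
#'   `elongation`, `solidity`).
#' @return data.frame, one row per retained focus: focus columns,
#'   `cluster_id`, cluster features, `distance_nm`.
#' @export
build_pairs <- function(foci, clusters) {
  stopifnot(all(c("nucleus_id", "gene_id", "z_nm", "y_nm", "x_nm") %in%
                  names(foci)),
            all(c("nucleus_id", "cluster_id", "z_nm", "y_nm", "x_nm") %in%
                  names(clusters)))
  dropped <- 0L
  rows <- lapply(seq_len(nrow(foci)), function(i) {
    f <- foci[i, , drop = FALSE]
    cl <- clusters[clusters$nucleus_id == f$nucleus_id, , drop = FALSE]
    if (nrow(cl) == 0L) return(NULL)
    dist <- sqrt((cl$z_nm - f$z_nm)^2 + (cl$y_nm - f$y_nm)^2 +
                   (cl$x_nm - f$x_nm)^2)
    best <- which(dist == min(dist))
    if (length(best) > 1L) {
      best <- best[order(cl$cluster_id[best])][1L]
      message("focus ", f$gene_id, "/", f$nucleus_id,
              ": equidistant clusters, tie broken to lowest cluster_id")
    }
    feat <- cl[best, setdiff(names(cl),
                             c("nucleus_id", "z_nm", "y_nm", "x_nm")),
               drop = FALSE]
    cbind(f, feat, data.frame(distance_nm = dist[best]),
          row.names = NULL)
  })
  keep <- !vapply(rows, is.null, TRUE)
  if (any(!keep))
    message(sum(!keep), " focus/foci dropped: no cluster in nucleus")
  if (!any(keep))
    return(NULL)
  out <- do.call(rbind, rows[keep])
  rownames(out) <- NULL
  out
}

#' Standardized feature matrix of interaction pairs
#'
#' Columns are z-scored; zero-variance features are dropped with a
#' warning. Centering/scaling parameters are stored as attributes so new
#' pairs can be projected consistently.
#'
#' @param pairs data.frame of pairs.
#' @param features character vector of feature column names. Default: all
#'   of `gene_intensity`-prefixed columns, cluster intensities, distance
#'   and shape that are present.
#' @export
feature_matrix <- function(pairs, features = NULL) {
  if (is.null(features)) {
    canonical <- c("ser5p_mean", "ser2p_mean", "distance_nm",
                   "elongation", "solidity")
    features <- c(grep("^gene_", names(pairs), value = TRUE),
                  intersect(canonical, names(pairs)))
    features <- setdiff(features, "gene_id")
  }
  if (nrow(pairs) < 8L) stopf("need >= 8 pairs, got %d", nrow(pairs))
  missing <- setdiff(features, names(pairs))
  if (length(missing) > 0L)
    stopf("features not in pairs: %s", paste(missing, collapse = ", "))
  m <- as.matrix(pairs[, features, drop = FALSE])
  sds <- apply(m, 2L, stats::sd)
  if (any(sds == 0)) {
    warnf("zero-variance feature(s) dropped: %s",
          paste(features[sds == 0], collapse = ", "))
    m <- m[, sds > 0, drop = FALSE]
    sds <- sds[sds > 0]
  }
  if (ncol(m) < 2L) stopf("need >= 2 usable features")
  ctr <- colMeans(m)
  z <- sweep(sweep(m, 2L, ctr), 2L, sds, `/`)
  attr(z, "center") <- ctr
  attr(z, "scale") <- sds
  z
}

#' Periodic pseudo-time coordinate from a feature matrix
#'
#' PCA by singular value decomposition of the centered matrix; the angle
#' atan2(PC2, PC1) divided by 2*pi, wrapped into [0, 1) (negative angles
#' get +1).
#'
#' @param fm matrix from [feature_matrix()].
#' @return object of class `pseudo_time`: `pc1`, `pc2`, `angle`
#'   (radians in [0, 2*pi)), `s` in [0, 1), `ordering` (circular rank),
#'   `explained` (variance shares of all PCs), `rotation`.
#' @export
pseudo_time <- function(fm) {
  fm <- as.matrix(fm)
  pc <- stats::prcomp(fm, center = TRUE, scale. = FALSE)
  if (length(pc$sdev) < 2L || pc$sdev[2L] < 1e-12 * pc$sdev[1L])
    stopf("no cyclic plane: feature matrix has rank < 2")
  pc1 <- pc$x[, 1L]; pc2 <- pc$x[, 2L]
  ang <- atan2(pc2, pc1)
  s <- ang / (2 * pi)
  s <- s - floor(s)            # wrap into [0, 1)
  structure(list(pc1 = pc1, pc2 = pc2, angle = s * 2 * pi, s = s,
                 ordering = order(s),
                 explained = pc$sdev^2 / sum(pc$sdev^2),
                 rotation = pc$rotation, center = pc$center),
            class = "pseudo_time")
}

#' @export
print.pseudo_time <- function(x, ...) {
  cat(sprintf(paste0("Pseudo-time over %d pairs; PC1+PC2 explain %.0f%%",
                     " of variance\n"),
              length(x$s), 100 * sum(x$explained[1:2])))
  invisible(x)
}

#' Feature profiles ordered by pseudo-time
#'
#' Sorts pairs by s and optionally applies a circular moving average
#' (window in pairs; window 1 = raw sorted values). Default window
#' max(5, n/40), mirroring a light smoothing of ~2.5% of the cycle.
#'
#' @param pairs data.frame containing the feature columns.
#' @param s pseudo-time coordinate per pair (or a `pseudo_time` object).
#' @param features columns to profile.
#' @param window odd circular smoothing window in pairs; NULL for the
#'   default.
#' @return list: `s` (sorted), `profiles` (data.frame of smoothed
#'   features in s-order), `order` (row permutation), `window`.
#' @export
order_profiles <- function(pairs, s, features, window = NULL) {
  if (inherits(s, "pseudo_time")) s <- s$s
  stopifnot(length(s) == nrow(pairs),
            all(features %in% names(pairs)))
  n <- length(s)
  window <- window %||% max(5L, round(n / 40))
  window <- max(1L, as.integer(window))
  if (window %% 2L == 0L) window <- window + 1L
  ord <- order(s)
  prof <- lapply(features, function(f)
    circular_smooth(pairs[[f]][ord], window))
  names(prof) <- features
  list(s = s[ord], profiles = as.data.frame(prof), order = ord,
       window = window)
}

circular_smooth <- function(x, window) {
  if (window <= 1L) return(x)
  n <- length(x)
  r <- (window - 1L) %/% 2L
  xp <- c(x[(n - r + 1L):n], x, x[1L:r])
  as.vector(stats::filter(xp, rep(1 / window, window),
                          sides = 2L))[(r + 1L):(r + n)]
}

#' Register-shift correlation of pseudo-time-ordered profiles
#'
#' Circularly shifts each feature profile by k data points along the
#' s-ordering and reports the Pearson correlation with the anchor profile,
#' with a percentile bootstrap band over pairs (the bootstrap resamples
#' pairs with replacement and re-derives the ordered profiles).
#'
#' @param pairs data.frame with feature columns.
#' @param s pseudo-time per pair (or a `pseudo_time` object).
#' @param anchor anchor feature name.
#' @param features features to correlate (default: all profiled).
#' @param max_shift maximum |register shift| in data points (< n).
#' @param window smoothing window passed to [order_profiles()].
#' @param n_bootstrap,alpha,seed bootstrap parameters.
#' @return object of class `register_shift`: `shifts`, per-feature `mean`,
#'   `ci_low`, `ci_high`.
#' @export
register_shift_correlation <- function(pairs, s, anchor, features = NULL,
                                       max_shift = NULL, window = NULL,
                                       n_bootstrap = 1000L, alpha = 0.05,
                                       seed = 1L) {
  if (inherits(s, "pseudo_time")) s <- s$s
  n <- nrow(pairs)
  if (n < 8L) stopf("need >= 8 ordered pairs")
  features <- features %||% setdiff(names(pairs),
                                    c("pair_id", "nucleus_id", "gene_id"))
  features <- union(anchor, features)
  max_shift <- max_shift %||% floor(n / 2)
  if (max_shift >= n) stopf("shift (%d) must be < n_pairs (%d)",
                            max_shift, n)
  shifts <- -max_shift:max_shift
  one <- function(idx) {
    op <- order_profiles(pairs[idx, , drop = FALSE], s[idx], features,
                         window = window)
    av <- op$profiles[[anchor]]
    vapply(features, function(f) {
      pr <- op$profiles[[f]]
      vapply(shifts, function(k) {
        shifted <- circular_shift(pr, k)
        if (stats::sd(av) == 0 || stats::sd(shifted) == 0) NA_real_
        else stats::cor(av, shifted)
      }, 0)
    }, numeric(length(shifts)))
  }
  point <- one(seq_len(n))
  boot <- with_seed(seed, {
    lapply(seq_len(n_bootstrap), function(b)
      one(sample.int(n, n, replace = TRUE)))
  })
  res <- lapply(seq_along(features), function(j) {
    bm <- vapply(boot, function(b) b[, j], numeric(length(shifts)))
    qs <- apply(bm, 1L, stats::quantile,
                probs = c(alpha / 2, 1 - alpha / 2), na.rm = TRUE)
    list(mean = point[, j], ci_low = qs[1L, ], ci_high = qs[2L, ])
  })
  names(res) <- features
  structure(list(anchor = anchor, shifts = shifts, features = res,
                 n_pairs = n, n_bootstrap = as.integer(n_bootstrap)),
            class = "register_shift")
}

circular_shift <- function(x, k) {
  n <- length(x)
  k <- ((k %% n) + n) %% n
  if (k == 0L) x else c(x[(k + 1L):n], x[1L:k])
}

#' Contact-fraction reliability check for a gene's pairs
#'
#' Pseudo-time reconstruction is only meaningful for genes that actually
#' come close to clusters; genes with rare contacts are flagged before any
#' pseudo-time is computed.
#'
#' @param pairs data.frame with `distance_nm`.
#' @param radius_nm contact radius.
#' @param min_fraction minimum share of pairs within the radius.
#' @return list: `pass`, `contact_fraction`, `radius_nm`, `min_fraction`.
#' @export
reliability_check <- function(pairs, radius_nm, min_fraction) {
  stopifnot("distance_nm" %in% names(pairs))
  assert_scalar_num(radius_nm, "radius_nm", lower = 0)
  assert_scalar_num(min_fraction, "min_fraction", lower = 0, upper = 1)
  frac <- mean(pairs$distance_nm <= radius_nm)
  list(pass = frac >= min_fraction, contact_fraction = frac,
       radius_nm = radius_nm, min_fraction = min_fraction)
}

#' Average interaction-cycle duration from pair counts
#'
#' Converts the register-shift distance between the correlation extrema
#' (known to span `seconds_for_those_steps` seconds) into seconds per
#' pseudo-time step, then multiplies each gene's total pair count by it:
#' the average time between two consecutive gene-cluster interaction
#' events, per gene and averaged across genes.
#'
#' @param pair_counts observed interaction pairs per gene (named or not).
#' @param steps_between_extrema register-shift steps between the
#'   correlation maximum and minimum (> 0).
#' @param seconds_for_those_steps seconds that span those steps (> 0).
#' @return list: `seconds_per_step`, `per_gene_s`, `mean_s`.
#' @export
cycle_duration <- function(pair_counts, steps_between_extrema,
                           seconds_for_those_steps) {
  if (!is.numeric(pair_counts) || length(pair_counts) < 1L ||
      any(pair_counts < 1))
    stopf("`pair_counts` must be counts >= 1")
  assert_scalar_num(steps_between_extrema, "steps_between_extrema",
                    lower = 1e-12)
  assert_scalar_num(seconds_for_those_steps, "seconds_for_those_steps",
                    lower = 1e-12)
  sps <- seconds_for_those_steps / steps_between_extrema
  per_gene <- pair_counts * sps
  list(seconds_per_step = sps, per_gene_s = per_gene,
       mean_s = mean(per_gene))
}

#' Circular correlation of two angle vectors
#'
#' Fisher-Lee circular correlation coefficient. Invariant to rotating
#' either input; reflection flips its sign, so gauge-invariant recovery
#' scoring uses the absolute value.
#'
#' @param a,b angles in radians.
#' @export
circular_correlation <- function(a, b) {
  stopifnot(length(a) == length(b))
  sa <- sin(a - circular_mean(a))
  sb <- sin(b - circular_mean(b))
  sum(sa * sb) / sqrt(sum(sa^2) * sum(sb^2))
}

circular_mean <- function(a) atan2(mean(sin(a)), mean(cos(a)))
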