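# Shared raster primitives: separable Gaussian smoothing, box sums via
# integral images, Otsu thresholding, and a small median filter. These are
# deliberately dependency-free; volumes in this workflow are small (tens of
# megavoxels at most).

gaussian_kernel_1d <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(seq(-r, r), sd = sigma)
  k / sum(k)
}

# convolve each column of a matrix with kernel k, replicate-padded edges
conv_cols <- function(m, k) {
  r <- (length(k) - 1L) %/% 2L
  n <- nrow(m)
  mp <- rbind(m[rep(1L, r), , drop = FALSE], m,
              m[rep(n, r), , drop = FALSE])
  out <- matrix(0, n, ncol(m))
  for (j in seq_along(k))
    out <- out + k[j] * mp[j:(j + n - 1L), , drop = FALSE]
  out
}

#' Separable Gaussian smoothing of a 2D or 3D raster
#'
#' @param arr matrix (Y,X) or 3D array (Z,Y,X).
#' @param sigma standard deviation in pixels, one value per axis (recycled).
#'   A zero skips that axis.
#' @return smoothed array, same shape.
#' @export
gaussian_smooth <- function(arr, sigma) {
  d <- dim(arr)
  nd <- length(d)
  sigma <- rep_len(sigma, nd)
  for (ax in seq_len(nd)) {
    if (sigma[ax] <= 0) next
    k <- gaussian_kernel_1d(sigma[ax])
    perm <- c(ax, seq_len(nd)[-ax])
    a <- aperm(arr, perm)
    dd <- dim(a)
    m <- conv_cols(matrix(a, nrow = dd[1L]), k)
    arr <- aperm(array(m, dim = dd), order(perm))
  }
  arr
}

# Sliding-window sums over a matrix with a centered (2r+1) square window,
# truncated at edges. Returns list(sum = S, n = window pixel counts).
box_sums <- function(m, r) {
  n1 <- nrow(m); n2 <- ncol(m)
  cs <- function(x) {
    # column-wise windowed sums via cumulative sums
    cc <- apply(x, 2L, cumsum)
    hi <- pmin(seq_len(nrow(x)) + r, nrow(x))
    lo <- seq_len(nrow(x)) - r - 1L
    up <- cc[hi, , drop = FALSE]
    down <- matrix(0, nrow(x), ncol(x))
    pos <- lo >= 1L
    down[pos, ] <- cc[lo[pos], , drop = FALSE]
    up - down
  }
  s <- t(cs(t(cs(m))))
  ones <- matrix(1, n1, n2)
  cnt <- t(cs(t(cs(ones))))
  list(sum = s, n = cnt)
}

#' Otsu threshold of a numeric sample
#'
#' Maximizes between-class variance over a 256-bin histogram; returns the
#' threshold value (upper edge of the chosen bin). Constant input returns
#' its single value.
#' @param x numeric vector or array.
#' @param n_bins histogram resolution.
#' @export
otsu_threshold <- function(x, n_bins = 256L) {
  x <- as.vector(x)
  if (any(!is.finite(x))) stopf("non-finite values in `x`")
  rng <- range(x)
  if (diff(rng) == 0) return(rng[1L])
  h <- tabulate(pmin(pmax(findInterval(
    x, seq(rng[1L], rng[2L], length.out = n_bins + 1L),
    rightmost.closed = TRUE), 1L), n_bins), n_bins)
  p <- h / sum(h)
  mids <- seq(rng[1L], rng[2L], length.out = n_bins + 1L)
  mids <- (mids[-1L] + mids[-(n_bins + 1L)]) / 2
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[n_bins]
  between <- (mu_t * w0 - mu)^2 / (w0 * (1 - w0))
  between[!is.finite(between)] <- -Inf
  k <- which.max(between)
  # threshold between bin k and k+1
  rng[1L] + diff(rng) * k / n_bins
}

# 3x3 (2D, per plane) median filter, replicate edges; used by the baseline
# median denoiser.
median_filter_plane <- function(m) {
  n1 <- nrow(m); n2 <- ncol(m)
  idx1 <- function(s) pmin(pmax(seq_len(n1) + s, 1L), n1)
  idx2 <- function(s) pmin(pmax(seq_len(n2) + s, 1L), n2)
  stack <- vapply(-1:1, function(dy) vapply(-1:1, function(dx)
    m[idx1(dy), idx2(dx)], m), array(0, c(n1, n2, 3L)))
  dim(stack) <- c(n1 * n2, 9L)
  matrix(apply(stack, 1L, stats::median), n1, n2)
}
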