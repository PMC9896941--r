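# Fourier ring correlation and effective-resolution extraction.
#
# FRC(r) = Re( sum_{r_i in ring r} F1(r_i) * Conj(F2(r_i)) ) /
#          sqrt( sum |F1|^2 * sum |F2|^2 )
#
# over annuli of constant spatial frequency. The effective resolution is
# 1 / f* where f* is the first frequency at which the curve falls below the
# conventional 1/7 threshold (linear interpolation between the bracketing
# rings). Curves that never fall below the threshold are "unresolved at
# Nyquist" with the Nyquist-limited bound 2 * pixel_size attached.

tukey_window_1d <- function(n, alpha) {
  if (alpha <= 0) return(rep(1, n))
  t <- seq(0, 1, length.out = n)
  w <- rep(1, n)
  lo <- t < alpha / 2
  hi <- t > 1 - alpha / 2
  w[lo] <- 0.5 * (1 + cos(pi * (2 * t[lo] / alpha - 1)))
  w[hi] <- 0.5 * (1 + cos(pi * (2 * (1 - t[hi]) / alpha - 1)))
  w
}

#' Fourier ring correlation curve of an image pair
#'
#' Images are tapered (Tukey window, alpha = 0.25, configurable to "none")
#' to suppress edge leakage, Fourier transformed, and correlated over rings
#' of integer frequency radius (nearest-ring binning, `bin_width` frequency
#' pixels per ring). Non-square inputs are center-cropped to square with a
#' warning. For 3D stacks use [frc_stack()].
#'
#' @param img1,img2 numeric matrices, same shape.
#' @param pixel_size_nm pixel pitch in nm.
#' @param bin_width ring width in frequency pixels.
#' @param window_fn `"tukey"` or `"none"`.
#' @param threshold resolution threshold, default 1/7.
#' @param tukey_alpha taper fraction of the Tukey window.
#' @return object of class `frc_curve` with `ring_frequencies` (1/nm, bin
#'   centers, up to Nyquist), `correlations`, `threshold`, `pixel_size_nm`,
#'   `n` (image edge), `bin_width`.
#' @export
frc_curve <- function(img1, img2, pixel_size_nm, bin_width = 1L,
                      window_fn = c("tukey", "none"), threshold = 1 / 7,
                      tukey_alpha = 0.25) {
  window_fn <- match.arg(window_fn)
  if (!is.matrix(img1) || !is.matrix(img2))
    stopf("`img1` and `img2` must be matrices")
  if (!identical(dim(img1), dim(img2)))
    stopf("shape mismatch: %s vs %s", paste(dim(img1), collapse = "x"),
          paste(dim(img2), collapse = "x"))
  assert_scalar_num(pixel_size_nm, "pixel_size_nm", lower = 1e-9)
  assert_scalar_num(bin_width, "bin_width", lower = 1, integer = TRUE)
  if (all(img1 == 0) || all(img2 == 0)) stopf("all-zero image")
  d <- dim(img1)
  if (d[1L] != d[2L]) {
    n <- min(d)
    warnf("non-square input %dx%d center-cropped to %dx%d",
          d[1L], d[2L], n, n)
    off <- floor((d - n) / 2)
    img1 <- img1[off[1L] + seq_len(n), off[2L] + seq_len(n)]
    img2 <- img2[off[1L] + seq_len(n), off[2L] + seq_len(n)]
  }
  n <- nrow(img1)
  if (window_fn == "tukey") {
    w <- outer(tukey_window_1d(n, tukey_alpha),
               tukey_window_1d(n, tukey_alpha))
    img1 <- img1 * w; img2 <- img2 * w
  }
  f1 <- stats::fft(img1)
  f2 <- stats::fft(img2)
  k <- fft_freq(n)
  rad <- sqrt(outer(k^2, k^2, `+`))
  ring <- as.integer(round(rad / bin_width))
  nring <- floor((n / 2) / bin_width)
  keep <- ring <= nring
  num <- rowsum(as.vector(Re(f1 * Conj(f2)))[keep], ring[keep])
  p1 <- rowsum(as.vector(Mod(f1)^2)[keep], ring[keep])
  p2 <- rowsum(as.vector(Mod(f2)^2)[keep], ring[keep])
  rings <- as.integer(rownames(num))
  corr <- as.vector(num) / sqrt(as.vector(p1) * as.vector(p2))
  freqs <- rings * bin_width / (n * pixel_size_nm)
  structure(list(ring_frequencies = freqs, correlations = corr,
                 threshold = threshold, pixel_size_nm = pixel_size_nm,
                 n = n, bin_width = as.integer(bin_width)),
            class = "frc_curve")
}

#' @export
print.frc_curve <- function(x, ...) {
  res <- effective_resolution(x)
  cat(sprintf("FRC curve: %d rings up to Nyquist (pixel %g nm); %s\n",
              length(x$ring_frequencies), x$pixel_size_nm,
              format(res)))
  invisible(x)
}

#' Effective resolution from an FRC curve
#'
#' @param curve an `frc_curve`.
#' @param threshold overrides the curve's stored threshold.
#' @return object of class `effective_resolution`: `value_nm` (interpolated
#'   1/f* when resolved; the Nyquist bound 2 * pixel_size when the curve
#'   never drops below threshold; NA when it starts below threshold),
#'   `status` one of `"resolved"`, `"unresolved-at-nyquist"`,
#'   `"unresolvable"`, and `crossing_frequency` (1/nm or NA).
#' @export
effective_resolution <- function(curve, threshold = NULL) {
  stopifnot(inherits(curve, "frc_curve"))
  thr <- threshold %||% curve$threshold
  co <- curve$correlations
  fr <- curve$ring_frequencies
  ok <- is.finite(co)
  co <- co[ok]; fr <- fr[ok]
  if (length(co) == 0L) stopf("empty FRC curve")
  nyq <- 2 * curve$pixel_size_nm
  out <- function(value, status, f)
    structure(list(value_nm = value, status = status,
                   crossing_frequency = f, threshold = thr,
                   nyquist_bound_nm = nyq),
              class = "effective_resolution")
  if (co[1L] < thr) return(out(NA_real_, "unresolvable", NA_real_))
  below <- which(co < thr)
  if (length(below) == 0L) return(out(nyq, "unresolved-at-nyquist",
                                      NA_real_))
  i <- below[1L]
  f_cross <- fr[i - 1L] + (thr - co[i - 1L]) *
    (fr[i] - fr[i - 1L]) / (co[i] - co[i - 1L])
  out(1 / f_cross, "resolved", f_cross)
}

#' @export
format.effective_resolution <- function(x, ...) {
  switch(x$status,
         resolved = sprintf("effective resolution %.1f nm", x$value_nm),
         `unresolved-at-nyquist` =
           sprintf("unresolved at Nyquist (<= %.1f nm)", x$value_nm),
         unresolvable = "unresolvable (curve starts below threshold)")
}

#' @export
print.effective_resolution <- function(x, ...) {
  cat(format(x), "\n"); invisible(x)
}

#' Plane-wise FRC of a 3D stack pair
#'
#' Lateral resolution convention: FRC is computed per xy-plane and the
#' per-position effective resolution is the median over planes containing
#' signal (plane SD above `signal_quantile` of all plane SDs).
#'
#' @param stack1,stack2 Z,Y,X arrays.
#' @param pixel_size_nm lateral pixel size.
#' @param planes `"signal"` (default: planes with above-median SD),
#'   `"central"` (middle plane only) or an integer vector of z indices.
#' @inheritParams frc_curve
#' @return list: `resolution_nm` (median over used planes, Nyquist bound
#'   substituted for unresolved planes, NA if all unresolvable),
#'   `per_plane` (numeric), `planes_used`.
#' @export
frc_stack <- function(stack1, stack2, pixel_size_nm, planes = "signal",
                      ...) {
  stopifnot(is_stack3d(stack1), identical(dim(stack1), dim(stack2)))
  nz <- dim(stack1)[1L]
  zsel <- if (is.numeric(planes)) as.integer(planes)
          else if (identical(planes, "central")) as.integer(ceiling(nz / 2))
          else {
            sds <- vapply(seq_len(nz), function(z)
              stats::sd(as.vector(stack1[z, , ])), 0)
            which(sds >= stats::median(sds))
          }
  vals <- vapply(zsel, function(z) {
    res <- effective_resolution(frc_curve(stack1[z, , ], stack2[z, , ],
                                          pixel_size_nm, ...))
    if (res$status == "unresolvable") NA_real_ else res$value_nm
  }, 0)
  list(resolution_nm = if (all(is.na(vals))) NA_real_
       else stats::median(vals, na.rm = TRUE),
       per_plane = vals, planes_used = zsel)
}
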