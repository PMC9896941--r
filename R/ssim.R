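# Structural-term SSIM. Only the covariance (structure) component of the
# structural similarity index is used, as a full-reference check between a
# reconstructed image and a matched reference:
#
#   s(x, y) = (2*sigma_xy + C) / (sigma_x^2 + sigma_y^2 + C),  C = 2*c3,
#
# computed per local window and averaged. This form is symmetric, bounded
# in [-1, 1], equals 1 for y = x and is invariant to adding a constant to
# either image. (The often-printed denominator sigma_x * sigma_y does not
# satisfy s(x, x) = 1 and is not used.)

#' Structural-term SSIM between two images
#'
#' @param x,y numeric matrices of identical shape.
#' @param window odd window edge length in pixels (uniform window); windows
#'   are truncated at the image border so the local map has the input shape.
#' @param c3 stabilizing constant (intensity^2). Default (0.03 * L)^2 / 2
#'   with L the joint dynamic range of `x` and `y`, the conventional SSIM
#'   stabilizer; it also keeps constant windows well-defined.
#' @return object of class `ssim_result`: `global_value` (mean of the local
#'   map), `local_map`, `window_size`, `c3`.
#' @export
ssim_structural <- function(x, y, window = 7L, c3 = NULL) {
  if (!is.matrix(x) || !is.matrix(y)) stopf("`x` and `y` must be matrices")
  if (!identical(dim(x), dim(y)))
    stopf("shape mismatch: %s vs %s", paste(dim(x), collapse = "x"),
          paste(dim(y), collapse = "x"))
  assert_scalar_num(window, "window", lower = 3, integer = TRUE)
  if (window %% 2L == 0L) stopf("`window` must be odd")
  if (is.null(c3)) {
    L <- diff(range(c(x, y)))
    if (L == 0) L <- 1
    c3 <- (0.03 * L)^2 / 2
  }
  assert_scalar_num(c3, "c3", lower = 0)
  r <- (window - 1L) %/% 2L
  bx <- box_sums(x, r); by <- box_sums(y, r); bxy <- box_sums(x * y, r)
  bx2 <- box_sums(x * x, r); by2 <- box_sums(y * y, r)
  n <- bx$n
  mx <- bx$sum / n; my <- by$sum / n
  vx <- bx2$sum / n - mx^2
  vy <- by2$sum / n - my^2
  cxy <- bxy$sum / n - mx * my
  cc <- 2 * c3
  map <- (2 * cxy + cc) / (vx + vy + cc)
  structure(list(global_value = mean(map), local_map = map,
                 window_size = as.integer(window), c3 = c3),
            class = "ssim_result")
}

#' @export
print.ssim_result <- function(x, ...) {
  cat(sprintf("Structural SSIM: %.4f (window %d, c3 = %.3g, map %dx%d)\n",
              x$global_value, x$window_size, x$c3,
              nrow(x$local_map), ncol(x$local_map)))
  invisible(x)
}

#' Fraction of the local SSIM map flagged as reconstruction error
#'
#' @param ssim an `ssim_result`.
#' @param floor local values below this are counted as errors.
#' @export
local_error_fraction <- function(ssim, floor) {
  stopifnot(inherits(ssim, "ssim_result"))
  assert_scalar_num(floor, "floor", lower = -1, upper = 1)
  mean(ssim$local_map < floor)
}
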