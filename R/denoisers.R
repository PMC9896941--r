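# Pluggable denoiser contract. The reconstruction network itself (a
# self-supervised blind-spot model in the original workflow) is out of
# scope; what matters here is the contract around it: a denoiser maps an
# image or stack to a same-shape raster, deterministically. Shipped
# baselines: identity, Gaussian, median. An adapter slot exists for an
# external backend and errors clearly when the backend is absent.

#' Create a denoiser
#'
#' @param fun function(image_or_stack) -> same-shape numeric array.
#' @param name identifier recorded in QC reports and provenance.
#' @return object of class `denoiser`.
#' @export
denoiser <- function(fun, name) {
  if (!is.function(fun)) stopf("`fun` must be a function")
  if (!is.character(name) || length(name) != 1L)
    stopf("`name` must be a single string")
  # registration check: must preserve shape on a probe input
  probe <- array(stats::runif(64), dim = c(4L, 4L, 4L))
  out <- fun(probe)
  if (!identical(dim(out), dim(probe)))
    stopf("denoiser '%s' rejected at registration: changes shape %s -> %s",
          name, paste(dim(probe), collapse = "x"),
          paste(dim(out) %||% length(out), collapse = "x"))
  structure(list(fun = fun, name = name), class = "denoiser")
}

#' Apply a denoiser to an image or stack
#' @param d a [denoiser()].
#' @param img numeric matrix or array; must be finite.
#' @export
denoise <- function(d, img) {
  stopifnot(inherits(d, "denoiser"))
  if (any(!is.finite(img))) stopf("non-finite values in input to denoiser")
  out <- d$fun(img)
  if (!identical(dim(out), dim(img)))
    stopf("denoiser '%s' changed shape", d$name)
  out
}

#' @rdname denoiser
#' @export
denoiser_identity <- function() denoiser(identity, "identity")

#' @rdname denoiser
#' @param sigma Gaussian SD in pixels; for 3D input a per-axis vector
#'   (z, y, x), recycled.
#' @export
denoiser_gaussian <- function(sigma = 1) {
  force(sigma)
  denoiser(function(img) gaussian_smooth(img, sigma),
           sprintf("gaussian(sigma=%s)", paste(sigma, collapse = ",")))
}

#' @rdname denoiser
#' @export
denoiser_median <- function() {
  denoiser(function(img) {
    if (is.matrix(img)) return(median_filter_plane(img))
    out <- img
    for (z in seq_len(dim(img)[1L]))
      out[z, , ] <- median_filter_plane(img[z, , ])
    out
  }, "median3x3")
}

#' @rdname denoiser
#' @param backend name of an external self-supervised denoising backend.
#'   No backend ships with this package; registration fails with an error
#'   naming the missing backend.
#' @export
denoiser_external <- function(backend = "n2v") {
  stopf(paste("external denoising backend '%s' is not available in this",
              "installation; use one of the shipped baselines",
              "(denoiser_identity, denoiser_gaussian, denoiser_median) or",
              "register your own via denoiser()"), backend)
}

#' @export
print.denoiser <- function(x, ...) {
  cat("Denoiser:", x$name, "\n"); invisible(x)
}
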