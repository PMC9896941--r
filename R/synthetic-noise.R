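# Camera noise model and phase-A/B acquisition-set synthesis.
#
# The camera model is the canonical sCMOS one: Poisson shot noise on the
# exposure-scaled photon signal, a fixed conversion gain, a constant offset,
# and additive Gaussian read noise. Noise is independent per pixel, which is
# the assumption self-supervised blind-spot denoisers rely on.

#' Camera / exposure noise parameters
#'
#' @param exposure_time_ms low-quality exposure time t_exp.
#' @param reference_exposure_ms high-quality reference exposure t_ref;
#'   must be >= t_exp. Clean photon rasters are interpreted as expected
#'   photon counts at the reference exposure.
#' @param read_noise_sd Gaussian read noise SD in counts.
#' @param gain counts per detected photon.
#' @param offset constant camera offset in counts.
#' @param seed integer seed for the noise draws.
#' @export
noise_params <- function(exposure_time_ms, reference_exposure_ms,
                         read_noise_sd = 2, gain = 1, offset = 100,
                         seed = 1L) {
  assert_scalar_num(exposure_time_ms, "exposure_time_ms", lower = 0)
  assert_scalar_num(reference_exposure_ms, "reference_exposure_ms", lower = 0)
  assert_scalar_num(read_noise_sd, "read_noise_sd", lower = 0)
  assert_scalar_num(gain, "gain", lower = 0)
  assert_scalar_num(offset, "offset", lower = 0)
  if (exposure_time_ms > reference_exposure_ms)
    stopf("exposure_time_ms (%s) must be <= reference_exposure_ms (%s)",
          exposure_time_ms, reference_exposure_ms)
  structure(list(exposure_time_ms = exposure_time_ms,
                 reference_exposure_ms = reference_exposure_ms,
                 read_noise_sd = read_noise_sd, gain = gain,
                 offset = offset, seed = as.integer(seed)),
            class = "noise_params")
}

#' Apply Poisson-Gaussian camera noise to a clean photon raster
#'
#' The clean raster holds expected photon counts at the reference exposure;
#' an acquisition at `exposure` scales it by exposure / reference_exposure.
#' Output counts have mean gain * scaled + offset and variance
#' gain^2 * scaled + read_noise_sd^2, independently per pixel.
#'
#' @param clean non-negative numeric array (expected photons at t_ref).
#' @param noise a [noise_params()] object.
#' @param exposure_ms exposure to simulate; defaults to
#'   `noise$exposure_time_ms`.
#' @param seed overrides `noise$seed` when given.
#' @return numeric array of counts, same shape (not clamped or quantized).
#' @export
apply_noise <- function(clean, noise, exposure_ms = NULL, seed = NULL) {
  stopifnot(inherits(noise, "noise_params"))
  if (any(!is.finite(clean)) || any(clean < 0))
    stopf("`clean` must be finite and non-negative")
  exposure_ms <- exposure_ms %||% noise$exposure_time_ms
  if (exposure_ms > noise$reference_exposure_ms)
    stopf("exposure_ms exceeds reference_exposure_ms")
  seed <- seed %||% noise$seed
  with_seed(seed, {
    lam <- as.vector(clean) * exposure_ms / noise$reference_exposure_ms
    counts <- noise$gain * stats::rpois(length(lam), lam) + noise$offset
    if (noise$read_noise_sd > 0)
      counts <- counts + stats::rnorm(length(lam), sd = noise$read_noise_sd)
    out <- clean
    out[] <- counts
    out
  })
}

#' Generate two noisy realizations of one band-limited image
#'
#' Builds a random image whose spectrum is exactly zero above `cutoff`
#' (unit signal SD), then adds two independent Gaussian noise fields with
#' SD = 1/snr. `snr = Inf` gives two identical noiseless images; `snr = 0`
#' gives two independent pure-noise images (unit noise SD, no signal).
#' This is the standard fixture for Fourier ring correlation: the FRC of the
#' pair should stay near 1 below the cutoff frequency and near 0 above it.
#'
#' @param shape c(ny, nx) in pixels.
#' @param cutoff_inm band limit in 1/nm; must not exceed Nyquist,
#'   1 / (2 * pixel_size_nm).
#' @param pixel_size_nm pixel pitch in nm.
#' @param snr ratio of signal SD to noise SD.
#' @param baseline constant added to both images, so they have the
#'   positive mean (dominant DC term) real micrographs have.
#' @param seed integer seed.
#' @return list with `img1`, `img2`, `signal` (baseline-free), and the
#'   call parameters.
#' @export
make_band_limited_pair <- function(shape, cutoff_inm, pixel_size_nm,
                                   snr = 10, baseline = 10, seed = 1L) {
  stopifnot(length(shape) == 2L, all(shape >= 8L))
  assert_scalar_num(pixel_size_nm, "pixel_size_nm", lower = 1e-9)
  nyquist <- 1 / (2 * pixel_size_nm)
  if (!is.numeric(cutoff_inm) || cutoff_inm <= 0 || cutoff_inm > nyquist)
    stopf("cutoff (%g /nm) must be in (0, Nyquist = %g /nm]",
          cutoff_inm, nyquist)
  if (!(is.numeric(snr) && length(snr) == 1L && snr >= 0))
    stopf("`snr` must be a single number >= 0 (Inf allowed)")
  with_seed(seed, {
    ny <- shape[1L]; nx <- shape[2L]
    white <- matrix(stats::rnorm(ny * nx), ny, nx)
    ky <- fft_freq(ny); kx <- fft_freq(nx)
    fr <- sqrt(outer((ky / (ny * pixel_size_nm))^2,
                     (kx / (nx * pixel_size_nm))^2, `+`))
    keep <- fr <= cutoff_inm
    sig <- Re(stats::fft(stats::fft(white) * keep, inverse = TRUE)) /
      (ny * nx)
    sig <- (sig - mean(sig)) / stats::sd(as.vector(sig))
    if (snr == 0) sig <- sig * 0
    noise_sd <- if (is.infinite(snr)) 0 else if (snr == 0) 1 else 1 / snr
    n1 <- if (noise_sd > 0) matrix(stats::rnorm(ny * nx, sd = noise_sd),
                                   ny, nx) else 0
    n2 <- if (noise_sd > 0) matrix(stats::rnorm(ny * nx, sd = noise_sd),
                                   ny, nx) else 0
    list(img1 = baseline + sig + n1, img2 = baseline + sig + n2,
         signal = sig, cutoff_inm = cutoff_inm,
         pixel_size_nm = pixel_size_nm, snr = snr, baseline = baseline,
         seed = seed)
  })
}

# signed integer FFT frequencies (in index units) for length n
fft_freq <- function(n) {
  k <- seq_len(n) - 1L
  k[k > n / 2] <- k[k > n / 2] - n
  k
}

#' Synthesize a two-phase acquisition set from clean volumes
#'
#' Phase A, per z plane of the clean volume: one low-quality image at t_exp,
#' two high-quality references at t_ref, and two low-quality test images at
#' t_exp, each an independent noise draw. Phase B: every clean time-lapse
#' frame imaged once at t_exp.
#'
#' @param clean_volume clean Z,Y,X photon raster used for phase A.
#' @param phase_b_clean clean T,Z,Y,X array for phase B (defaults to one
#'   frame equal to `clean_volume`).
#' @param noise a [noise_params()] object; its seed drives all draws.
#' @param position_id identifier carried into QC reports.
#' @param frame_interval_s phase-B frame spacing, stored as timestamps.
#' @return an [acquisition_set()] object.
#' @export
make_acquisition_set <- function(clean_volume, noise,
                                 phase_b_clean = NULL, position_id = "pos1",
                                 frame_interval_s = 1) {
  stopifnot(is_stack3d(clean_volume), inherits(noise, "noise_params"))
  if (is.null(phase_b_clean))
    phase_b_clean <- array(clean_volume, dim = c(1L, dim(clean_volume)))
  stopifnot(length(dim(phase_b_clean)) == 4L, dim(phase_b_clean)[1L] >= 1L)
  t_exp <- noise$exposure_time_ms
  t_ref <- noise$reference_exposure_ms
  draw <- function(k, exp_ms)
    apply_noise(clean_volume, noise, exposure_ms = exp_ms,
                seed = derive_seed(noise$seed, k))
  phase_a <- list(low_quality   = draw(1L, t_exp),
                  high_quality_1 = draw(2L, t_ref),
                  high_quality_2 = draw(3L, t_ref),
                  test_1 = draw(4L, t_exp),
                  test_2 = draw(5L, t_exp))
  nt <- dim(phase_b_clean)[1L]
  phase_b <- array(0, dim = dim(phase_b_clean))
  for (fi in seq_len(nt))
    phase_b[fi, , , ] <- apply_noise(
      array(phase_b_clean[fi, , , ], dim = dim(phase_b_clean)[-1L]),
      noise, exposure_ms = t_exp, seed = derive_seed(noise$seed, 100L + fi))
  acquisition_set(position_id = position_id, phase_a = phase_a,
                  phase_b = phase_b, exposure_time_ms = t_exp,
                  reference_exposure_ms = t_ref,
                  timestamps_s = (seq_len(nt) - 1) * frame_interval_s)
}
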