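# Exposure-time sweep: how far can exposure be shortened while denoising
# still recovers the effective resolution? One row per exposure level,
# computed from that level's phase-A images only.

#' Exposure sweep report
#'
#' For each acquisition set (one per exposure time): FRC effective
#' resolution of the raw test pair and of the denoised test pair, pairwise
#' structural SSIM of the raw tests, SSIM of the denoised test against the
#' high-quality reference, and the local-SSIM error fraction. A failing
#' position produces an NA row with a warning; the sweep continues.
#'
#' @param sets named list of [acquisition_set()] objects, one per t_exp
#'   (>= 2 levels).
#' @param d a [denoiser()].
#' @param pixel_size_nm lateral pixel size.
#' @param local_ssim_floor local map values below this count as errors.
#' @param planes passed to [frc_stack()].
#' @return data.frame, one row per exposure level.
#' @export
exposure_sweep_report <- function(sets, d, pixel_size_nm,
                                  local_ssim_floor = 0.5,
                                  planes = "central") {
  if (length(sets) < 2L) stopf("need >= 2 exposure levels")
  stopifnot(inherits(d, "denoiser"))
  rows <- lapply(sets, function(set) {
    tryCatch({
      stopifnot(inherits(set, "acquisition_set"))
      nz <- dim(set$phase_a$test_1)[1L]
      zc <- if (identical(planes, "central"))
        as.integer(ceiling(nz / 2)) else planes
      rec1 <- denoise(d, set$phase_a$test_1)
      rec2 <- denoise(d, set$phase_a$test_2)
      res_raw <- frc_stack(set$phase_a$test_1, set$phase_a$test_2,
                           pixel_size_nm, planes = zc)
      res_rec <- frc_stack(rec1, rec2, pixel_size_nm, planes = zc)
      z <- if (is.numeric(zc)) zc[1L] else as.integer(ceiling(nz / 2))
      ss_pair <- ssim_structural(set$phase_a$test_1[z, , ],
                                 set$phase_a$test_2[z, , ])
      ss_ref <- ssim_structural(rec1[z, , ],
                                set$phase_a$high_quality_1[z, , ])
      data.frame(position_id = set$position_id,
                 exposure_time_ms = set$exposure_time_ms,
                 resolution_raw_nm = res_raw$resolution_nm,
                 resolution_reconstructed_nm = res_rec$resolution_nm,
                 ssim_pairwise = ss_pair$global_value,
                 ssim_vs_reference = ss_ref$global_value,
                 local_error_fraction = local_error_fraction(
                   ss_ref, local_ssim_floor))
    }, error = function(e) {
      warnf("sweep position failed (%s); continuing",
            conditionMessage(e))
      data.frame(position_id = NA_character_,
                 exposure_time_ms = NA_real_,
                 resolution_raw_nm = NA_real_,
                 resolution_reconstructed_nm = NA_real_,
                 ssim_pairwise = NA_real_, ssim_vs_reference = NA_real_,
                 local_error_fraction = NA_real_)
    })
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$exposure_time_ms), , drop = FALSE]
}
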