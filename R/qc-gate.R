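# Two-phase acquisition data model and the per-position QC gate.
#
# Phase A carries, per position: one low-quality image, two high-quality
# references (t_ref) and two low-quality test images (t_exp), each a Z,Y,X
# volume. Phase B is the low-quality time-lapse. The gate reconstructs the
# two test images with the candidate denoiser and accepts the position only
# if (i) the FRC effective resolution of the reconstructed pair meets the
# required resolution, (ii) the structural SSIM of the reconstruction
# against a high-quality reference is high enough, and (iii) the fraction
# of the local SSIM map flagged as reconstruction error is low enough.
# Phase-B frames never enter the metrics.

#' Construct a two-phase acquisition set
#'
#' @param position_id identifier for the imaged position.
#' @param phase_a named list of Z,Y,X arrays: `low_quality`,
#'   `high_quality_1`, `high_quality_2`, `test_1`, `test_2`.
#' @param phase_b T,Z,Y,X array of low-quality time-lapse volumes.
#' @param exposure_time_ms,reference_exposure_ms exposure metadata.
#' @param timestamps_s phase-B frame times (defaults to 0, 1, ...).
#' @export
acquisition_set <- function(position_id, phase_a, phase_b,
                            exposure_time_ms, reference_exposure_ms,
                            timestamps_s = NULL) {
  need <- c("low_quality", "high_quality_1", "high_quality_2",
            "test_1", "test_2")
  if (!is.list(phase_a) || !all(need %in% names(phase_a)))
    stopf("phase_a must contain: %s", paste(need, collapse = ", "))
  shp <- dim(phase_a$low_quality)
  for (nm in need) {
    if (!is_stack3d(phase_a[[nm]]))
      stopf("phase_a$%s must be a Z,Y,X array", nm)
    if (!identical(dim(phase_a[[nm]]), shp))
      stopf("phase_a$%s shape differs from low_quality", nm)
  }
  stopifnot(length(dim(phase_b)) == 4L, identical(dim(phase_b)[-1L], shp))
  assert_scalar_num(exposure_time_ms, "exposure_time_ms", lower = 0)
  assert_scalar_num(reference_exposure_ms, "reference_exposure_ms",
                    lower = 0)
  nt <- dim(phase_b)[1L]
  timestamps_s <- timestamps_s %||% (seq_len(nt) - 1)
  stopifnot(length(timestamps_s) == nt)
  structure(list(position_id = position_id, phase_a = phase_a[need],
                 phase_b = phase_b, exposure_time_ms = exposure_time_ms,
                 reference_exposure_ms = reference_exposure_ms,
                 timestamps_s = as.numeric(timestamps_s)),
            class = "acquisition_set")
}

#' @export
print.acquisition_set <- function(x, ...) {
  cat(sprintf(paste0("Acquisition set '%s': phase A %s (5 images/plane),",
                     " phase B %d frames, t_exp %g ms / t_ref %g ms\n"),
              x$position_id,
              paste(dim(x$phase_a$low_quality), collapse = "x"),
              dim(x$phase_b)[1L], x$exposure_time_ms,
              x$reference_exposure_ms))
  invisible(x)
}

#' Per-position QC gate
#'
#' Reconstructs the two phase-A test images, then measures: FRC effective
#' resolution of the reconstructed pair and of the raw test pair, global
#' structural SSIM of reconstructed test 1 against high-quality reference 1,
#' pairwise SSIM of the raw test images, and the local-SSIM error fraction.
#' All thresholds are mandatory (the gate makes no silent choices). Any
#' metric failure yields a rejection with reason `"metric-error"`, never a
#' silent accept. Metrics use the central z-plane by default.
#'
#' @param set an [acquisition_set()].
#' @param d a [denoiser()].
#' @param thresholds named list with `min_resolution_nm` (required
#'   effective resolution in nm: accept needs measured <= this),
#'   `min_ssim` (accept needs SSIM vs. reference >= this),
#'   `max_local_error_fraction`, and `local_ssim_floor` (local map values
#'   below the floor count as errors).
#' @param pixel_size_nm lateral pixel size for the FRC.
#' @param planes passed to [frc_stack()] (`"central"` default, `"signal"`
#'   for a median over signal planes).
#' @return object of class `qc_report`.
#' @export
qc_gate <- function(set, d, thresholds, pixel_size_nm,
                    planes = "central") {
  stopifnot(inherits(set, "acquisition_set"), inherits(d, "denoiser"))
  need <- c("min_resolution_nm", "min_ssim", "max_local_error_fraction",
            "local_ssim_floor")
  missing <- setdiff(need, names(thresholds))
  if (length(missing) > 0L)
    stopf("thresholds are config-mandatory; missing: %s",
          paste(missing, collapse = ", "))
  metrics <- tryCatch({
    rec1 <- denoise(d, set$phase_a$test_1)
    rec2 <- denoise(d, set$phase_a$test_2)
    nz <- dim(rec1)[1L]
    zc <- if (identical(planes, "central")) as.integer(ceiling(nz / 2))
          else NULL
    res_rec <- frc_stack(rec1, rec2, pixel_size_nm,
                         planes = if (is.null(zc)) planes else zc)
    res_raw <- frc_stack(set$phase_a$test_1, set$phase_a$test_2,
                         pixel_size_nm,
                         planes = if (is.null(zc)) planes else zc)
    z <- zc %||% as.integer(ceiling(nz / 2))
    ss_pair <- ssim_structural(set$phase_a$test_1[z, , ],
                               set$phase_a$test_2[z, , ])
    ss_ref <- ssim_structural(rec1[z, , ],
                              set$phase_a$high_quality_1[z, , ])
    list(effective_resolution_reconstructed = res_rec$resolution_nm,
         effective_resolution_raw = res_raw$resolution_nm,
         ssim_pairwise = ss_pair$global_value,
         ssim_vs_reference = ss_ref$global_value,
         local_error_fraction = local_error_fraction(
           ss_ref, thresholds$local_ssim_floor))
  }, error = function(e) e)
  if (inherits(metrics, "error")) {
    return(new_qc_report(set$position_id, d$name, thresholds,
                         metrics = list(
                           effective_resolution_reconstructed = NA_real_,
                           effective_resolution_raw = NA_real_,
                           ssim_pairwise = NA_real_,
                           ssim_vs_reference = NA_real_,
                           local_error_fraction = NA_real_),
                         decision = "reject",
                         reasons = paste0("metric-error: ",
                                          conditionMessage(metrics))))
  }
  dec <- qc_decision(metrics, thresholds)
  new_qc_report(set$position_id, d$name, thresholds, metrics,
                dec$decision, dec$reasons)
}

# Pure function of stored numbers + thresholds: the auditability contract.
# Recomputing the decision from a report must reproduce it.
qc_decision <- function(metrics, thresholds) {
  reasons <- character()
  res <- metrics$effective_resolution_reconstructed
  if (is.na(res) || res > thresholds$min_resolution_nm)
    reasons <- c(reasons, "resolution")
  if (is.na(metrics$ssim_vs_reference) ||
      metrics$ssim_vs_reference < thresholds$min_ssim)
    reasons <- c(reasons, "ssim")
  if (is.na(metrics$local_error_fraction) ||
      metrics$local_error_fraction > thresholds$max_local_error_fraction)
    reasons <- c(reasons, "local-error")
  list(decision = if (length(reasons) == 0L) "accept" else "reject",
       reasons = reasons)
}

new_qc_report <- function(position_id, denoiser_name, thresholds, metrics,
                          decision, reasons) {
  structure(c(list(position_id = position_id,
                   denoiser = denoiser_name,
                   thresholds = thresholds),
              metrics,
              list(decision = decision, reasons = reasons)),
            class = "qc_report")
}

#' Recompute a QC decision from the numbers stored in a report
#' @param report a `qc_report`.
#' @return list with `decision` and `reasons`.
#' @export
qc_recheck <- function(report) {
  stopifnot(inherits(report, "qc_report"))
  if (any(grepl("^metric-error", report$reasons)))
    return(list(decision = "reject", reasons = report$reasons))
  qc_decision(report, report$thresholds)
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("QC report for '%s' (denoiser %s): %s\n", x$position_id,
              x$denoiser, toupper(x$decision)))
  cat(sprintf("  resolution (reconstructed / raw): %.1f / %.1f nm\n",
              x$effective_resolution_reconstructed,
              x$effective_resolution_raw))
  cat(sprintf("  SSIM pairwise %.3f, vs reference %.3f, local error %.3f\n",
              x$ssim_pairwise, x$ssim_vs_reference,
              x$local_error_fraction))
  if (length(x$reasons)) cat("  reasons:", paste(x$reasons, collapse = ", "),
                             "\n")
  invisible(x)
}

#' Reconstruct the phase-B time-lapse of an accepted position
#'
#' Applies the denoiser frame by frame. Refuses to run on a rejected
#' position unless `override = TRUE` (the override is recorded in the
#' output provenance). Frame count, shape and timestamps are preserved;
#' provenance (denoiser id, QC decision) is attached as an attribute.
#'
#' @param set an [acquisition_set()].
#' @param d a [denoiser()].
#' @param report the position's `qc_report`; NULL skips the gate check
#'   only when `override = TRUE`.
#' @param override logged escape hatch for rejected positions.
#' @return T,Z,Y,X array with attributes `timestamps_s` and `provenance`.
#' @export
reconstruct_timelapse <- function(set, d, report = NULL,
                                  override = FALSE) {
  stopifnot(inherits(set, "acquisition_set"), inherits(d, "denoiser"))
  if (is.null(report) && !override)
    stopf("no QC report supplied; pass the position's qc_report or set
override = TRUE")
  if (!is.null(report)) {
    stopifnot(inherits(report, "qc_report"))
    if (report$decision != "accept" && !override)
      stopf(paste("position '%s' was rejected by the QC gate (%s);",
                  "refusing to reconstruct without override"),
            set$position_id, paste(report$reasons, collapse = ", "))
  }
  if (override) message("QC override active for position ",
                        set$position_id)
  out <- set$phase_b
  for (fi in seq_len(dim(out)[1L]))
    out[fi, , , ] <- denoise(d, array(set$phase_b[fi, , , ],
                                      dim = dim(set$phase_b)[-1L]))
  attr(out, "timestamps_s") <- set$timestamps_s
  attr(out, "provenance") <- list(
    denoiser = d$name, position_id = set$position_id,
    qc_decision = if (is.null(report)) NA_character_ else report$decision,
    override = override)
  out
}
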