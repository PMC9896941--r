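# Per-cluster measurements. Intensities for both channels are read inside
# the Ser5P-derived mask; only average intensity is taken from the Ser2P
# channel (its shape is never quantified). Centroids are intensity-weighted
# and reported in physical units (voxel-center convention, 0-based indices).

#' Measure labeled clusters in a two-channel volume
#'
#' @param labels integer Z,Y,X label array (from [segment_clusters()]).
#' @param ser5p,ser2p numeric Z,Y,X intensity arrays, same shape.
#' @param voxel_size_nm numeric c(z, y, x) in nm.
#' @param frame_index frame number recorded in the output.
#' @param labels_wanted labels to measure (default: all present); a wanted
#'   label absent from the raster is skipped with a warning.
#' @param background_subtract subtract the median intensity outside all
#'   labels from the mean intensities (off by default). With a camera
#'   offset in the counts, the raw mask mean is dominated by how much
#'   dim boundary the mask includes; subtraction removes that term.
#' @param erode_mask number of 6-neighbor erosion steps applied to the
#'   intensity-measurement mask only (shape, volume and centroid always
#'   use the full mask). Segmentation masks of blurred data include a
#'   partial-intensity shoulder whose share tracks the cluster's surface
#'   area, diluting mask means in phase with the shape cycle; measuring
#'   on the eroded core removes this bias. Falls back to the full mask
#'   when fewer than 4 voxels remain.
#' @return data.frame, one row per cluster: frame, label, centroid (nm),
#'   volume (voxels and um^3), mean intensities, elongation, solidity.
#' @export
measure_clusters <- function(labels, ser5p, ser2p, voxel_size_nm,
                             frame_index = 1L, labels_wanted = NULL,
                             background_subtract = FALSE,
                             erode_mask = 0L) {
  stopifnot(is_stack3d(labels), identical(dim(labels), dim(ser5p)),
            identical(dim(labels), dim(ser2p)),
            length(voxel_size_nm) == 3L)
  present <- sort(unique(labels[labels > 0L]))
  wanted <- labels_wanted %||% present
  absent <- setdiff(wanted, present)
  if (length(absent) > 0L)
    warnf("labels absent from raster skipped: %s",
          paste(absent, collapse = ", "))
  wanted <- intersect(wanted, present)
  if (length(wanted) == 0L)
    return(empty_observations())
  d <- dim(labels)
  idx_all <- which(labels > 0L)
  lab_vec <- labels[idx_all]
  bg5 <- bg2 <- 0
  if (background_subtract) {
    out_idx <- labels == 0L
    bg5 <- stats::median(ser5p[out_idx])
    bg2 <- stats::median(ser2p[out_idx])
  }
  rows <- lapply(wanted, function(lb) {
    idx <- idx_all[lab_vec == lb]
    z <- (idx - 1L) %% d[1L] + 1L
    y <- ((idx - 1L) %/% d[1L]) %% d[2L] + 1L
    x <- (idx - 1L) %/% (d[1L] * d[2L]) + 1L
    coords <- cbind(z, y, x)
    w5 <- ser5p[idx]
    w <- if (sum(w5) > 0) w5 / sum(w5) else rep(1 / length(idx),
                                                length(idx))
    cen <- colSums(sweep(coords - 0.5, 2L, as.numeric(voxel_size_nm),
                         `*`) * w)
    mcoords <- coords
    if (erode_mask > 0L) {
      for (e in seq_len(erode_mask)) {
        core <- interior_voxels(mcoords)
        if (nrow(core) < 4L) break
        mcoords <- core
      }
    }
    midx <- mcoords[, 1L] + (mcoords[, 2L] - 1L) * d[1L] +
      (mcoords[, 3L] - 1L) * d[1L] * d[2L]
    el <- if (length(idx) >= 4L) elongation(coords, voxel_size_nm)
          else NA_real_
    so <- if (length(idx) >= 4L)
      tryCatch(solidity(coords, voxel_size_nm),
               error = function(e) NA_real_) else NA_real_
    data.frame(frame = frame_index, label = lb,
               z_nm = cen[1L], y_nm = cen[2L], x_nm = cen[3L],
               volume_vox = length(idx),
               volume_um3 = length(idx) * prod(voxel_size_nm) / 1e9,
               ser5p_mean = mean(ser5p[midx]) - bg5,
               ser2p_mean = mean(ser2p[midx]) - bg2,
               elongation = as.numeric(el), solidity = as.numeric(so))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

empty_observations <- function() {
  data.frame(frame = integer(), label = integer(), z_nm = numeric(),
             y_nm = numeric(), x_nm = numeric(), volume_vox = integer(),
             volume_um3 = numeric(), ser5p_mean = numeric(),
             ser2p_mean = numeric(), elongation = numeric(),
             solidity = numeric())
}

#' Segment and measure every frame of a two-channel time-lapse
#'
#' Convenience wrapper: [segment_clusters()] on the Ser5P channel of each
#' frame, then [measure_clusters()] with both channels.
#'
#' @param ser5p,ser2p T,Z,Y,X arrays.
#' @param voxel_size_nm numeric c(z, y, x).
#' @param background_subtract,erode_mask passed to [measure_clusters()].
#' @param ... passed to [segment_clusters()].
#' @return data.frame of observations across frames.
#' @export
measure_timelapse <- function(ser5p, ser2p, voxel_size_nm,
                              background_subtract = FALSE,
                              erode_mask = 0L, ...) {
  stopifnot(length(dim(ser5p)) == 4L, identical(dim(ser5p), dim(ser2p)))
  nt <- dim(ser5p)[1L]
  shp <- dim(ser5p)[-1L]
  obs <- lapply(seq_len(nt), function(fi) {
    vol5 <- array(ser5p[fi, , , ], dim = shp)
    vol2 <- array(ser2p[fi, , , ], dim = shp)
    lab <- segment_clusters(vol5, ...)
    measure_clusters(lab, vol5, vol2, voxel_size_nm, frame_index = fi,
                     background_subtract = background_subtract,
                     erode_mask = erode_mask)
  })
  do.call(rbind, obs)
}
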