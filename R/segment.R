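# 3D segmentation of Pol II Ser5P clusters: Gaussian smoothing, a global
# robust threshold (Otsu by default), 26-connected components, and a
# minimum-volume filter.

#' Segment clusters in a 3D stack
#'
#' @param stack Z,Y,X numeric array (single channel).
#' @param smoothing_sigma Gaussian SD in pixels, per axis (z, y, x) or a
#'   scalar (recycled).
#' @param threshold_method `"otsu"` (default) or `"quantile"`.
#' @param threshold_quantile used when `threshold_method = "quantile"`.
#' @param min_volume_vox components smaller than this are removed.
#' @return integer label array, same shape; 0 is background, labels are
#'   1..k in decreasing component size. Zero clusters is a valid result.
#' @export
segment_clusters <- function(stack, smoothing_sigma = 1,
                             threshold_method = c("otsu", "quantile"),
                             threshold_quantile = 0.999,
                             min_volume_vox = 8L) {
  threshold_method <- match.arg(threshold_method)
  if (!is_stack3d(stack)) stopf("`stack` must be a Z,Y,X array")
  if (any(!is.finite(stack))) stopf("non-finite voxels in `stack`")
  sm <- if (any(smoothing_sigma > 0))
    gaussian_smooth(stack, rep_len(smoothing_sigma, 3L)) else stack
  thr <- switch(threshold_method,
                otsu = otsu_threshold(sm),
                quantile = stats::quantile(sm, threshold_quantile,
                                           names = FALSE))
  mask <- sm > thr
  if (!any(mask)) return(array(0L, dim = dim(stack)))
  labels <- label_components_26(mask)
  sizes <- tabulate(labels[labels > 0L])
  keep <- which(sizes >= min_volume_vox)
  if (length(keep) == 0L) return(array(0L, dim = dim(stack)))
  # relabel 1..k by decreasing size
  ord <- keep[order(sizes[keep], decreasing = TRUE)]
  remap <- integer(length(sizes))
  remap[ord] <- seq_along(ord)
  out <- array(0L, dim = dim(stack))
  pos <- labels > 0L
  out[pos] <- remap[labels[pos]]
  out
}

# 26-connected component labeling of a logical Z,Y,X mask via vectorized
# frontier expansion (breadth-first).
label_components_26 <- function(mask) {
  d <- dim(mask)
  labels <- array(0L, dim = d)
  fg <- which(mask)
  if (length(fg) == 0L) return(labels)
  offs <- as.matrix(expand.grid(dz = -1:1, dy = -1:1, dx = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0L, , drop = FALSE]
  visited <- array(FALSE, dim = d)
  nxt <- 0L
  coords_of <- function(idx) {
    z <- (idx - 1L) %% d[1L] + 1L
    y <- ((idx - 1L) %/% d[1L]) %% d[2L] + 1L
    x <- (idx - 1L) %/% (d[1L] * d[2L]) + 1L
    cbind(z, y, x)
  }
  for (start in fg) {
    if (visited[start]) next
    nxt <- nxt + 1L
    frontier <- start
    visited[start] <- TRUE
    labels[start] <- nxt
    while (length(frontier) > 0L) {
      co <- coords_of(frontier)
      cand <- do.call(rbind, lapply(seq_len(nrow(offs)), function(i)
        cbind(co[, 1L] + offs[i, 1L], co[, 2L] + offs[i, 2L],
              co[, 3L] + offs[i, 3L])))
      ok <- cand[, 1L] >= 1L & cand[, 1L] <= d[1L] &
        cand[, 2L] >= 1L & cand[, 2L] <= d[2L] &
        cand[, 3L] >= 1L & cand[, 3L] <= d[3L]
      cand <- cand[ok, , drop = FALSE]
      idx <- unique(cand[, 1L] + (cand[, 2L] - 1L) * d[1L] +
                      (cand[, 3L] - 1L) * d[1L] * d[2L])
      idx <- idx[mask[idx] & !visited[idx]]
      visited[idx] <- TRUE
      labels[idx] <- nxt
      frontier <- idx
    }
  }
  labels
}
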