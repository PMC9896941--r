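# Tracking by spatial proximity in consecutive time points: greedy
# mutual-nearest-neighbor linking with a mandatory linking radius.
# Unmatched observations start new tracks; tracks may bridge up to
# `max_gap` missing frames (default 0: a vanished cluster ends its track).

#' Track cluster observations through time
#'
#' @param observations data.frame from [measure_clusters()] /
#'   [measure_timelapse()]: needs `frame`, `label`, `z_nm`, `y_nm`, `x_nm`.
#' @param linking_radius_nm maximum centroid displacement between linked
#'   observations (config-mandatory; no default).
#' @param max_gap number of missing frames a track may bridge.
#' @return the observations with a `track_id` column, ordered by track and
#'   frame; attribute `gaps` counts bridged gaps per track.
#' @export
track_clusters <- function(observations, linking_radius_nm, max_gap = 0L) {
  assert_scalar_num(linking_radius_nm, "linking_radius_nm", lower = 0)
  assert_scalar_num(max_gap, "max_gap", lower = 0, integer = TRUE)
  obs <- observations
  stopifnot(all(c("frame", "label", "z_nm", "y_nm", "x_nm") %in%
                  names(obs)))
  if (nrow(obs) == 0L) {
    obs$track_id <- integer()
    return(obs)
  }
  dup <- stats::aggregate(seq_len(nrow(obs)),
                          by = obs[c("frame", "label")], FUN = length)
  if (any(dup$x > 1L))
    stopf("duplicate labels within a frame: frame %s label %s",
          dup$frame[dup$x > 1L][1L], dup$label[dup$x > 1L][1L])
  obs <- obs[order(obs$frame, obs$label), , drop = FALSE]
  obs$track_id <- NA_integer_
  frames <- sort(unique(obs$frame))
  next_id <- 0L
  # active track heads: track_id, last frame, last centroid
  heads <- data.frame(track_id = integer(), frame = integer(),
                      z = numeric(), y = numeric(), x = numeric())
  gaps <- integer()
  for (fr in frames) {
    cur <- which(obs$frame == fr)
    alive <- heads$frame >= fr - 1L - max_gap
    heads <- heads[alive, , drop = FALSE]
    matched_cur <- rep(FALSE, length(cur))
    if (nrow(heads) > 0L && length(cur) > 0L) {
      cc <- as.matrix(obs[cur, c("z_nm", "y_nm", "x_nm")])
      hh <- as.matrix(heads[, c("z", "y", "x")])
      dm <- sqrt(pmax(outer(rowSums(hh^2), rowSums(cc^2), `+`) -
                        2 * hh %*% t(cc), 0))
      dm[dm > linking_radius_nm] <- Inf
      # mutual nearest neighbors within the radius
      nn_h <- apply(dm, 1L, which.min)   # best obs per head
      nn_c <- apply(dm, 2L, which.min)   # best head per obs
      for (hi in seq_len(nrow(heads))) {
        ci <- nn_h[hi]
        if (is.finite(dm[hi, ci]) && nn_c[ci] == hi) {
          id <- heads$track_id[hi]
          obs$track_id[cur[ci]] <- id
          if (fr - heads$frame[hi] > 1L) gaps[id] <- gaps[id] + 1L
          heads$frame[hi] <- fr
          heads[hi, c("z", "y", "x")] <- obs[cur[ci],
                                             c("z_nm", "y_nm", "x_nm")]
          matched_cur[ci] <- TRUE
        }
      }
    }
    for (ci in which(!matched_cur)) {
      next_id <- next_id + 1L
      gaps[next_id] <- 0L
      obs$track_id[cur[ci]] <- next_id
      heads <- rbind(heads, data.frame(
        track_id = next_id, frame = fr,
        z = obs$z_nm[cur[ci]], y = obs$y_nm[cur[ci]],
        x = obs$x_nm[cur[ci]]))
    }
  }
  out <- obs[order(obs$track_id, obs$frame), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "gaps") <- gaps
  out
}
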