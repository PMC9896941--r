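# Synthetic two-channel 3D time-lapses of Pol II clusters with known ground
# truth. Clusters are rendered as (optionally bent) ellipsoids whose
# intensities and shape follow one stereotyped sinusoidal cycle:
#   Ser5P intensity peaks first, Ser2P intensity follows lag_ser2p seconds
#   later, and the shape excursion (elongation up, solidity down, via the
#   bend) follows lag_shape seconds after Ser5P.
# Straight ellipsoids cannot vary in solidity (they are convex), so the
# solidity cycle is driven by a quadratic bend of the major axis.

#' Parameters of a synthetic cluster scene
#'
#' Defaults describe the imaging regime this workflow targets: confocal-like
#' anisotropic voxels (z twice as coarse as xy), a 36 s interaction cycle,
#' a Ser2P intensity lag of 5 s and a shape lag of 10 s relative to Ser5P,
#' and 3D volumes every 2 s.
#'
#' @param volume_shape integer c(z, y, x) voxel counts.
#' @param voxel_size_nm numeric c(z, y, x) voxel edge lengths in nm.
#' @param n_clusters number of clusters placed without overlap.
#' @param cluster_radius_nm volume-equivalent sphere radius of a cluster.
#' @param elongation_max peak elongation of the shape cycle (>= 1).
#' @param bend_max peak dimensionless bend amplitude (drives solidity < 1).
#' @param cycle_period_s,lag_ser2p_s,lag_shape_s cycle timing in seconds;
#'   must satisfy lag_ser2p < lag_shape < cycle_period.
#' @param frame_interval_s,n_frames time-lapse sampling.
#' @param background,peak_signal photons per voxel per unit (reference)
#'   exposure: uniform background and in-cluster amplitude at cycle midpoint.
#' @param intensity_amplitude relative amplitude of the intensity cycle.
#' @param psf_sigma_nm Gaussian blur emulating the optical transfer, per
#'   axis (z, y, x); no full PSF model is attempted.
#' @param seed integer controlling all placement and phase randomness.
#' @return object of class `scene_params`.
#' @export
scene_params <- function(volume_shape = c(16L, 96L, 96L),
                         voxel_size_nm = c(200, 100, 100),
                         n_clusters = 3L,
                         cluster_radius_nm = 400,
                         elongation_max = 2,
                         bend_max = 0.6,
                         cycle_period_s = 36,
                         lag_ser2p_s = 5,
                         lag_shape_s = 10,
                         frame_interval_s = 2,
                         n_frames = 60L,
                         background = 10,
                         peak_signal = 100,
                         intensity_amplitude = 0.6,
                         psf_sigma_nm = c(150, 80, 80),
                         seed = 1L) {
  stopifnot(length(volume_shape) == 3L, all(volume_shape > 0),
            length(voxel_size_nm) == 3L, all(voxel_size_nm > 0),
            all(psf_sigma_nm >= 0))
  assert_scalar_num(n_clusters, "n_clusters", lower = 1, integer = TRUE)
  assert_scalar_num(cluster_radius_nm, "cluster_radius_nm", lower = 1e-9)
  assert_scalar_num(elongation_max, "elongation_max", lower = 1)
  assert_scalar_num(bend_max, "bend_max", lower = 0)
  assert_scalar_num(cycle_period_s, "cycle_period_s", lower = 1e-9)
  assert_scalar_num(frame_interval_s, "frame_interval_s", lower = 1e-9)
  assert_scalar_num(n_frames, "n_frames", lower = 2, integer = TRUE)
  assert_scalar_num(background, "background", lower = 0)
  assert_scalar_num(peak_signal, "peak_signal", lower = 0)
  assert_scalar_num(intensity_amplitude, "intensity_amplitude",
                    lower = 0, upper = 1)
  if (!(lag_ser2p_s < lag_shape_s && lag_shape_s < cycle_period_s))
    stopf("need lag_ser2p_s < lag_shape_s < cycle_period_s, got %s, %s, %s",
          lag_ser2p_s, lag_shape_s, cycle_period_s)
  structure(list(
    volume_shape = as.integer(volume_shape),
    voxel_size_nm = as.numeric(voxel_size_nm),
    n_clusters = as.integer(n_clusters),
    cluster_radius_nm = cluster_radius_nm,
    elongation_max = elongation_max, bend_max = bend_max,
    cycle_period_s = cycle_period_s, lag_ser2p_s = lag_ser2p_s,
    lag_shape_s = lag_shape_s, frame_interval_s = frame_interval_s,
    n_frames = as.integer(n_frames), background = background,
    peak_signal = peak_signal, intensity_amplitude = intensity_amplitude,
    psf_sigma_nm = as.numeric(psf_sigma_nm), seed = as.integer(seed)),
    class = "scene_params")
}

# Rasterize one bent ellipsoid into logical mask coordinates.
# center_nm: c(z,y,x); semi-axes (a along x, b along y, c along z) in nm;
# bend displaces y by bend * dx^2 / a. Returns integer voxel index matrix.
ellipsoid_voxels <- function(center_nm, a, b, c_, bend, volume_shape,
                             voxel_size_nm) {
  # bounding box in voxels (bend enlarges y extent by at most bend * a)
  ext <- c(c_, b + bend * a, a)  # z, y, x extents in nm
  lo <- pmax(1L, floor((center_nm - ext) / voxel_size_nm - 1))
  hi <- pmin(volume_shape, ceiling((center_nm + ext) / voxel_size_nm + 1))
  if (any(lo > hi)) return(matrix(integer(), 0L, 3L))
  zz <- lo[1L]:hi[1L]; yy <- lo[2L]:hi[2L]; xx <- lo[3L]:hi[3L]
  g <- as.matrix(expand.grid(z = zz, y = yy, x = xx))
  # voxel centers in nm (voxel i spans [(i-1)*s, i*s], center (i-0.5)*s)
  pz <- (g[, 1L] - 0.5) * voxel_size_nm[1L] - center_nm[1L]
  py <- (g[, 2L] - 0.5) * voxel_size_nm[2L] - center_nm[2L]
  px <- (g[, 3L] - 0.5) * voxel_size_nm[3L] - center_nm[3L]
  py_b <- py - bend * px^2 / a
  inside <- (px / a)^2 + (py_b / b)^2 + (pz / c_)^2 <= 1
  g[inside, , drop = FALSE]
}

#' Render a clean two-channel time-lapse with ground truth
#'
#' Places `n_clusters` bent ellipsoids at random non-overlapping positions
#' with random cycle phases, and renders photon-rate volumes for the Ser5P
#' and Ser2P channels at every frame. Returns the clean (pre-noise) stacks
#' together with exact per-frame ground truth: label masks, phases,
#' centroids, semi-axes, bend, and the true intensity/shape driver values.
#'
#' @param params a [scene_params()] object.
#' @return list with `ser5p`, `ser2p` (T,Z,Y,X photon-rate arrays),
#'   `labels` (T,Z,Y,X integer array), `truth` (data.frame, one row per
#'   cluster per frame) and `params`.
#' @export
render_scene <- function(params) {
  stopifnot(inherits(params, "scene_params"))
  p <- params
  with_seed(p$seed, {
    vol_nm <- p$volume_shape * p$voxel_size_nm
    margin <- p$cluster_radius_nm * p$elongation_max * 1.3 +
      max(p$psf_sigma_nm)
    min_gap <- 2 * p$cluster_radius_nm * p$elongation_max * 1.3
    centers <- matrix(NA_real_, p$n_clusters, 3L)
    for (i in seq_len(p$n_clusters)) {
      placed <- FALSE
      for (try in seq_len(500L)) {
        cand <- margin + stats::runif(3L) * (vol_nm - 2 * margin)
        if (any(vol_nm - 2 * margin <= 0))
          stopf(paste("volume too small to place clusters:",
                      "need > %.0f nm per axis"), 2 * margin)
        ok <- i == 1L ||
          all(sqrt(rowSums(sweep(centers[seq_len(i - 1L), , drop = FALSE],
                                 2L, cand)^2)) > min_gap)
        if (ok) { centers[i, ] <- cand; placed <- TRUE; break }
      }
      if (!placed)
        stopf(paste("could not place cluster %d without overlap after 500",
                    "retries (pairwise gap > %.0f nm required)"), i, min_gap)
    }
    phases <- stats::runif(p$n_clusters) * 2 * pi

    tt <- (seq_len(p$n_frames) - 1L) * p$frame_interval_s
    omega <- 2 * pi / p$cycle_period_s
    cyc <- function(t, lag, ph) sin(omega * (t - lag) + ph)

    dims <- c(p$n_frames, p$volume_shape)
    ser5p <- array(p$background, dim = dims)
    ser2p <- array(p$background, dim = dims)
    labels <- array(0L, dim = dims)
    truth <- vector("list", p$n_frames * p$n_clusters)
    sigma_vox <- p$psf_sigma_nm / p$voxel_size_nm

    for (fi in seq_len(p$n_frames)) {
      t <- tt[fi]
      s5 <- array(0, dim = p$volume_shape)
      s2 <- array(0, dim = p$volume_shape)
      lab <- array(0L, dim = p$volume_shape)
      for (ci in seq_len(p$n_clusters)) {
        ph <- phases[ci]
        i5 <- 1 + p$intensity_amplitude * cyc(t, 0, ph)
        i2 <- 1 + p$intensity_amplitude * cyc(t, p$lag_ser2p_s, ph)
        u <- (1 + cyc(t, p$lag_shape_s, ph)) / 2      # shape driver in [0,1]
        elong <- 1 + (p$elongation_max - 1) * u
        bend <- p$bend_max * u
        r <- p$cluster_radius_nm
        a <- r * elong^(2 / 3); b <- r * elong^(-1 / 3)  # volume-preserving
        vox <- ellipsoid_voxels(centers[ci, ], a, b, b, bend,
                                p$volume_shape, p$voxel_size_nm)
        if (nrow(vox) > 0L) {
          idx <- vox[, 1L] + (vox[, 2L] - 1L) * p$volume_shape[1L] +
            (vox[, 3L] - 1L) * prod(p$volume_shape[1:2])
          s5[idx] <- s5[idx] + p$peak_signal * i5
          s2[idx] <- s2[idx] + p$peak_signal * i2
          lab[idx] <- ci
        }
        truth[[(fi - 1L) * p$n_clusters + ci]] <- data.frame(
          frame = fi, cluster = ci, phase = ph, t_s = t,
          z_nm = centers[ci, 1L], y_nm = centers[ci, 2L],
          x_nm = centers[ci, 3L],
          axis_a_nm = a, axis_b_nm = b, bend = bend,
          elongation_true = elong, shape_driver = u,
          ser5p_true = i5, ser2p_true = i2, n_voxels = nrow(vox))
      }
      if (any(sigma_vox > 0)) {
        # clusters are sparse: blur only their joint bounding box
        nz <- which(s5 > 0, arr.ind = TRUE)
        if (nrow(nz) > 0L) {
          pad <- ceiling(4 * sigma_vox)
          lo <- pmax(1L, apply(nz, 2L, min) - pad)
          hi <- pmin(p$volume_shape, apply(nz, 2L, max) + pad)
          zi <- lo[1L]:hi[1L]; yi <- lo[2L]:hi[2L]; xi <- lo[3L]:hi[3L]
          s5[zi, yi, xi] <- gaussian_smooth(s5[zi, yi, xi, drop = FALSE],
                                            sigma_vox)
          s2[zi, yi, xi] <- gaussian_smooth(s2[zi, yi, xi, drop = FALSE],
                                            sigma_vox)
        }
      }
      ser5p[fi, , , ] <- ser5p[fi, , , ] + s5
      ser2p[fi, , , ] <- ser2p[fi, , , ] + s2
      labels[fi, , , ] <- lab
    }
    list(ser5p = ser5p, ser2p = ser2p, labels = labels,
         truth = do.call(rbind, truth), params = p)
  })
}
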