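# cluster_analysis module: segmentation, shape quantifiers, measurement,
# tracking.

test_that("segmentation finds rendered clusters and tolerates empties", {
  expect_equal(max(segment_clusters(array(0, c(4, 8, 8)))), 0L)
  expect_error(segment_clusters(array(NA_real_, c(4, 8, 8))),
               "non-finite")
  sp <- scene_params(n_frames = 2L, n_clusters = 1L, bend_max = 0,
                     seed = 31L)
  sc <- render_scene(sp)
  v <- array(sc$ser5p[1, , , ], dim = sp$volume_shape)
  lab <- segment_clusters(v)
  expect_equal(max(lab), 1L)
  m <- measure_clusters(lab, v, v, sp$voxel_size_nm)
  tr <- sc$truth[sc$truth$frame == 1, ]
  expect_lt(abs(m$z_nm - tr$z_nm), sp$voxel_size_nm[1])
  expect_lt(abs(m$y_nm - tr$y_nm), sp$voxel_size_nm[2])
  expect_lt(abs(m$x_nm - tr$x_nm), sp$voxel_size_nm[3])
  # two well-separated clusters give two labels
  sp2 <- scene_params(n_frames = 2L, n_clusters = 2L, seed = 32L)
  v2 <- array(render_scene(sp2)$ser5p[1, , , ], dim = sp2$volume_shape)
  expect_equal(max(segment_clusters(v2)), 2L)
})

test_that("cluster measurements honor intensity contracts", {
  # uniform-intensity ball: mean equals that intensity, shape ~ spherical
  co <- digital_ball(6)
  d <- apply(co, 2, max) + 1L
  lab <- array(0L, dim = d); lab[co] <- 1L
  s5 <- array(0, dim = d); s5[co] <- 40
  s2 <- 2 * s5
  m <- measure_clusters(lab, s5, s2, c(1, 1, 1))
  expect_equal(m$ser5p_mean, 40)
  expect_equal(m$ser2p_mean, 2 * m$ser5p_mean)  # linearity
  expect_lt(abs(m$elongation - 1), 0.05)
  expect_gt(m$solidity, 0.97)
  expect_equal(m$volume_vox, nrow(co))
  # absent wanted label warns and is skipped
  expect_warning(m2 <- measure_clusters(lab, s5, s2, c(1, 1, 1),
                                        labels_wanted = c(1L, 7L)),
                 "absent")
  expect_equal(nrow(m2), 1L)
  # mask-preserving relabeling conserves mean intensities
  lab2 <- lab; lab2[lab == 1L] <- 3L
  m3 <- measure_clusters(lab2, s5, s2, c(1, 1, 1))
  expect_equal(m3$ser5p_mean, m$ser5p_mean)
})

test_that("elongation matches analytic moments and is rotation-invariant", {
  expect_lt(abs(elongation(digital_ball(8), c(1, 1, 1)) - 1), 0.05)
  # (a, b, b) ellipsoid: covariance diag(a^2, b^2, b^2)/5 -> ratio a/b
  ell <- digital_ellipsoid(c(5, 5, 10))
  expect_lt(abs(elongation(ell, c(1, 1, 1)) - 2) / 2, 0.05)
  # anisotropic voxels, 2:1:1 in physical units
  ell_an <- digital_ellipsoid(c(10, 5, 10), spacing = c(2, 1, 1))
  expect_lt(abs(elongation(ell_an, c(2, 1, 1)) - 2) / 2, 0.05)
  # rotated copy agrees within 2%
  e0 <- elongation(digital_ellipsoid(c(6, 6, 12)), c(1, 1, 1))
  e30 <- elongation(digital_ellipsoid(c(6, 6, 12), angle_xy = pi / 6),
                    c(1, 1, 1))
  expect_lt(abs(e30 - e0) / e0, 0.02)
  # degenerate single-plane region: flagged, still finite
  flat <- as.matrix(expand.grid(z = 3, y = 1:6, x = 1:9))
  ef <- elongation(flat, c(1, 1, 1))
  expect_true(attr(ef, "degenerate"))
  expect_true(is.finite(ef))
  expect_error(elongation(flat[1:3, ], c(1, 1, 1)), ">= 4")
})

test_that("solidity matches the hull oracle and its bounds", {
  expect_equal(solidity(digital_cuboid(5, 7, 4)), 1)
  plus <- digital_plus()
  expect_equal(solidity(plus), oracle_solidity(plus), tolerance = 1e-9)
  expect_lt(solidity(plus), 1)
  set.seed(5)
  for (i in 1:3) {
    co <- unique(rbind(digital_cuboid(3, 4, 5),
                       as.matrix(expand.grid(z = 1:3, y = 1:2, x = 6:8))))
    expect_lte(solidity(co), 1 + 1e-9)
  }
  # shape measures ignore intensity: they only see the mask
  expect_error(solidity(digital_cuboid(5, 7, 4)[1:3, ]), ">= 4")
})

test_that("quickhull volume matches the plane-enumeration oracle", {
  set.seed(9)
  for (i in 1:4) {
    pts <- matrix(stats::rnorm(3 * 25), ncol = 3)
    expect_equal(convex_hull_volume(pts), oracle_hull_volume(pts),
                 tolerance = 1e-6)
  }
  expect_equal(convex_hull_volume(as.matrix(expand.grid(0:1, 0:1, 0:1))),
               1, tolerance = 1e-12)
  expect_error(convex_hull_volume(cbind(1:5, 1:5, 1:5)), "collinear")
  flat <- cbind(c(0, 1, 0, 1, 0.5), c(0, 0, 1, 1, 0.5), 0)
  expect_error(convex_hull_volume(flat), "coplanar")
})

test_that("tracking links by mutual proximity and respects gaps", {
  mk_obs <- function(frame, label, z, y, x)
    data.frame(frame = frame, label = label, z_nm = z, y_nm = y,
               x_nm = x)
  # one stationary cluster over 5 frames: a single track
  obs <- do.call(rbind, lapply(1:5, function(f) mk_obs(f, 1L, 0, 0, 0)))
  tr <- track_clusters(obs, linking_radius_nm = 100)
  expect_equal(length(unique(tr$track_id)), 1L)
  expect_equal(nrow(tr), 5L)
  # two slowly moving clusters never approaching: two pure tracks
  obs2 <- do.call(rbind, lapply(1:10, function(f)
    rbind(mk_obs(f, 1L, 0, 0, 50 * f),
          mk_obs(f, 2L, 0, 5000, -50 * f))))
  tr2 <- track_clusters(obs2, linking_radius_nm = 200)
  expect_equal(length(unique(tr2$track_id)), 2L)
  by_track <- split(tr2$y_nm, tr2$track_id)
  expect_true(all(vapply(by_track, function(v)
    length(unique(v)) == 1L, TRUE)))  # no identity switches
  # vanishing cluster ends its track; reappearance starts a new one
  obs3 <- rbind(mk_obs(1, 1L, 0, 0, 0), mk_obs(2, 1L, 0, 0, 10),
                mk_obs(4, 1L, 0, 0, 20))
  tr3 <- track_clusters(obs3, linking_radius_nm = 100, max_gap = 0L)
  expect_equal(length(unique(tr3$track_id)), 2L)
  tr3g <- track_clusters(obs3, linking_radius_nm = 100, max_gap = 1L)
  expect_equal(length(unique(tr3g$track_id)), 1L)
  expect_equal(attr(tr3g, "gaps"), 1L)
  # duplicate labels within a frame are an error
  expect_error(track_clusters(rbind(mk_obs(1, 1L, 0, 0, 0),
                                    mk_obs(1, 1L, 0, 0, 1)), 100),
               "duplicate")
})

test_that("tracking on a rendered scene recovers ground truth", {
  sp <- scene_params(n_frames = 10L, n_clusters = 3L, seed = 33L)
  sc <- render_scene(sp)
  obs <- measure_timelapse(sc$ser5p, sc$ser2p, sp$voxel_size_nm,
                           threshold_method = "quantile",
                           threshold_quantile = 0.99)
  tr <- track_clusters(obs, linking_radius_nm = 1000)
  expect_equal(length(unique(tr$track_id)), 3L)
  expect_true(all(table(tr$track_id) == 10L))
  # zero identity switches: every track stays at one true position
  drift <- tapply(seq_len(nrow(tr)), tr$track_id, function(i)
    max(dist(tr[i, c("z_nm", "y_nm", "x_nm")])))
  expect_lt(max(drift), 500)
})
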