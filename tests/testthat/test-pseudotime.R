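# pseudotime module: pairing, feature matrix, PCA/atan2 coordinate,
# profiles, register-shift correlation, reliability, cycle duration.

test_that("interaction pairs take the nearest cluster with documented
          tie-breaks", {
  foci <- data.frame(nucleus_id = c(1, 1, 2, 3), gene_id = "g",
                     z_nm = 0, y_nm = 0, x_nm = c(0, 10, 0, 0),
                     gene_intensity = 1:4)
  clusters <- data.frame(nucleus_id = c(1, 1, 2),
                         cluster_id = c(1, 2, 5),
                         z_nm = 0, y_nm = 0, x_nm = c(3, 100, 7),
                         ser5p_mean = c(10, 20, 30))
  expect_message(pairs <- build_pairs(foci, clusters), "dropped")
  expect_equal(nrow(pairs), 3L)  # nucleus 3 has no cluster
  expect_equal(pairs$cluster_id, c(1, 1, 5))
  expect_equal(pairs$distance_nm, c(3, 7, 7))
  # equidistant clusters: lowest cluster_id, logged
  cl2 <- data.frame(nucleus_id = 1, cluster_id = c(9, 4), z_nm = 0,
                    y_nm = 0, x_nm = c(5, -5), ser5p_mean = 1:2)
  expect_message(p2 <- build_pairs(foci[1, ], cl2), "tie")
  expect_equal(p2$cluster_id, 4)
})

test_that("feature matrix is z-scored and guards its preconditions", {
  pt <- make_pair_table(pair_cycle_params(n_pairs = 40L, seed = 3L))
  fm <- feature_matrix(pt$table)
  expect_equal(unname(colMeans(fm)), rep(0, ncol(fm)), tolerance = 1e-12)
  expect_equal(unname(apply(fm, 2, stats::sd)), rep(1, ncol(fm)),
               tolerance = 1e-12)
  tab <- pt$table
  tab$flat <- 5
  expect_warning(fm2 <- feature_matrix(tab, c("ser5p_mean", "ser2p_mean",
                                              "flat")),
                 "zero-variance")
  expect_equal(ncol(fm2), 2L)
  expect_error(feature_matrix(pt$table[1:5, ]), ">= 8")
})

test_that("pseudo-time follows the atan2 convention and stays in [0,1)", {
  pt <- make_pair_table(pair_cycle_params(n_pairs = 60L, noise_sd = 0.1,
                                          seed = 4L))
  ps <- pseudo_time(feature_matrix(pt$table))
  expect_true(all(ps$s >= 0 & ps$s < 1))
  # s is exactly the wrapped atan2 of the stored PC coordinates
  sref <- atan2(ps$pc2, ps$pc1) / (2 * pi)
  expect_equal(ps$s, sref - floor(sref), tolerance = 1e-12)
  expect_true(all(sort(ps$ordering) == seq_along(ps$s)))
  # rank-deficient input has no cyclic plane
  one_dim <- cbind(a = stats::rnorm(20))
  expect_error(pseudo_time(cbind(one_dim, 2 * one_dim)), "cyclic plane")
})

test_that("noise-free cycles are recovered exactly up to gauge", {
  # symmetric offsets make the PC-plane image a circle, so recovery is
  # exact; asymmetric offsets give an ellipse and only near-exact order
  p_circ <- pair_cycle_params(
    n_pairs = 1000L,
    feature_amplitudes = c(a = 1, b = 1, c = 1, d = 1),
    feature_phase_offsets = c(a = 0, b = pi / 2, c = pi, d = 3 * pi / 2),
    noise_sd = 0, seed = 5L)
  pt <- make_pair_table(p_circ)
  ps <- pseudo_time(feature_matrix(pt$table, c("a", "b", "c", "d")))
  expect_gt(abs(circular_correlation(2 * pi * ps$s, pt$true_phase)),
            0.999)
  # default (asymmetric) offsets still give near-perfect recovery
  pt2 <- make_pair_table(pair_cycle_params(n_pairs = 80L, noise_sd = 0,
                                           seed = 5L))
  ps2 <- pseudo_time(feature_matrix(pt2$table))
  expect_gt(abs(circular_correlation(2 * pi * ps2$s, pt2$true_phase)),
            0.95)
})

test_that("orientation gauge: reflecting PC2 reverses the circular
          ordering", {
  pt <- make_pair_table(pair_cycle_params(n_pairs = 40L, noise_sd = 0.05,
                                          seed = 6L))
  ps <- pseudo_time(feature_matrix(pt$table))
  s_ref <- atan2(-ps$pc2, ps$pc1) / (2 * pi)
  s_ref <- s_ref - floor(s_ref)
  # reflected coordinate reverses orientation: circular corr flips sign
  expect_equal(circular_correlation(2 * pi * ps$s, 2 * pi * s_ref), -1,
               tolerance = 1e-9)
})

test_that("profiles: window 1 is raw order, constants are preserved", {
  pt <- make_pair_table(pair_cycle_params(n_pairs = 30L, seed = 7L))
  ps <- pseudo_time(feature_matrix(pt$table))
  op1 <- order_profiles(pt$table, ps, "ser5p_mean", window = 1)
  expect_equal(op1$profiles$ser5p_mean,
               pt$table$ser5p_mean[order(ps$s)])
  tab <- pt$table; tab$const <- 4.2
  op2 <- order_profiles(tab, ps, "const", window = 7)
  expect_equal(op2$profiles$const, rep(4.2, 30))
})

test_that("register-shift correlation matches the circular
          autocorrelation oracle", {
  pt <- make_pair_table(pair_cycle_params(n_pairs = 24L, noise_sd = 0.2,
                                          seed = 8L))
  ps <- pseudo_time(feature_matrix(pt$table))
  rs <- register_shift_correlation(pt$table, ps, anchor = "ser5p_mean",
                                   features = "ser5p_mean",
                                   max_shift = 11, window = 1,
                                   n_bootstrap = 20, seed = 1)
  prof <- pt$table$ser5p_mean[order(ps$s)]
  oracle <- vapply(rs$shifts, function(k)
    oracle_circular_autocorr(prof, k), 0)
  expect_equal(unname(rs$features$ser5p_mean$mean), oracle,
               tolerance = 1e-10)
  expect_equal(unname(rs$features$ser5p_mean$mean[rs$shifts == 0]), 1)
  expect_error(register_shift_correlation(pt$table, ps, "ser5p_mean",
                                          max_shift = 24), "must be <")
})

test_that("reliability check separates rare from frequent contact", {
  expect_true(reliability_check(data.frame(distance_nm = rep(0, 10)),
                                200, 0.25)$pass)
  expect_false(reliability_check(data.frame(distance_nm = rep(5000, 10)),
                                 200, 0.25)$pass)
  rare <- data.frame(distance_nm = c(rep(50, 1), rep(3000, 9)))
  freq <- data.frame(distance_nm = c(rep(50, 6), rep(3000, 4)))
  expect_false(reliability_check(rare, 200, 0.25)$pass)
  expect_true(reliability_check(freq, 200, 0.25)$pass)
  expect_equal(reliability_check(freq, 200, 0.25)$contact_fraction, 0.6)
})

test_that("cycle duration arithmetic is linear in counts", {
  cd <- cycle_duration(50, 50, 10)
  expect_equal(cd$mean_s, 10)
  cd2 <- cycle_duration(c(10, 20), 50, 10)
  cd3 <- cycle_duration(c(20, 40), 50, 10)
  expect_equal(cd3$per_gene_s, 2 * cd2$per_gene_s)
  expect_error(cycle_duration(c(10, 20), 0, 10), "steps")
})
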