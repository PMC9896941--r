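# Gene-cluster interaction-pair tables lying on a noisy closed cycle in
# feature space, with the true cycle phase returned for recovery scoring.

#' Parameters of a synthetic interaction-pair cycle
#'
#' Each pair draws a true phase theta uniform on [0, 2pi); feature j is
#' amplitude_j * cos(theta + offset_j) + N(0, noise_sd_j). Default features
#' mirror the measured interaction-pair vector (gene intensity, cluster
#' Ser5P/Ser2P intensity, gene-cluster distance, elongation, solidity) with
#' phase offsets implied by the 36 s cycle: Ser2P 5 s after Ser5P, shape
#' 10 s after, distance maximal (gene detached) half a cycle after contact.
#'
#' @param n_pairs number of pairs (>= 8); default 186, a typical per-gene
#'   pair count in this assay.
#' @param feature_amplitudes named numeric vector, one entry per feature.
#' @param feature_phase_offsets radians, same names; at least two distinct
#'   offsets are required for a non-degenerate cycle plane.
#' @param noise_sd per-feature noise SD (recycled); default 25% of a unit
#'   amplitude.
#' @param baseline additive constant per feature (recycled), so features
#'   such as intensities stay positive.
#' @param seed integer seed.
#' @export
pair_cycle_params <- function(n_pairs = 186L,
                              feature_amplitudes = c(
                                gene_intensity = 1, ser5p_mean = 1,
                                ser2p_mean = 1, distance_nm = 1,
                                elongation = 1, solidity = 1),
                              feature_phase_offsets = c(
                                gene_intensity = pi / 2,
                                ser5p_mean = 0,
                                ser2p_mean = 2 * pi * 5 / 36,
                                distance_nm = pi,
                                elongation = 2 * pi * 10 / 36,
                                solidity = 2 * pi * 10 / 36 + pi),
                              noise_sd = 0.25, baseline = 3,
                              seed = 1L) {
  assert_scalar_num(n_pairs, "n_pairs", lower = 8, integer = TRUE)
  nms <- names(feature_amplitudes)
  if (is.null(nms) || !identical(sort(nms),
                                 sort(names(feature_phase_offsets))))
    stopf("feature_amplitudes and feature_phase_offsets need matching names")
  feature_phase_offsets <- feature_phase_offsets[nms]
  if (length(nms) < 2L)
    stopf("at least 2 features are required")
  if (length(unique(round(feature_phase_offsets %% (2 * pi), 10))) < 2L)
    warnf(paste("all phase offsets equal: the cycle is degenerate and the",
                "PCA plane collapses to a line"))
  structure(list(n_pairs = as.integer(n_pairs),
                 feature_amplitudes = feature_amplitudes,
                 feature_phase_offsets = feature_phase_offsets,
                 noise_sd = rep_len(noise_sd, length(nms)),
                 baseline = rep_len(baseline, length(nms)),
                 seed = as.integer(seed)),
            class = "pair_cycle_params")
}

#' Generate an interaction-pair table on a noisy feature-space cycle
#'
#' @param params a [pair_cycle_params()] object.
#' @return list with `table` (data.frame: pair_id, one column per feature)
#'   and `true_phase` (radians in [0, 2pi), the generating cycle phase).
#' @export
make_pair_table <- function(params) {
  stopifnot(inherits(params, "pair_cycle_params"))
  p <- params
  with_seed(p$seed, {
    theta <- stats::runif(p$n_pairs) * 2 * pi
    nms <- names(p$feature_amplitudes)
    cols <- lapply(seq_along(nms), function(j) {
      p$baseline[j] +
        p$feature_amplitudes[j] * cos(theta + p$feature_phase_offsets[j]) +
        stats::rnorm(p$n_pairs, sd = p$noise_sd[j])
    })
    names(cols) <- nms
    tab <- data.frame(pair_id = seq_len(p$n_pairs), cols)
    list(table = tab, true_phase = theta, params = p)
  })
}
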