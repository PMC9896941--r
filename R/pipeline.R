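# Pipeline runner: reproducible subcommands over a single YAML/JSON config,
# with a manifest (config hash, seed, package version, inputs/outputs)
# written next to every stage's outputs. Downstream stages refuse inputs
# lacking a manifest unless no_provenance = TRUE.

PIPELINE_COMMANDS <- c("simulate", "qc", "reconstruct", "segment-track",
                       "fluctuation", "pseudotime", "all")

#' Read a pipeline configuration (YAML or JSON)
#' @param path config file; `.json` is parsed as JSON, otherwise YAML.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stopf("config file not found: %s", path)
  if (grepl("\\.json$", path)) jsonlite::fromJSON(path,
                                                  simplifyVector = TRUE)
  else yaml::read_yaml(path)
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(config, tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

write_manifest <- function(out_dir, command, config, seed, inputs,
                           outputs) {
  manifest <- list(
    command = command,
    package = "polpulse",
    version = as.character(utils::packageVersion("polpulse")),
    config_hash = config_hash(config),
    seed = seed,
    inputs = inputs, outputs = outputs,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  path <- file.path(out_dir, paste0("manifest_", command, ".json"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  path
}

require_manifest <- function(out_dir, upstream, no_provenance) {
  if (no_provenance) return(invisible(TRUE))
  p <- file.path(out_dir, paste0("manifest_", upstream, ".json"))
  if (!file.exists(p))
    stopf(paste("input of stage '%s' lacks a manifest (%s); rerun the",
                "upstream stage or pass no_provenance = TRUE"),
          upstream, p)
  invisible(TRUE)
}

# field-level schema validation per command
validate_config <- function(config, command) {
  need <- switch(command,
    simulate = c("scene", "noise"),
    qc = c("noise", "denoiser", "qc_thresholds"),
    reconstruct = c("denoiser"),
    `segment-track` = c("scene", "segmentation", "tracking"),
    fluctuation = c("scene", "fluctuation"),
    pseudotime = c("pseudotime"),
    all = c("scene", "noise", "denoiser", "qc_thresholds",
            "segmentation", "tracking", "fluctuation", "pairs",
            "pseudotime"))
  miss <- setdiff(need, names(config))
  if (length(miss) > 0L)
    stopf("config for '%s' is missing block(s): %s", command,
          paste(miss, collapse = ", "))
  if ("qc_thresholds" %in% names(config)) {
    tneed <- c("min_resolution_nm", "min_ssim",
               "max_local_error_fraction", "local_ssim_floor")
    tmiss <- setdiff(tneed, names(config$qc_thresholds))
    if (length(tmiss) > 0L)
      stopf("config field qc_thresholds is missing: %s",
            paste(tmiss, collapse = ", "))
  }
  invisible(TRUE)
}

denoiser_from_config <- function(cfg) {
  type <- cfg$type %||% "gaussian"
  switch(type,
         identity = denoiser_identity(),
         gaussian = denoiser_gaussian(cfg$sigma %||% 1),
         median = denoiser_median(),
         external = denoiser_external(cfg$backend %||% "n2v"),
         stopf("unknown denoiser type '%s'", type))
}

#' Run a pipeline stage
#'
#' Subcommands: `simulate` (synthetic scene + acquisition + pair table),
#' `qc` (per-position QC gate), `reconstruct` (phase-B denoising, gated),
#' `segment-track`, `fluctuation`, `pseudotime`, `all`. Each stage writes
#' its outputs plus a manifest into `out_dir` and reads its inputs from
#' there.
#'
#' @param command one of the subcommands above.
#' @param config config list or path to a YAML/JSON file.
#' @param out_dir working directory for inputs/outputs.
#' @param seed overrides `config$seed`.
#' @param no_provenance accept inputs without a manifest.
#' @param override_qc reconstruct even for rejected positions (logged).
#' @return invisibly, a named list of produced artifact paths.
#' @export
run_pipeline <- function(command, config, out_dir, seed = NULL,
                         no_provenance = FALSE, override_qc = FALSE) {
  command <- match.arg(command, PIPELINE_COMMANDS)
  if (is.character(config)) config <- read_config(config)
  validate_config(config, command)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(seed %||% config$seed %||% 1L)
  stage <- function(cmd) run_pipeline(cmd, config, out_dir, seed,
                                      no_provenance = no_provenance,
                                      override_qc = override_qc)
  out <- switch(
    command,
    simulate = stage_simulate(config, out_dir, seed),
    qc = { require_manifest(out_dir, "simulate", no_provenance)
           stage_qc(config, out_dir, seed) },
    reconstruct = { require_manifest(out_dir, "qc", no_provenance)
                    stage_reconstruct(config, out_dir, seed,
                                      override_qc) },
    `segment-track` = { require_manifest(out_dir, "reconstruct",
                                         no_provenance)
                        stage_segment_track(config, out_dir, seed) },
    fluctuation = { require_manifest(out_dir, "segment-track",
                                     no_provenance)
                    stage_fluctuation(config, out_dir, seed) },
    pseudotime = { require_manifest(out_dir, "simulate", no_provenance)
                   stage_pseudotime(config, out_dir, seed) },
    all = {
      for (cmd in c("simulate", "qc", "reconstruct", "segment-track",
                    "fluctuation", "pseudotime")) stage(cmd)
      list(out_dir = out_dir)
    })
  invisible(out)
}

stage_simulate <- function(config, out_dir, seed) {
  sp <- do.call(scene_params, c(config$scene, list(seed = seed)))
  np <- do.call(noise_params,
                c(config$noise, list(seed = derive_seed(seed, 1L))))
  scene <- render_scene(sp)
  nt <- sp$n_frames
  dims5 <- c(nt, sp$volume_shape[1L], 2L, sp$volume_shape[2:3])
  noisy <- array(0, dim = dims5)
  for (fi in seq_len(nt)) {
    for (ch in 1:2) {
      clean <- array((if (ch == 1L) scene$ser5p else scene$ser2p)[fi, , , ],
                     dim = sp$volume_shape)
      noisy[fi, , ch, , ] <- apply_noise(
        clean, np, seed = derive_seed(seed, 1000L + fi * 2L + ch))
    }
  }
  f_scene <- file.path(out_dir, "scene.tif")
  write_tiff(f_scene, noisy, voxel_size_nm = sp$voxel_size_nm,
             metadata = list(frame_interval_s = sp$frame_interval_s,
                             channels = c("ser5p", "ser2p")))
  f_labels <- file.path(out_dir, "labels.tif")
  write_tiff(f_labels, scene$labels, voxel_size_nm = sp$voxel_size_nm)
  f_truth <- file.path(out_dir, "truth.csv")
  utils::write.csv(scene$truth, f_truth, row.names = FALSE)
  # phase-A set from the clean first Ser5P frame
  clean_vol <- array(scene$ser5p[1L, , , ], dim = sp$volume_shape)
  set <- make_acquisition_set(clean_vol, np, position_id = "pos1",
                              frame_interval_s = sp$frame_interval_s)
  fa <- character()
  for (nm in names(set$phase_a)) {
    f <- file.path(out_dir, paste0("phase_a_", nm, ".tif"))
    write_tiff(f, set$phase_a[[nm]], voxel_size_nm = sp$voxel_size_nm)
    fa <- c(fa, f)
  }
  pc <- do.call(pair_cycle_params,
                c(config$pairs %||% list(),
                  list(seed = derive_seed(seed, 2L))))
  pt <- make_pair_table(pc)
  f_pairs <- file.path(out_dir, "pairs.csv")
  utils::write.csv(cbind(pt$table, true_phase = pt$true_phase), f_pairs,
                   row.names = FALSE)
  outputs <- c(f_scene, f_labels, f_truth, fa, f_pairs)
  write_manifest(out_dir, "simulate", config, seed, character(), outputs)
  list(scene = f_scene, labels = f_labels, truth = f_truth,
       phase_a = fa, pairs = f_pairs)
}

read_phase_a <- function(out_dir) {
  nms <- c("low_quality", "high_quality_1", "high_quality_2", "test_1",
           "test_2")
  imgs <- lapply(nms, function(nm) {
    f <- file.path(out_dir, paste0("phase_a_", nm, ".tif"))
    if (!file.exists(f)) stopf("missing phase-A image: %s", f)
    read_tiff(f)$data
  })
  names(imgs) <- nms
  imgs
}

stage_qc <- function(config, out_dir, seed) {
  pa <- read_phase_a(out_dir)
  sc <- read_tiff(file.path(out_dir, "scene.tif"))
  nt <- dim(sc$data)[1L]
  phase_b <- array(sc$data[, , 1L, , ], dim = dim(sc$data)[-3L])
  np <- config$noise
  set <- acquisition_set("pos1", pa, phase_b,
                         exposure_time_ms = np$exposure_time_ms,
                         reference_exposure_ms = np$reference_exposure_ms)
  d <- denoiser_from_config(config$denoiser)
  px <- sc$metadata$voxel_size_nm[3L] %||% 100
  rep <- qc_gate(set, d, config$qc_thresholds, pixel_size_nm = px)
  f_json <- file.path(out_dir, "qc_report.json")
  jsonlite::write_json(unclass(rep), f_json, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  f_csv <- file.path(out_dir, "qc_summary.csv")
  utils::write.csv(data.frame(
    position_id = rep$position_id, decision = rep$decision,
    resolution_reconstructed_nm = rep$effective_resolution_reconstructed,
    resolution_raw_nm = rep$effective_resolution_raw,
    ssim_pairwise = rep$ssim_pairwise,
    ssim_vs_reference = rep$ssim_vs_reference,
    local_error_fraction = rep$local_error_fraction,
    reasons = paste(rep$reasons, collapse = ";")), f_csv,
    row.names = FALSE)
  write_manifest(out_dir, "qc", config, seed,
                 inputs = file.path(out_dir, "scene.tif"),
                 outputs = c(f_json, f_csv))
  list(report = f_json, summary = f_csv)
}

stage_reconstruct <- function(config, out_dir, seed, override_qc) {
  f_rep <- file.path(out_dir, "qc_report.json")
  rep_raw <- jsonlite::fromJSON(f_rep)
  sc <- read_tiff(file.path(out_dir, "scene.tif"))
  d <- denoiser_from_config(config$denoiser)
  if (rep_raw$decision != "accept" && !override_qc)
    stopf(paste("position '%s' is QC-rejected (%s); pass override_qc =",
                "TRUE to reconstruct anyway"), rep_raw$position_id,
          paste(rep_raw$reasons, collapse = ", "))
  if (override_qc && rep_raw$decision != "accept")
    message("QC override active for position ", rep_raw$position_id)
  dims <- dim(sc$data)
  out <- sc$data
  for (fi in seq_len(dims[1L])) for (ch in seq_len(dims[3L]))
    out[fi, , ch, , ] <- denoise(d, array(sc$data[fi, , ch, , ],
                                          dim = dims[c(2L, 4L, 5L)]))
  f_out <- file.path(out_dir, "reconstructed.tif")
  meta <- sc$metadata
  meta$provenance <- list(denoiser = d$name,
                          qc_decision = rep_raw$decision,
                          override = override_qc)
  write_tiff(f_out, out, dtype = "float32",
             voxel_size_nm = meta$voxel_size_nm,
             metadata = meta[setdiff(names(meta),
                                     c("axes", "shape", "voxel_size_nm"))])
  write_manifest(out_dir, "reconstruct", config, seed,
                 inputs = c(file.path(out_dir, "scene.tif"), f_rep),
                 outputs = f_out)
  list(reconstructed = f_out)
}

stage_segment_track <- function(config, out_dir, seed) {
  sc <- read_tiff(file.path(out_dir, "reconstructed.tif"))
  vz <- sc$metadata$voxel_size_nm
  fi_s <- sc$metadata$frame_interval_s %||%
    config$scene$frame_interval_s %||% 1
  seg <- config$segmentation
  obs <- measure_timelapse(
    array(sc$data[, , 1L, , ], dim = dim(sc$data)[-3L]),
    array(sc$data[, , 2L, , ], dim = dim(sc$data)[-3L]),
    voxel_size_nm = vz,
    background_subtract = seg$background_subtract %||% FALSE,
    erode_mask = seg$erode_mask %||% 0L,
    smoothing_sigma = seg$smoothing_sigma %||% 1,
    threshold_method = seg$threshold_method %||% "otsu",
    min_volume_vox = seg$min_volume_vox %||% 8L)
  tracks <- track_clusters(obs, config$tracking$linking_radius_nm,
                           max_gap = config$tracking$max_gap %||% 0L)
  tracks$t_seconds <- (tracks$frame - 1) * fi_s
  f_tracks <- file.path(out_dir, "tracks.csv")
  utils::write.csv(tracks, f_tracks, row.names = FALSE)
  write_manifest(out_dir, "segment-track", config, seed,
                 inputs = file.path(out_dir, "reconstructed.tif"),
                 outputs = f_tracks)
  list(tracks = f_tracks)
}

stage_fluctuation <- function(config, out_dir, seed) {
  tracks <- utils::read.csv(file.path(out_dir, "tracks.csv"))
  fc <- config$fluctuation
  xc <- cross_correlate_tracks(
    tracks,
    signals = fc$signals %||% c("ser5p_mean", "ser2p_mean", "solidity"),
    anchor = fc$anchor %||% "elongation",
    frame_interval_s = config$scene$frame_interval_s %||% 1,
    max_lag_s = fc$max_lag_s %||% 30,
    n_bootstrap = fc$n_bootstrap %||% 1000L,
    seed = derive_seed(seed, 3L),
    min_length = fc$min_length %||% 10L)
  rows <- do.call(rbind, lapply(names(xc$signals), function(s)
    data.frame(signal = s, lag_s = xc$lags_s,
               mean = xc$signals[[s]]$mean,
               ci_low = xc$signals[[s]]$ci_low,
               ci_high = xc$signals[[s]]$ci_high,
               n_tracks = xc$n_tracks)))
  f_cc <- file.path(out_dir, "crosscorr.csv")
  # positive lag = signal follows the anchor (documented output header)
  con <- file(f_cc, "w")
  writeLines(paste("# anchor:", xc$anchor,
                   "| positive lag = signal follows anchor"), con)
  utils::write.csv(rows, con, row.names = FALSE)
  close(con)
  write_manifest(out_dir, "fluctuation", config, seed,
                 inputs = file.path(out_dir, "tracks.csv"),
                 outputs = f_cc)
  list(crosscorr = f_cc)
}

stage_pseudotime <- function(config, out_dir, seed) {
  pairs <- utils::read.csv(file.path(out_dir, "pairs.csv"))
  pcfg <- config$pseudotime
  rel <- reliability_check(
    data.frame(distance_nm = pairs$distance_nm),
    radius_nm = pcfg$contact_radius_nm %||% 0,
    min_fraction = pcfg$min_contact_fraction %||% 0)
  fm <- feature_matrix(pairs)
  ps <- pseudo_time(fm)
  pairs$pc1 <- ps$pc1; pairs$pc2 <- ps$pc2; pairs$s <- ps$s
  f_pairs <- file.path(out_dir, "pairs_pseudotime.csv")
  utils::write.csv(pairs, f_pairs, row.names = FALSE)
  feats <- colnames(fm)
  op <- order_profiles(pairs, ps, feats, window = pcfg$window %||% NULL)
  f_prof <- file.path(out_dir, "profiles.csv")
  utils::write.csv(cbind(s = op$s, op$profiles), f_prof,
                   row.names = FALSE)
  rs <- register_shift_correlation(
    pairs, ps, anchor = pcfg$anchor_feature %||% "ser5p_mean",
    features = feats, max_shift = pcfg$max_shift %||% NULL,
    window = pcfg$window %||% NULL,
    n_bootstrap = pcfg$n_bootstrap %||% 200L,
    seed = derive_seed(seed, 4L))
  rows <- do.call(rbind, lapply(names(rs$features), function(f)
    data.frame(feature = f, shift = rs$shifts,
               mean = rs$features[[f]]$mean,
               ci_low = rs$features[[f]]$ci_low,
               ci_high = rs$features[[f]]$ci_high)))
  f_rs <- file.path(out_dir, "register_shift.csv")
  utils::write.csv(rows, f_rs, row.names = FALSE)
  f_rel <- file.path(out_dir, "reliability.json")
  jsonlite::write_json(rel, f_rel, auto_unbox = TRUE, pretty = TRUE)
  write_manifest(out_dir, "pseudotime", config, seed,
                 inputs = file.path(out_dir, "pairs.csv"),
                 outputs = c(f_pairs, f_prof, f_rs, f_rel))
  list(pairs = f_pairs, profiles = f_prof, register_shift = f_rs,
       reliability = f_rel)
}

#' Default demo configuration
#'
#' A small, fast configuration exercising every stage on synthetic data;
#' the values mirror the package defaults (36 s cycle, 5 s / 10 s lags,
#' 2 s frames).
#' @export
demo_config <- function() {
  list(
    seed = 1L,
    scene = list(volume_shape = c(12L, 72L, 72L), n_clusters = 2L,
                 n_frames = 40L),
    noise = list(exposure_time_ms = 50, reference_exposure_ms = 200,
                 read_noise_sd = 2),
    denoiser = list(type = "gaussian", sigma = c(0.5, 1, 1)),
    qc_thresholds = list(min_resolution_nm = 800, min_ssim = 0.3,
                         max_local_error_fraction = 0.5,
                         local_ssim_floor = 0),
    segmentation = list(smoothing_sigma = 1, threshold_method = "otsu",
                        min_volume_vox = 8L, background_subtract = TRUE,
                        erode_mask = 2L),
    tracking = list(linking_radius_nm = 1000, max_gap = 0L),
    fluctuation = list(anchor = "elongation", max_lag_s = 16,
                       n_bootstrap = 200L),
    pairs = list(n_pairs = 120L, noise_sd = 0.25),
    pseudotime = list(anchor_feature = "ser5p_mean",
                      n_bootstrap = 100L))
}
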