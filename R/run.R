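#' Run configuration
#'
#' Bundles everything needed for a reproducible end-to-end run: the
#' experiment preset (which fixes stimulus conditions and model strip/filter
#' parameters), rendering geometry, model constants, the kernel-frequency
#' sweep grid, the synthetic-observer link, and the run seed. All randomness
#' in a run flows from this single seed.
#'
#' @param preset `"exp1"` (deforming bar), `"exp2"` (moire illusion),
#'   `"exp3"` (moire, bar-luminance series), or `"custom"`.
#' @param seed Integer run seed.
#' @param pixels_per_degree,frame_rate,n_frames Rendering geometry.
#' @param conditions Optional integer subset of the preset's condition rows.
#' @param kernel_fs Kernel spatial frequencies for NCC profiles and sweeps.
#' @param link_f Kernel frequency whose direction-map NCC drives the
#'   synthetic observer.
#' @param link_a,link_b Generating parameters of the exponential link
#'   `p = a * exp(b * ncc)`.
#' @param n_trials Synthetic trials per condition.
#' @param max_response,semi_saturation Normalization constants.
#' @param temporal_freq Filter carrier temporal frequency (Hz).
#' @param custom_conditions For `preset = "custom"`: a data frame of stimulus
#'   conditions (same columns as the preset tables).
#' @return A `run_config` list.
#' @export
run_config <- function(preset = c("exp1", "exp2", "exp3", "custom"),
                       seed = 1,
                       pixels_per_degree = 200, frame_rate = 60,
                       n_frames = 180,
                       conditions = NULL,
                       kernel_fs = c(0.1, 0.2, 0.4, 0.8, 1.6, 3.2, 6.4),
                       link_f = 0.2, link_a = 0.1, link_b = 2.0,
                       n_trials = 70,
                       max_response = 1, semi_saturation = 0.1,
                       temporal_freq = 0.4,
                       custom_conditions = NULL) {
  preset <- match.arg(preset)
  cfg <- list(preset = preset, seed = as.integer(seed),
              pixels_per_degree = pixels_per_degree,
              frame_rate = frame_rate, n_frames = as.integer(n_frames),
              conditions = conditions,
              kernel_fs = kernel_fs, link_f = link_f,
              link_a = link_a, link_b = link_b,
              n_trials = as.integer(n_trials),
              max_response = max_response,
              semi_saturation = semi_saturation,
              temporal_freq = temporal_freq,
              custom_conditions = custom_conditions)
  class(cfg) <- "run_config"
  cfg
}

#' Serialize / parse a run configuration (YAML)
#'
#' `parse_run_config(serialize_run_config(cfg))` reproduces `cfg` exactly:
#' parsing re-canonicalizes through [run_config()].
#'
#' @param config A `run_config`.
#' @return `serialize_run_config`: a YAML string; `parse_run_config`: a
#'   `run_config`.
#' @export
serialize_run_config <- function(config) {
  stopifnot(inherits(config, "run_config"))
  x <- unclass(config)
  x$schema_version <- 1L
  yaml::as.yaml(x)
}

#' @param text A YAML string produced by [serialize_run_config()].
#' @rdname serialize_run_config
#' @export
parse_run_config <- function(text) {
  x <- yaml::yaml.load(text)
  if (!identical(as.integer(x$schema_version), 1L)) {
    stop("unknown run_config schema version: ", x$schema_version, call. = FALSE)
  }
  x$schema_version <- NULL
  if (!is.null(x$custom_conditions)) {
    x$custom_conditions <- as.data.frame(x$custom_conditions)
  }
  do.call(run_config, x)
}

#' Stimulus condition tables for the experiment presets
#'
#' One row per simulated condition. The deforming-bar preset crosses seven
#' modulation frequencies (fixed amplitude 0.04 deg, 1 Hz, downward drift,
#' dark bar 38 cd/m^2 on a 76 cd/m^2 background). The moire preset crosses
#' seven grating tilts with three grating frequencies; the analysis strip
#' width and filter-position count follow the grating frequency
#' (0.16 deg/32, 0.08 deg/64, 0.04 deg/128). The bar-luminance preset holds
#' the grating at 12.9 cpd and tilts 1 or 16 deg while the bar takes nine
#' luminances spanning the neutral gray.
#'
#' @param config A [run_config()].
#' @return A data frame of conditions with model-parameter columns
#'   `strip_width_deg` and `n_positions`.
#' @export
preset_conditions <- function(config) {
  tab <- switch(config$preset,
    exp1 = data.frame(
      condition = paste0("sf", c(0.1, 0.2, 0.4, 0.8, 1.6, 3.2, 6.4)),
      stimulus = "deforming_bar",
      deform_sf = c(0.1, 0.2, 0.4, 0.8, 1.6, 3.2, 6.4),
      amplitude_deg = 0.04, modulation_tf = 1, drift_sign = -1,
      bar_luminance = 38, background_luminance = 76,
      strip_width_deg = 0.08, n_positions = 64L),
    exp2 = {
      g <- expand.grid(
        grating_orientation_deg = c(0.5, 1, 2, 4, 8, 12, 16),
        grating_sf = c(6.4, 12.9, 25.8))
      sw <- c(`6.4` = 0.16, `12.9` = 0.08, `25.8` = 0.04)
      np <- c(`6.4` = 32L, `12.9` = 64L, `25.8` = 128L)
      data.frame(
        condition = sprintf("ori%g_sf%g", g$grating_orientation_deg,
                            g$grating_sf),
        stimulus = "moire",
        grating_orientation_deg = g$grating_orientation_deg,
        grating_sf = g$grating_sf, grating_tf = 1,
        grating_contrast = 0.75, bar_luminance = 37,
        strip_width_deg = unname(sw[as.character(g$grating_sf)]),
        n_positions = unname(np[as.character(g$grating_sf)]))
    },
    exp3 = {
      g <- expand.grid(
        bar_luminance = c(0, 17.5, 37, 58, 76, 95, 112, 132, 148),
        grating_orientation_deg = c(1, 16))
      data.frame(
        condition = sprintf("ori%g_lum%g", g$grating_orientation_deg,
                            g$bar_luminance),
        stimulus = "moire",
        grating_orientation_deg = g$grating_orientation_deg,
        grating_sf = 12.9, grating_tf = 1, grating_contrast = 0.75,
        bar_luminance = g$bar_luminance,
        strip_width_deg = 0.08, n_positions = 64L)
    },
    custom = {
      if (is.null(config$custom_conditions)) {
        stop("custom preset requires custom_conditions", call. = FALSE)
      }
      config$custom_conditions
    })
  if (!is.null(config$conditions)) tab <- tab[config$conditions, , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

#' Trial schedules of the three psychophysical designs
#'
#' The deforming-bar design: 2 sessions x 7 modulation frequencies x 10
#' repetitions = 140 trials. The moire design: 4 sessions x 3 grating
#' frequencies x 7 tilts x 5 repetitions = 420. The bar-luminance design:
#' 4 sessions x 2 tilts x 9 luminances x 5 repetitions = 360.
#'
#' @param preset `"exp1"`, `"exp2"` or `"exp3"`.
#' @param seed Shuffle seed.
#' @return A [build_trial_schedule()] result.
#' @export
preset_trial_schedule <- function(preset = c("exp1", "exp2", "exp3"),
                                  seed = 1) {
  preset <- match.arg(preset)
  switch(preset,
    exp1 = build_trial_schedule(
      list(deform_sf = c(0.1, 0.2, 0.4, 0.8, 1.6, 3.2, 6.4)),
      sessions = 2, repetitions = 10, seed = seed),
    exp2 = build_trial_schedule(
      list(grating_sf = c(6.4, 12.9, 25.8),
           grating_orientation_deg = c(0.5, 1, 2, 4, 8, 12, 16)),
      sessions = 4, repetitions = 5, seed = seed),
    exp3 = build_trial_schedule(
      list(grating_orientation_deg = c(1, 16),
           bar_luminance = c(0, 17.5, 37, 58, 76, 95, 112, 132, 148)),
      sessions = 4, repetitions = 5, seed = seed))
}

.render_condition <- function(row, geom) {
  if (row$stimulus == "deforming_bar") {
    spec <- deforming_bar_spec(
      deform_sf = row$deform_sf, amplitude_deg = row$amplitude_deg,
      modulation_tf = row$modulation_tf, drift_sign = row$drift_sign,
      bar_luminance = row$bar_luminance,
      background_luminance = row$background_luminance)
    render_deforming_bar(spec, geom)
  } else {
    spec <- moire_spec(
      grating_orientation_deg = row$grating_orientation_deg,
      grating_sf = row$grating_sf, grating_tf = row$grating_tf,
      grating_contrast = row$grating_contrast,
      bar_luminance = row$bar_luminance)
    render_moire_stimulus(spec, geom)
  }
}

#' End-to-end experiment run
#'
#' For every condition of the preset: render the clip, compute the V1
#' energy map and MT direction map, and score both with the kernel across
#' the sweep frequencies. A synthetic observer is then simulated from the
#' direction-map NCCs at `link_f` via the exponential link, and the
#' kernel-frequency sweep fits the link for every kernel frequency against
#' both map types, yielding the r2 curves and their argmax.
#'
#' @param config A [run_config()].
#' @param outdir Optional output directory; when given, writes per-condition
#'   map CSVs, NCC profiles, the synthetic dataset, sweep tables, the
#'   serialized config and a manifest.
#' @param keep_maps Keep the (large) map objects in the returned bundle.
#' @param verbose Print per-condition progress.
#' @return A `run_bundle`: `conditions`, `profiles` (long data frame of NCC
#'   by condition, map type and kernel f), `dataset`, `sweeps` (list with
#'   `energy` and `direction` sweep tables), `schedule`, `maps` (if kept),
#'   `manifest`.
#' @export
run_experiment_preset <- function(config, outdir = NULL, keep_maps = TRUE,
                                  verbose = FALSE) {
  stopifnot(inherits(config, "run_config"))
  tab <- preset_conditions(config)
  geom <- clip_geometry(pixels_per_degree = config$pixels_per_degree,
                        frame_rate = config$frame_rate,
                        n_frames = config$n_frames)
  constants <- normalization_constants(config$max_response,
                                       config$semi_saturation)
  maps <- vector("list", nrow(tab))
  profiles <- list()
  for (i in seq_len(nrow(tab))) {
    row <- tab[i, , drop = FALSE]
    if (verbose) message("condition ", row$condition)
    clip <- .render_condition(row, geom)
    params <- model_params(strip_width_deg = row$strip_width_deg,
                           n_positions = row$n_positions,
                           temporal_freq = config$temporal_freq,
                           constants = constants)
    m <- compute_model_maps(clip, params)
    rm(clip)
    maps[[i]] <- m
    for (type in c("energy", "direction")) {
      pr <- ncc_profile(m[[type]], fs = config$kernel_fs)
      pr$condition <- row$condition
      pr$map_type <- type
      profiles[[length(profiles) + 1]] <- pr
    }
  }
  profiles <- do.call(rbind, profiles)
  link_ncc <- vapply(maps, function(m) {
    max_ncc_over_phase(config$link_f, m$direction)$ncc
  }, numeric(1))
  dataset <- simulate_observer(config$link_a, config$link_b, link_ncc,
                               n_trials = config$n_trials,
                               seed = config$seed,
                               condition = tab$condition)
  sweeps <- list(
    energy = kernel_frequency_sweep(lapply(maps, `[[`, "energy"), dataset,
                                    fs = config$kernel_fs),
    direction = kernel_frequency_sweep(lapply(maps, `[[`, "direction"),
                                       dataset, fs = config$kernel_fs))
  schedule <- if (config$preset %in% c("exp1", "exp2", "exp3")) {
    preset_trial_schedule(config$preset, seed = config$seed)
  }
  cfg_yaml <- serialize_run_config(config)
  manifest <- list(
    config_md5 = .string_md5(cfg_yaml),
    seed = config$seed,
    n_conditions = nrow(tab),
    r_version = as.character(getRversion()),
    package_version = as.character(utils::packageVersion("deformsense"))
  )
  bundle <- list(conditions = tab, profiles = profiles, dataset = dataset,
                 sweeps = sweeps, schedule = schedule,
                 maps = if (keep_maps) maps else NULL,
                 config = config, manifest = manifest)
  class(bundle) <- "run_bundle"
  if (!is.null(outdir)) .write_bundle(bundle, outdir, cfg_yaml)
  bundle
}

.string_md5 <- function(s) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(s, f)
  unname(tools::md5sum(f))
}

.write_bundle <- function(bundle, outdir, cfg_yaml) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(bundle$profiles, file.path(outdir, "ncc_profiles.csv"),
                   row.names = FALSE)
  write_dataset_csv(bundle$dataset, file.path(outdir, "dataset.csv"))
  for (type in names(bundle$sweeps)) {
    utils::write.csv(bundle$sweeps[[type]],
                     file.path(outdir, paste0("sweep_", type, ".csv")),
                     row.names = FALSE)
  }
  if (!is.null(bundle$maps)) {
    for (i in seq_along(bundle$maps)) {
      cond <- bundle$conditions$condition[i]
      write_map_csv(bundle$maps[[i]]$energy,
                    file.path(outdir, paste0("energy_", cond, ".csv")))
      write_map_csv(bundle$maps[[i]]$direction,
                    file.path(outdir, paste0("direction_", cond, ".csv")))
    }
  }
  writeLines(cfg_yaml, file.path(outdir, "config.yaml"))
  jsonlite::write_json(bundle$manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(outdir)
}

#' Miniature seeded fixtures for testing
#'
#' Emits small deterministic objects: a zero-amplitude bar clip and a
#' deforming mini-clip (both <= 0.5 deg, <= 12 frames), a one-hot energy
#' map, a direction map derived from a 0.4 cpd kernel (whose NCC profile
#' argmax is therefore 0.4), and a seeded random map.
#'
#' @param seed Integer seed.
#' @param dir Optional directory; when given, clips and maps are written
#'   there (TIFF + CSV) and the file list is returned in the result.
#' @return A named list of fixtures.
#' @export
generate_fixtures <- function(seed = 1, dir = NULL) {
  geom <- clip_geometry(pixels_per_degree = 100, frame_rate = 60,
                        width_deg = 0.5, height_deg = 0.5, n_frames = 12)
  flat_spec <- deforming_bar_spec(deform_sf = 2, amplitude_deg = 0,
                                  bar_width_deg = 0.2, bar_height_deg = 0.4,
                                  bar_luminance = 38,
                                  background_luminance = 76)
  wobble_spec <- deforming_bar_spec(deform_sf = 2, amplitude_deg = 0.02,
                                    bar_width_deg = 0.2, bar_height_deg = 0.4,
                                    bar_luminance = 38,
                                    background_luminance = 76)
  dirs <- (0:23) * 15
  pos <- seq(0, 4.97, length.out = 61)
  onehot <- matrix(0, 61, 24)
  onehot[, dirs == 180] <- 1
  kmap <- build_kernel(kernel_spec(0.4, phi = 0.5), pos, dirs)
  noise <- withr::with_seed(seed, matrix(stats::runif(61 * 24), 61, 24))
  fx <- list(
    flat_bar_clip = render_deforming_bar(flat_spec, geom),
    wobble_bar_clip = render_deforming_bar(wobble_spec, geom),
    onehot_energy = new_energy_map(onehot, pos, pos[2] - pos[1], dirs,
                                   normalization_constants()),
    kernel_direction_map = new_direction_map(1 + kmap$values, pos,
                                             pos[2] - pos[1], dirs,
                                             normalization_constants()),
    random_map = new_direction_map(noise, pos, pos[2] - pos[1], dirs,
                                   normalization_constants())
  )
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    write_clip(fx$flat_bar_clip, file.path(dir, "flat_bar.tif"))
    write_clip(fx$wobble_bar_clip, file.path(dir, "wobble_bar.tif"))
    write_map_csv(fx$onehot_energy, file.path(dir, "onehot_energy.csv"))
    write_map_csv(fx$kernel_direction_map,
                  file.path(dir, "kernel_direction_map.csv"))
    write_map_csv(fx$random_map, file.path(dir, "random_map.csv"))
    fx$files <- list.files(dir, full.names = TRUE)
  }
  fx
}
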