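test_that("run configuration round-trips losslessly through YAML", {
  cfg <- run_config(preset = "exp1", seed = 7, n_frames = 12,
                    conditions = c(1L, 3L), kernel_fs = c(0.2, 0.8),
                    link_a = 0.12, n_trials = 40)
  expect_equal(parse_run_config(serialize_run_config(cfg)), cfg)

  custom <- run_config(
    preset = "custom", seed = 2, pixels_per_degree = 50, n_frames = 6,
    custom_conditions = data.frame(
      condition = c("a", "b", "c"), stimulus = "deforming_bar",
      deform_sf = c(0.2, 0.8, 3.2), amplitude_deg = 0.04,
      modulation_tf = 1, drift_sign = -1, bar_luminance = 38,
      background_luminance = 76, strip_width_deg = 0.08, n_positions = 40L))
  expect_equal(parse_run_config(serialize_run_config(custom)), custom)
  expect_error(parse_run_config("schema_version: 99"), "schema version")
})

test_that("preset condition tables carry the reference factor structure", {
  exp1 <- preset_conditions(run_config("exp1"))
  expect_identical(nrow(exp1), 7L)
  expect_identical(exp1$deform_sf, c(0.1, 0.2, 0.4, 0.8, 1.6, 3.2, 6.4))
  expect_true(all(exp1$n_positions == 64L))

  exp2 <- preset_conditions(run_config("exp2"))
  expect_identical(nrow(exp2), 21L)
  expect_identical(sort(unique(exp2$grating_orientation_deg)),
                   c(0.5, 1, 2, 4, 8, 12, 16))
  key <- unique(exp2[, c("grating_sf", "strip_width_deg", "n_positions")])
  expect_identical(key$strip_width_deg[order(key$grating_sf)],
                   c(0.16, 0.08, 0.04))
  expect_identical(key$n_positions[order(key$grating_sf)],
                   c(32L, 64L, 128L))

  exp3 <- preset_conditions(run_config("exp3"))
  expect_identical(nrow(exp3), 18L)
  expect_identical(sort(unique(exp3$bar_luminance)),
                   c(0, 17.5, 37, 58, 76, 95, 112, 132, 148))
  expect_identical(unique(exp3$grating_sf), 12.9)
})

test_that("fixtures are deterministic, miniature, and self-consistent", {
  fx1 <- generate_fixtures(seed = 3)
  fx2 <- generate_fixtures(seed = 3)
  expect_identical(fx1, fx2)
  expect_false(identical(fx1$random_map$values,
                         generate_fixtures(seed = 4)$random_map$values))

  d <- dim(fx1$flat_bar_clip$frames)
  expect_lte(fx1$flat_bar_clip$geometry$width_deg, 0.5)
  expect_lte(d[3], 12)
  for (k in 2:d[3]) {
    expect_identical(fx1$flat_bar_clip$frames[, , k],
                     fx1$flat_bar_clip$frames[, , 1])
  }
  prof <- ncc_profile(fx1$kernel_direction_map)
  expect_identical(prof$f[which.max(prof$best_ncc)], 0.4)

  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  f1 <- generate_fixtures(seed = 3, dir = dir1)$files
  f2 <- generate_fixtures(seed = 3, dir = dir2)$files
  expect_identical(basename(f1), basename(f2))
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
})

small_custom_cfg <- function(seed = 1) {
  run_config(
    preset = "custom", seed = seed, pixels_per_degree = 50, n_frames = 6,
    kernel_fs = c(0.2, 0.8), link_f = 0.2, n_trials = 50,
    custom_conditions = data.frame(
      condition = c("lo", "mid", "hi"), stimulus = "deforming_bar",
      deform_sf = c(0.2, 0.8, 3.2), amplitude_deg = 0.04,
      modulation_tf = 1, drift_sign = -1, bar_luminance = 38,
      background_luminance = 76, strip_width_deg = 0.08,
      n_positions = 40L))
}

test_that("end-to-end runs are deterministic and compose from stages", {
  cfg <- small_custom_cfg()
  b1 <- run_experiment_preset(cfg)
  b2 <- run_experiment_preset(cfg)
  expect_identical(b1$dataset, b2$dataset)
  expect_identical(b1$profiles, b2$profiles)
  expect_identical(b1$sweeps, b2$sweeps)

  # stage-wise recomputation of one bundle entry
  geom <- clip_geometry(pixels_per_degree = 50, n_frames = 6)
  clip <- render_deforming_bar(deforming_bar_spec(deform_sf = 0.8), geom)
  D <- compute_direction_map(clip, model_params(n_positions = 40))
  manual <- max_ncc_over_phase(0.2, D)$ncc
  got <- b1$profiles[b1$profiles$condition == "mid" &
                       b1$profiles$map_type == "direction" &
                       b1$profiles$f == 0.2, "best_ncc"]
  expect_identical(got, manual)
  expect_identical(nrow(b1$dataset), 3L)
})

test_that("bundles write a complete, re-readable output directory", {
  out <- withr::local_tempdir()
  bundle <- run_experiment_preset(small_custom_cfg(), outdir = out)
  expect_true(all(file.exists(file.path(out, c(
    "ncc_profiles.csv", "dataset.csv", "sweep_energy.csv",
    "sweep_direction.csv", "config.yaml", "manifest.json",
    "direction_lo.csv", "energy_hi.csv")))))
  back <- read_dataset_csv(file.path(out, "dataset.csv"))
  expect_equal(back$proportion, bundle$dataset$proportion)
  dmap <- read_map_csv(file.path(out, "direction_mid.csv"))
  expect_equal(dmap$values, unname(bundle$maps[[2]]$direction$values),
               tolerance = 1e-12, ignore_attr = TRUE)
  cfg_back <- parse_run_config(paste(readLines(file.path(out, "config.yaml")),
                                     collapse = "\n"))
  expect_equal(cfg_back, bundle$config)
  manifest <- jsonlite::read_json(file.path(out, "manifest.json"))
  expect_identical(manifest$n_conditions, 3L)
})
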