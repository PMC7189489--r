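mini_geom <- function(n_frames = 3, ppd = 100)
  clip_geometry(pixels_per_degree = ppd, width_deg = 0.5, height_deg = 0.6,
                n_frames = n_frames)

mini_bar <- function(...)
  deforming_bar_spec(bar_width_deg = 0.2, bar_height_deg = 0.4,
                     ...)

test_that("zero-amplitude bar renders static frames with exact luminances", {
  clip <- render_deforming_bar(mini_bar(deform_sf = 2, amplitude_deg = 0),
                               mini_geom())
  for (k in 2:3) expect_identical(clip$frames[, , k], clip$frames[, , 1])
  # bar center (0.25, 0.3) deg and a far corner, away from any edge
  expect_identical(clip$frames[30, 25, 1], 38)
  expect_identical(clip$frames[3, 3, 1], 76)
})

test_that("rendered edge locus matches the closed-form sinusoid sub-pixel", {
  geom <- clip_geometry(pixels_per_degree = 200, width_deg = 1.0,
                        height_deg = 5.2, n_frames = 2)
  spec <- deforming_bar_spec(deform_sf = 0.5, amplitude_deg = 0.1)
  clip <- render_deforming_bar(spec, geom)
  ppd <- 200
  rows <- 150:850                       # strictly interior bar rows
  for (k in 1:2) {
    t <- (k - 1) / geom$frame_rate
    fr <- clip$frames[, , k]
    # right-edge locus from per-row luminance coverage right of bar center
    cov <- (76 - fr[rows, 101:200]) / (76 - 38)
    est_px <- 100 + rowSums(cov)
    y <- (rows - 0.5) / ppd
    true_px <- (0.8 + deforming_edge_offset(spec, y, t)) * ppd
    expect_lt(max(abs(est_px - true_px)), 0.5)
  }
})

test_that("deforming clips repeat at the period and reverse with drift sign", {
  geom <- mini_geom(n_frames = 12)
  down <- render_deforming_bar(
    mini_bar(deform_sf = 2, amplitude_deg = 0.02, modulation_tf = 6,
             drift_sign = -1), geom)
  up <- render_deforming_bar(
    mini_bar(deform_sf = 2, amplitude_deg = 0.02, modulation_tf = 6,
             drift_sign = 1), geom)
  P <- geom$frame_rate / 6              # 10-frame period
  expect_all_close(down$frames[, , 1], down$frames[, , 1 + P], 1e-10)
  expect_all_close(up$frames[, , 2], up$frames[, , 2 + P], 1e-10)
  # time reversal: downward frame k = upward frame (P + 2 - k)
  for (k in c(1, 2, 5)) {
    expect_all_close(down$frames[, , k], up$frames[, , P + 2 - k], 1e-10)
  }
})

test_that("stimuli that do not fit the raster are rejected", {
  expect_error(
    render_deforming_bar(mini_bar(deform_sf = 1, amplitude_deg = 0.16),
                         mini_geom()),
    "exits the field")
  expect_error(
    render_moire_stimulus(moire_spec(1, grating_sf = 25.8),
                          clip_geometry(pixels_per_degree = 50, n_frames = 2)),
    "px/deg")
  expect_error(
    stimulus_clip(array(1, c(2, 2, 2)), mini_geom()), "does not match")
  expect_error(
    stimulus_clip(array(-1, c(60, 50, 3)), mini_geom()), ">= 0")
})

test_that("zero-contrast moire background is uniform at the mean luminance", {
  geom <- clip_geometry(pixels_per_degree = 100, width_deg = 1.0,
                        height_deg = 1.2, n_frames = 2)
  clip <- render_moire_stimulus(
    moire_spec(1, grating_contrast = 0, bar_width_deg = 0.2,
               bar_height_deg = 0.4, mean_luminance = 74.5,
               bar_luminance = 37), geom)
  expect_identical(clip$frames[5, 5, 1], 74.5)
  expect_identical(clip$frames[5, 5, 2], 74.5)
  expect_identical(clip$frames[60, 50, 1], 37)   # bar center (0.5, 0.6) deg
})

test_that("moire crest-crossing kinematics match the closed form", {
  geom <- clip_geometry(n_frames = 8)
  spec <- moire_spec(grating_orientation_deg = 2, grating_sf = 25.8)
  clip <- render_moire_stimulus(spec, geom)
  ppd <- geom$pixels_per_degree
  col <- round((clip$metadata$bar_right_edge_deg + 0.05) * ppd)
  th <- spec$grating_orientation_deg * pi / 180
  ky <- 2 * pi * spec$grating_sf * sin(th)
  rows <- seq_len(round(4 * 2 * pi / ky * ppd))   # integer number of cycles
  y <- (rows - 0.5) / ppd
  ph <- sapply(seq_len(8), function(k) {
    v <- clip$frames[rows, col, k]
    v <- v - mean(v)
    atan2(sum(v * sin(ky * y)), sum(v * cos(ky * y)))
  })
  dph <- (diff(ph) + pi) %% (2 * pi) - pi
  shift <- dph / ky                        # crest displacement per frame, deg
  expected <- spec$grating_tf / (spec$grating_sf * sin(th)) / geom$frame_rate
  expect_true(all(shift > 0))              # positive tilt + drift: downward
  expect_lt(max(abs(shift - expected)), 1 / ppd)
})

test_that("analysis strip has the expected pixel extents and exact content", {
  geom <- clip_geometry(n_frames = 2)
  clip <- render_deforming_bar(deforming_bar_spec(deform_sf = 0.4), geom)
  strip <- extract_analysis_strip(clip, 0.08)
  expect_identical(dim(strip$frames)[1:2],
                   as.integer(c(round(4.97 * 200), round(0.08 * 200))))
  # independent index arithmetic: bar right edge at 0.8 deg, center y 2.6 deg
  cols <- (round(0.8 * 200 - 8) + 1):(round(0.8 * 200 - 8) + 16)
  rows <- (round(2.6 * 200 - 497) + 1):(round(2.6 * 200 - 497) + 994)
  expect_identical(strip$frames, clip$frames[rows, cols, , drop = FALSE])
  expect_identical(sum(strip$frames), sum(clip$frames[rows, cols, ]))
})

test_that("whole-frame strip is the identity and out-of-bounds strips fail", {
  geom <- clip_geometry(pixels_per_degree = 100, width_deg = 0.5,
                        height_deg = 0.6, n_frames = 2)
  clip <- render_deforming_bar(mini_bar(deform_sf = 1), geom)
  whole <- extract_analysis_strip(clip, 0.5, strip_height_deg = 0.6,
                                  center_x_deg = 0.25, center_y_deg = 0.3)
  expect_identical(whole$frames, clip$frames)
  expect_error(extract_analysis_strip(clip, 0.2, strip_height_deg = 0.6,
                                      center_x_deg = 0.45, center_y_deg = 0.3),
               "outside")
})

test_that("clip TIFF + sidecar round-trip preserves luminance and geometry", {
  geom <- mini_geom(n_frames = 4)
  clip <- render_deforming_bar(mini_bar(deform_sf = 2, amplitude_deg = 0.02),
                               geom)
  path <- withr::local_tempfile(fileext = ".tif")
  write_clip(clip, path)
  expect_true(file.exists(paste0(path, ".json")))
  back <- read_clip(path)
  expect_equal(back$frames, clip$frames, tolerance = 1e-6)
  expect_equal(back$geometry$pixels_per_degree, 100)
  expect_equal(back$geometry$n_frames, 4L)
  expect_equal(back$metadata$kind, "deforming_bar")
})
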