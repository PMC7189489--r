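#' Clip geometry
#'
#' Describes the raster and temporal sampling of a rendered stimulus clip.
#' The default resolution (200 px/deg) is deliberately much finer than a
#' typical display (~27 px/deg) so that sub-pixel contour deformations
#' (amplitude 0.04 deg) and the finest analysis wavelength (0.04 deg) are
#' resolved; the finest filter then spans 8 px.
#'
#' @param pixels_per_degree Spatial resolution in pixels per degree of visual
#'   angle. Must be positive.
#' @param frame_rate Temporal sampling rate in Hz.
#' @param width_deg,height_deg Field of view in degrees. The defaults are just
#'   large enough to contain the 0.6 x 5.0 deg bar plus the analysis strip;
#'   rendering the full display raster would add nothing to the model input.
#' @param n_frames Number of frames in the clip. Default 180 frames at 60 Hz
#'   (a 3 s presentation); the model itself only needs >= 6 frames.
#' @return A `clip_geometry` object (list).
#' @export
clip_geometry <- function(pixels_per_degree = 200, frame_rate = 60,
                          width_deg = 1.0, height_deg = 5.2,
                          n_frames = 180) {
  stopifnot(pixels_per_degree > 0, frame_rate > 0, n_frames >= 1,
            width_deg > 0, height_deg > 0)
  g <- list(
    pixels_per_degree = pixels_per_degree,
    frame_rate = frame_rate,
    width_deg = width_deg,
    height_deg = height_deg,
    n_frames = as.integer(n_frames),
    width_px = max(1L, as.integer(round(width_deg * pixels_per_degree))),
    height_px = max(1L, as.integer(round(height_deg * pixels_per_degree)))
  )
  class(g) <- "clip_geometry"
  g
}

#' Deforming-bar stimulus parameters
#'
#' A vertical bar whose contour is horizontally displaced by a vertically
#' drifting sinusoid: displacement(y, t) = amplitude * sin(2*pi*sf*y +
#' drift_sign * 2*pi*tf*t), with y in degrees measured downward from the
#' frame top and t in seconds. `drift_sign = +1` drifts the modulation
#' upward, `-1` downward.
#'
#' @param bar_width_deg,bar_height_deg Bar size in degrees.
#' @param deform_sf Spatial frequency of the contour modulation (cpd).
#' @param amplitude_deg Modulation amplitude (deg).
#' @param modulation_tf Modulation temporal frequency (Hz).
#' @param drift_sign +1 (upward drift) or -1 (downward drift).
#' @param bar_luminance,background_luminance Luminances in cd/m^2.
#' @param both_edges If `TRUE` (default) both bar edges carry the same
#'   displacement so the bar undulates at constant width; if `FALSE` only the
#'   right edge is displaced.
#' @return A `deforming_bar_spec` object.
#' @export
deforming_bar_spec <- function(deform_sf, amplitude_deg = 0.04,
                               modulation_tf = 1, drift_sign = -1,
                               bar_width_deg = 0.6, bar_height_deg = 5.0,
                               bar_luminance = 38, background_luminance = 76,
                               both_edges = TRUE) {
  stopifnot(deform_sf >= 0, amplitude_deg >= 0, modulation_tf >= 0,
            drift_sign %in% c(-1, 1),
            bar_luminance >= 0, background_luminance >= 0,
            bar_width_deg > 0, bar_height_deg > 0)
  s <- list(deform_sf = deform_sf, amplitude_deg = amplitude_deg,
            modulation_tf = modulation_tf, drift_sign = drift_sign,
            bar_width_deg = bar_width_deg, bar_height_deg = bar_height_deg,
            bar_luminance = bar_luminance,
            background_luminance = background_luminance,
            both_edges = isTRUE(both_edges))
  class(s) <- "deforming_bar_spec"
  s
}

#' Moire-illusion stimulus parameters
#'
#' A static vertical bar occluding a drifting grating tilted slightly from
#' vertical. Where the bar edge crosses the grating stripes, the
#' intersections sweep along the edge at speed tf / (sf * sin(orientation))
#' deg/s, producing a coarse moire modulation that drives the illusory
#' deformation.
#'
#' @param grating_orientation_deg Grating tilt from vertical (deg); positive
#'   tilt plus positive drift makes the moire intersections move downward.
#' @param grating_sf Grating spatial frequency (cpd).
#' @param grating_tf Drift temporal frequency (Hz).
#' @param grating_contrast Michelson contrast of the grating (0.75).
#' @param mean_luminance Mean grating luminance (cd/m^2); default midway
#'   between the 37 and 112 cd/m^2 extremes.
#' @param envelope_sd_deg SD of the horizontal Gaussian contrast envelope
#'   (deg), centered on the bar's vertical midline.
#' @param bar_luminance Bar luminance (cd/m^2).
#' @param bar_width_deg,bar_height_deg Bar size (deg).
#' @param waveform `"sine"` (default) or `"square"`.
#' @return A `moire_spec` object.
#' @export
moire_spec <- function(grating_orientation_deg, grating_sf = 12.9,
                       grating_tf = 1, grating_contrast = 0.75,
                       mean_luminance = (37 + 112) / 2,
                       envelope_sd_deg = 0.62,
                       bar_luminance = 37,
                       bar_width_deg = 0.6, bar_height_deg = 5.0,
                       waveform = c("sine", "square")) {
  waveform <- match.arg(waveform)
  stopifnot(grating_sf > 0, grating_contrast >= 0, grating_contrast <= 1,
            envelope_sd_deg > 0, mean_luminance >= 0, bar_luminance >= 0)
  s <- list(grating_orientation_deg = grating_orientation_deg,
            grating_sf = grating_sf, grating_tf = grating_tf,
            grating_contrast = grating_contrast,
            mean_luminance = mean_luminance,
            envelope_sd_deg = envelope_sd_deg,
            bar_luminance = bar_luminance,
            bar_width_deg = bar_width_deg, bar_height_deg = bar_height_deg,
            waveform = waveform)
  class(s) <- "moire_spec"
  s
}

new_stimulus_clip <- function(frames, geometry, metadata) {
  stopifnot(length(dim(frames)) == 3L)
  x <- list(frames = frames, geometry = geometry, metadata = metadata)
  class(x) <- "stimulus_clip"
  x
}

#' Construct a stimulus clip from a luminance array
#'
#' For user-supplied grayscale stacks (or synthetic probes): frames are a
#' `height x width x n_frames` array of luminances in cd/m^2, matching the
#' geometry's pixel counts.
#'
#' @param frames Numeric array, `height_px x width_px x n_frames`, values
#'   >= 0.
#' @param geometry A [clip_geometry()].
#' @param metadata Optional provenance list; `bar_right_edge_deg` /
#'   `bar_center_y_deg` entries let [extract_analysis_strip()] locate the
#'   default strip.
#' @return A `stimulus_clip`.
#' @export
stimulus_clip <- function(frames, geometry, metadata = list(kind = "user")) {
  stopifnot(inherits(geometry, "clip_geometry"),
            is.numeric(frames), length(dim(frames)) == 3L)
  d <- dim(frames)
  if (d[1] != geometry$height_px || d[2] != geometry$width_px ||
      d[3] != geometry$n_frames) {
    stop(sprintf("frame array %d x %d x %d does not match geometry %d x %d x %d",
                 d[1], d[2], d[3], geometry$height_px, geometry$width_px,
                 geometry$n_frames), call. = FALSE)
  }
  if (any(frames < 0)) stop("luminances must be >= 0", call. = FALSE)
  new_stimulus_clip(frames, geometry, metadata)
}

#' @export
print.stimulus_clip <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<stimulus_clip> %d x %d px, %d frames (%.2f x %.2f deg @ %g px/deg, %g Hz)\n",
              d[1], d[2], d[3], x$geometry$height_deg, x$geometry$width_deg,
              x$geometry$pixels_per_degree, x$geometry$frame_rate))
  cat(sprintf("  luminance range [%.2f, %.2f] cd/m^2; kind: %s\n",
              min(x$frames), max(x$frames),
              if (is.null(x$metadata$kind)) "?" else x$metadata$kind))
  invisible(x)
}

#' Closed-form contour displacement of the deforming bar
#'
#' @param spec A [deforming_bar_spec()].
#' @param y_deg Vertical positions (deg, from frame top, increasing downward).
#' @param t_sec Time (s).
#' @return Horizontal displacement in degrees.
#' @export
deforming_edge_offset <- function(spec, y_deg, t_sec) {
  spec$amplitude_deg *
    sin(2 * pi * spec$deform_sf * y_deg +
        spec$drift_sign * 2 * pi * spec$modulation_tf * t_sec)
}

# Horizontal anti-aliased coverage for a bar spanning [xl, xr] (px units,
# one pair per row), clipped to each pixel's [j-1, j] footprint.
.row_coverage <- function(xl_px, xr_px, width_px) {
  H <- length(xl_px)
  Jr <- matrix(seq_len(width_px), H, width_px, byrow = TRUE)      # right pixel edge
  cov <- pmin(Jr, xr_px) - pmax(Jr - 1, xl_px)
  cov[cov < 0] <- 0
  cov[cov > 1] <- 1
  cov
}

# Vertical coverage fraction of each pixel row for a bar spanning
# [y0, y1] degrees.
.vertical_coverage <- function(y0_deg, y1_deg, geom) {
  ppd <- geom$pixels_per_degree
  i <- seq_len(geom$height_px)
  cov <- pmin(i, y1_deg * ppd) - pmax(i - 1, y0_deg * ppd)
  cov[cov < 0] <- 0
  cov[cov > 1] <- 1
  cov
}

#' Render a deforming-bar clip
#'
#' Renders the bar with linear (coverage-weighted) anti-aliasing at the
#' luminance boundaries, so sub-pixel contour displacements survive
#' rasterization. The bar is centered in the field.
#'
#' @param spec A [deforming_bar_spec()].
#' @param geom A [clip_geometry()].
#' @return A `stimulus_clip` with frames as a height x width x n_frames array
#'   of luminances (cd/m^2).
#' @export
render_deforming_bar <- function(spec, geom = clip_geometry()) {
  stopifnot(inherits(spec, "deforming_bar_spec"), inherits(geom, "clip_geometry"))
  ppd <- geom$pixels_per_degree
  H <- geom$height_px; W <- geom$width_px
  xc <- geom$width_deg / 2
  x_left0 <- xc - spec$bar_width_deg / 2
  x_right0 <- xc + spec$bar_width_deg / 2
  if (x_left0 - spec$amplitude_deg < 0 ||
      x_right0 + spec$amplitude_deg > geom$width_deg) {
    stop("deforming bar exits the field of view: amplitude ",
         spec$amplitude_deg, " deg does not fit a ", geom$width_deg,
         " deg wide field", call. = FALSE)
  }
  y_top <- (geom$height_deg - spec$bar_height_deg) / 2
  y_bot <- y_top + spec$bar_height_deg
  vcov <- .vertical_coverage(y_top, y_bot, geom)
  y_deg <- (seq_len(H) - 0.5) / ppd
  frames <- array(spec$background_luminance, dim = c(H, W, geom$n_frames))
  dlum <- spec$bar_luminance - spec$background_luminance
  for (k in seq_len(geom$n_frames)) {
    t <- (k - 1) / geom$frame_rate
    d <- deforming_edge_offset(spec, y_deg, t)
    xl <- if (spec$both_edges) (x_left0 + d) * ppd else rep(x_left0 * ppd, H)
    xr <- (x_right0 + d) * ppd
    cov <- .row_coverage(xl, xr, W) * vcov
    frames[, , k] <- spec$background_luminance + dlum * cov
  }
  new_stimulus_clip(frames, geom, list(
    kind = "deforming_bar", spec = spec,
    bar_right_edge_deg = x_right0, bar_center_x_deg = xc,
    bar_center_y_deg = geom$height_deg / 2))
}

#' Render a moire-illusion clip (static bar over tilted drifting grating)
#'
#' The background is `mean_luminance * (1 + c(x) * sin(2*pi*sf*u -
#' 2*pi*tf*t))` where `u = x*cos(theta) + y*sin(theta)` is the coordinate
#' perpendicular to the stripes (theta = tilt from vertical, y downward) and
#' `c(x)` is the Michelson contrast attenuated by a horizontal Gaussian
#' envelope centered on the bar. The static bar occludes the grating.
#'
#' @param spec A [moire_spec()].
#' @param geom A [clip_geometry()].
#' @return A `stimulus_clip`.
#' @export
render_moire_stimulus <- function(spec, geom = clip_geometry()) {
  stopifnot(inherits(spec, "moire_spec"), inherits(geom, "clip_geometry"))
  ppd <- geom$pixels_per_degree
  px_per_cycle <- ppd / spec$grating_sf
  if (px_per_cycle < 4) {
    stop(sprintf(paste0("grating of %.1f cpd needs >= %.0f px/deg for 4 px ",
                        "per cycle; geometry has %.0f px/deg"),
                 spec$grating_sf, 4 * spec$grating_sf, ppd), call. = FALSE)
  }
  H <- geom$height_px; W <- geom$width_px
  xc <- geom$width_deg / 2
  x_deg <- (seq_len(W) - 0.5) / ppd
  y_deg <- (seq_len(H) - 0.5) / ppd
  th <- spec$grating_orientation_deg * pi / 180
  U <- outer(y_deg, x_deg, function(y, x) x * cos(th) + y * sin(th))
  cenv <- spec$grating_contrast *
    exp(-((x_deg - xc)^2) / (2 * spec$envelope_sd_deg^2))
  Cmat <- matrix(cenv, H, W, byrow = TRUE)
  # static bar occluder, anti-aliased
  x_left0 <- xc - spec$bar_width_deg / 2
  x_right0 <- xc + spec$bar_width_deg / 2
  y_top <- (geom$height_deg - spec$bar_height_deg) / 2
  vcov <- .vertical_coverage(y_top, y_top + spec$bar_height_deg, geom)
  bcov <- .row_coverage(rep(x_left0 * ppd, H), rep(x_right0 * ppd, H), W) * vcov
  frames <- array(0, dim = c(H, W, geom$n_frames))
  for (k in seq_len(geom$n_frames)) {
    t <- (k - 1) / geom$frame_rate
    carrier <- sin(2 * pi * spec$grating_sf * U - 2 * pi * spec$grating_tf * t)
    if (spec$waveform == "square") carrier <- sign(carrier)
    bg <- spec$mean_luminance * (1 + Cmat * carrier)
    frames[, , k] <- bg * (1 - bcov) + spec$bar_luminance * bcov
  }
  new_stimulus_clip(frames, geom, list(
    kind = "moire", spec = spec,
    bar_right_edge_deg = x_right0, bar_center_x_deg = xc,
    bar_center_y_deg = geom$height_deg / 2))
}

#' Extract the analysis strip near the bar's right edge
#'
#' The model analyzes a narrow vertical strip centered on the bar's right
#' edge (0.08 deg wide for the deforming bar; 0.16/0.08/0.04 deg for the
#' 6.4/12.9/25.8 cpd gratings), of constant height 4.97 deg.
#'
#' @param clip A `stimulus_clip`.
#' @param strip_width_deg Strip width (deg).
#' @param strip_height_deg Strip height (deg), default 4.97.
#' @param center_x_deg,center_y_deg Strip center; defaults to the bar's right
#'   edge and the bar's vertical center recorded in the clip metadata.
#' @return A `stimulus_clip` covering only the strip.
#' @export
extract_analysis_strip <- function(clip, strip_width_deg,
                                   strip_height_deg = 4.97,
                                   center_x_deg = NULL, center_y_deg = NULL) {
  stopifnot(inherits(clip, "stimulus_clip"), strip_width_deg > 0,
            strip_height_deg > 0)
  g <- clip$geometry
  ppd <- g$pixels_per_degree
  if (is.null(center_x_deg)) center_x_deg <- clip$metadata$bar_right_edge_deg
  if (is.null(center_y_deg)) center_y_deg <- clip$metadata$bar_center_y_deg
  if (is.null(center_x_deg) || is.null(center_y_deg)) {
    stop("clip metadata does not locate the bar; supply center_x_deg/center_y_deg",
         call. = FALSE)
  }
  nw <- max(1L, as.integer(round(strip_width_deg * ppd)))
  nh <- max(1L, as.integer(round(strip_height_deg * ppd)))
  c0 <- as.integer(round(center_x_deg * ppd - nw / 2))
  r0 <- as.integer(round(center_y_deg * ppd - nh / 2))
  if (c0 < 0 || r0 < 0 || c0 + nw > g$width_px || r0 + nh > g$height_px) {
    stop(sprintf("analysis strip [%d:%d, %d:%d] extends outside the %d x %d frame",
                 r0 + 1, r0 + nh, c0 + 1, c0 + nw, g$height_px, g$width_px),
         call. = FALSE)
  }
  sub <- clip$frames[(r0 + 1):(r0 + nh), (c0 + 1):(c0 + nw), , drop = FALSE]
  sg <- clip_geometry(pixels_per_degree = ppd, frame_rate = g$frame_rate,
                      width_deg = nw / ppd, height_deg = nh / ppd,
                      n_frames = g$n_frames)
  sg$width_px <- nw; sg$height_px <- nh
  md <- clip$metadata
  md$strip <- list(row_offset = r0, col_offset = c0,
                   width_deg = strip_width_deg, height_deg = strip_height_deg)
  new_stimulus_clip(sub, sg, md)
}
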