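#' Spatiotemporal filter-bank parameters
#'
#' A bank of Gabor-like spatiotemporal filters: a Gaussian-enveloped drifting
#' sinusoidal carrier whose spatial wavelength equals the (square) spatial
#' support, sampled over 6 frames. 24 channels tile motion direction in 15
#' deg steps; each channel is applied at two carrier phases (0 and pi) whose
#' half-wave rectified outputs are summed downstream, which together act as
#' a full-wave rectifier of the channel response.
#'
#' @param filter_size_deg Square spatial support and spatial wavelength (deg).
#' @param n_orientations Number of direction channels (default 24, 15 deg
#'   steps over the full circle).
#' @param phases Carrier phases (radians); default `c(0, pi)`. Use
#'   `c(0, pi/2)` for a quadrature pair.
#' @param temporal_extent_frames Temporal support (frames), default 6
#'   (~100 ms at 60 Hz).
#' @param temporal_freq Carrier temporal frequency (Hz), default 0.4.
#' @return A `filter_bank_spec` object.
#' @export
filter_bank_spec <- function(filter_size_deg, n_orientations = 24,
                             phases = c(0, pi), temporal_extent_frames = 6,
                             temporal_freq = 0.4) {
  stopifnot(filter_size_deg > 0, n_orientations >= 2,
            temporal_extent_frames >= 2, length(phases) >= 1)
  s <- list(filter_size_deg = filter_size_deg,
            n_orientations = as.integer(n_orientations),
            phases = phases,
            temporal_extent_frames = as.integer(temporal_extent_frames),
            temporal_freq = temporal_freq)
  class(s) <- "filter_bank_spec"
  s
}

#' Direction label to image-plane unit vector
#'
#' Directions are measured with 0 deg = leftward and 90 deg = downward
#' (image rows increase downward), so 180 deg = rightward and 270 deg =
#' upward.
#'
#' @param direction_deg Direction(s) in degrees.
#' @return A 2-column matrix of (vx, vy) unit vectors.
#' @export
direction_vector <- function(direction_deg) {
  a <- direction_deg * pi / 180
  cbind(vx = -cos(a), vy = sin(a))
}

#' Build the spatiotemporal filter bank
#'
#' Each kernel is `env(x, y) * cos(2*pi*fs*(x*vx + y*vy) - 2*pi*ft*t + phi)`
#' with `fs = 1/filter_size_deg`, `(vx, vy)` the unit vector of the channel's
#' preferred direction, a spatial Gaussian envelope of SD `filter_size/4`, a
#' flat temporal envelope, and the DC component subtracted so every kernel
#' sums exactly to zero. A drifting grating moving along `(vx, vy)` at the
#' carrier's speed is the kernel's best stimulus.
#'
#' @param spec A [filter_bank_spec()].
#' @param geom A [clip_geometry()] supplying px/deg and frame rate.
#' @return A `filter_bank` object containing the kernel array
#'   (px x px x frames x orientations x phases) and a flattened kernel matrix
#'   used for fast application.
#' @export
build_filter_bank <- function(spec, geom) {
  stopifnot(inherits(spec, "filter_bank_spec"), inherits(geom, "clip_geometry"))
  ppd <- geom$pixels_per_degree
  fpx <- as.integer(round(spec$filter_size_deg * ppd))
  if (fpx < 4) {
    stop(sprintf("filter support %.3f deg is only %d px at %.0f px/deg; need >= 4 px",
                 spec$filter_size_deg, fpx, ppd), call. = FALSE)
  }
  nt <- spec$temporal_extent_frames
  fs <- 1 / spec$filter_size_deg
  # patch coordinates centered on the support (deg / s)
  xy <- ((seq_len(fpx) - 0.5) - fpx / 2) / ppd
  tt <- ((seq_len(nt) - 0.5) - nt / 2) / geom$frame_rate
  sd_env <- spec$filter_size_deg / 4
  env2d <- outer(exp(-xy^2 / (2 * sd_env^2)), exp(-xy^2 / (2 * sd_env^2)))
  dirs <- (seq_len(spec$n_orientations) - 1) * 360 / spec$n_orientations
  V <- direction_vector(dirs)
  n_ph <- length(spec$phases)
  kernels <- array(0, dim = c(fpx, fpx, nt, spec$n_orientations, n_ph))
  for (o in seq_len(spec$n_orientations)) {
    U <- outer(xy * V[o, "vy"], xy * V[o, "vx"], "+")   # rows = y, cols = x
    for (p in seq_len(n_ph)) {
      for (k in seq_len(nt)) {
        arg <- 2 * pi * fs * U - 2 * pi * spec$temporal_freq * tt[k] +
          spec$phases[p]
        kernels[, , k, o, p] <- env2d * cos(arg)
      }
      kernels[, , , o, p] <- kernels[, , , o, p] - mean(kernels[, , , o, p])
    }
  }
  kmat <- matrix(kernels, nrow = fpx * fpx * nt,
                 ncol = spec$n_orientations * n_ph)
  b <- list(kernels = kernels, kmat = kmat, spec = spec, geom = geom,
            filter_px = fpx, direction_labels_deg = dirs)
  class(b) <- "filter_bank"
  b
}

#' Apply the filter bank to an analysis strip
#'
#' Filters tile the strip vertically; by default placements do not overlap
#' (stride = filter size). When `n_positions` asks for more placements than
#' fit without overlap, the stride shrinks below the filter size and the
#' tiling span is centered in the strip. Each placement is evaluated at
#' every fully-supported temporal offset; responses are kept per offset
#' because the subsequent rectification is nonlinear (averaging the linear
#' responses over a modulation period would cancel all direction
#' information).
#'
#' @param strip A `stimulus_clip` whose width equals the filter support.
#' @param bank A `filter_bank`.
#' @param n_positions Target number of filter placements, or `NULL` for the
#'   non-overlapping maximum `floor(height/filter_size)`.
#' @return A `v1_raw` object: array `positions x orientations x phases x
#'   offsets` plus placement geometry.
#' @export
apply_filters <- function(strip, bank, n_positions = NULL) {
  stopifnot(inherits(strip, "stimulus_clip"), inherits(bank, "filter_bank"))
  fpx <- bank$filter_px
  d <- dim(strip$frames)
  if (d[2] != fpx) {
    stop(sprintf("strip width (%d px) must equal the filter support (%d px)",
                 d[2], fpx), call. = FALSE)
  }
  nt <- bank$spec$temporal_extent_frames
  if (d[3] < nt) {
    stop(sprintf("clip has %d frames; the filters need at least %d", d[3], nt),
         call. = FALSE)
  }
  H <- d[1]
  if (is.null(n_positions)) {
    n_pos <- H %/% fpx
    stride <- fpx
  } else {
    n_pos <- as.integer(n_positions)
    stride <- if (n_pos > 1) (H - fpx) %/% (n_pos - 1L) else fpx
    if (n_pos < 1 || stride < 1) {
      stop(sprintf("cannot place %d filters of %d px in a %d px strip",
                   n_pos, fpx, H), call. = FALSE)
    }
    stride <- min(stride, fpx)
  }
  if (n_pos < 1) stop("strip too short for a single filter placement", call. = FALSE)
  span <- (n_pos - 1L) * stride + fpx
  y0 <- (H - span) %/% 2L
  n_off <- d[3] - nt + 1L
  # rows: position-major, then offset; cols: flattened patch
  P <- matrix(0, nrow = n_pos * n_off, ncol = fpx * fpx * nt)
  r <- 1L
  for (off in seq_len(n_off)) {
    for (i in seq_len(n_pos)) {
      rows <- (y0 + (i - 1L) * stride + 1L):(y0 + (i - 1L) * stride + fpx)
      P[r, ] <- strip$frames[rows, , off:(off + nt - 1L)]
      r <- r + 1L
    }
  }
  R <- P %*% bank$kmat
  raw <- array(R, dim = c(n_pos, n_off, bank$spec$n_orientations,
                          length(bank$spec$phases)))
  raw <- aperm(raw, c(1, 3, 4, 2))   # positions x orientations x phases x offsets
  ppd <- strip$geometry$pixels_per_degree
  centers <- (y0 + (seq_len(n_pos) - 1) * stride + fpx / 2) / ppd
  out <- list(values = raw,
              position_deg = centers,
              position_spacing_deg = stride / ppd,
              direction_labels_deg = bank$direction_labels_deg,
              phases = bank$spec$phases,
              stride_px = stride, filter_px = fpx)
  class(out) <- "v1_raw"
  out
}

#' Divisive-normalization constants
#'
#' @param max_response Maximum attainable response constant.
#' @param semi_saturation Semi-saturation constant added to the pooled
#'   rectified activity in the denominator; it guards the zero-input case and
#'   sets the contrast at which responses half-saturate.
#' @return A `normalization_constants` object.
#' @export
normalization_constants <- function(max_response = 1, semi_saturation = 0.1) {
  stopifnot(max_response > 0, semi_saturation > 0)
  s <- list(max_response = max_response, semi_saturation = semi_saturation)
  class(s) <- "normalization_constants"
  s
}

new_energy_map <- function(values, position_deg, spacing, labels, constants,
                           pooled = FALSE) {
  dimnames(values) <- list(NULL, paste0("dir", labels))
  m <- list(values = values, position_deg = position_deg,
            position_spacing_deg = spacing, direction_labels_deg = labels,
            constants = constants, pooled = pooled)
  class(m) <- "energy_map"
  m
}

#' Construct response maps from plain matrices
#'
#' For scoring externally computed (or synthetic) response fields with the
#' kernel machinery: wraps a `positions x directions` matrix with its grid
#' coordinates.
#'
#' @param values Numeric matrix, positions x direction channels, values >= 0.
#' @param positions_deg Position coordinates (deg), strictly increasing;
#'   default an even grid over 4.97 deg.
#' @param directions_deg Direction labels (deg); default 24 channels in 15
#'   deg steps.
#' @return An `energy_map` / `direction_map`.
#' @export
as_energy_map <- function(values,
                          positions_deg = seq(0, 4.97,
                                              length.out = nrow(values)),
                          directions_deg = (seq_len(ncol(values)) - 1) * 360 /
                            ncol(values)) {
  stopifnot(is.matrix(values), all(values >= 0),
            length(positions_deg) == nrow(values),
            length(directions_deg) == ncol(values))
  spacing <- if (nrow(values) > 1) positions_deg[2] - positions_deg[1] else 1
  new_energy_map(values, positions_deg, spacing, directions_deg,
                 normalization_constants())
}

#' @export
print.energy_map <- function(x, ...) {
  cat(sprintf("<energy_map%s> %d positions x %d channels, range [%.4g, %.4g]\n",
              if (isTRUE(x$pooled)) " (pooled)" else "",
              nrow(x$values), ncol(x$values), min(x$values), max(x$values)))
  invisible(x)
}

#' Half-wave rectification and divisive normalization
#'
#' Per position (and per temporal offset), each response is half-wave
#' rectified, scaled by the maximum attainable response constant, and divided
#' by the summed rectified activity across all orientation channels and
#' phases plus the semi-saturation constant:
#' `E(o) = sum_phi max_response * max(raw, 0) / (sum max(raw', 0) + sigma)`.
#' The two carrier phases are summed after rectification; energies are then
#' averaged across temporal offsets.
#'
#' @param raw A `v1_raw` object, or a bare array `positions x orientations x
#'   phases` (a single temporal offset) or `positions x orientations x
#'   phases x offsets`.
#' @param constants A [normalization_constants()].
#' @return An `energy_map` (positions x orientation channels), all values in
#'   `[0, max_response]`.
#' @export
rectify_and_normalize <- function(raw, constants = normalization_constants()) {
  info <- NULL
  if (inherits(raw, "v1_raw")) {
    info <- raw
    raw <- raw$values
  }
  if (length(dim(raw)) == 3L) dim(raw) <- c(dim(raw), 1L)
  stopifnot(length(dim(raw)) == 4L, all(is.finite(raw)))
  d <- dim(raw)
  A <- pmax(raw, 0)
  denom <- apply(A, c(1, 4), sum) + constants$semi_saturation  # pos x off
  E_off <- array(0, dim = c(d[1], d[2], d[4]))
  for (off in seq_len(d[4])) {
    num <- constants$max_response *
      apply(A[, , , off, drop = FALSE], c(1, 2), sum)
    E_off[, , off] <- num / denom[, off]
  }
  E <- apply(E_off, c(1, 2), mean)
  if (!is.null(info)) {
    new_energy_map(E, info$position_deg, info$position_spacing_deg,
                   info$direction_labels_deg, constants)
  } else {
    new_energy_map(E, seq_len(d[1]), 1,
                   (seq_len(d[2]) - 1) * 360 / d[2], constants)
  }
}
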