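#' Spatial-pooling parameters
#'
#' Energies are pooled over a small window of adjacent filter positions with
#' Gaussian weights centered on the pooling range (SD in position units),
#' stride 1, so N input positions yield N - window + 1 pooled positions
#' (64 -> 61, 32 -> 29, 128 -> 125).
#'
#' @param window Number of adjacent positions pooled (default 4).
#' @param sd Gaussian SD in position units (default 1.2).
#' @param stride Pooling stride (default 1).
#' @return A `pooling_spec` object.
#' @export
pooling_spec <- function(window = 4, sd = 1.2, stride = 1) {
  stopifnot(window >= 2, sd > 0, stride >= 1)
  s <- list(window = as.integer(window), sd = sd, stride = as.integer(stride))
  class(s) <- "pooling_spec"
  s
}

#' Gaussian pooling weights
#'
#' Weights are the Gaussian density at the window offsets (centered on the
#' pooling range: offsets -1.5, -0.5, 0.5, 1.5 for a window of 4),
#' renormalized to sum to 1.
#'
#' @param spec A [pooling_spec()].
#' @return Numeric vector of length `window`, summing to 1.
#' @export
pooling_weights <- function(spec = pooling_spec()) {
  off <- seq_len(spec$window) - (spec$window + 1) / 2
  w <- stats::dnorm(off, mean = 0, sd = spec$sd)
  w / sum(w)
}

#' Pool energies over adjacent positions
#'
#' @param energy An `energy_map`.
#' @param spec A [pooling_spec()].
#' @return A pooled `energy_map` with `N - window + 1` positions (stride 1).
#' @export
pool_responses <- function(energy, spec = pooling_spec()) {
  stopifnot(inherits(energy, "energy_map"))
  N <- nrow(energy$values)
  w <- spec$window
  if (N < w) {
    stop(sprintf("pooling needs >= %d positions, got %d", w, N), call. = FALSE)
  }
  g <- pooling_weights(spec)
  idx <- seq(1L, N - w + 1L, by = spec$stride)
  out <- matrix(0, length(idx), ncol(energy$values))
  for (j in seq_along(g)) {
    out <- out + g[j] * energy$values[idx + j - 1L, , drop = FALSE]
  }
  centers <- vapply(idx, function(i) {
    mean(energy$position_deg[i:(i + w - 1L)])
  }, numeric(1))
  new_energy_map(out, centers,
                 energy$position_spacing_deg * spec$stride,
                 energy$direction_labels_deg, energy$constants, pooled = TRUE)
}

new_direction_map <- function(values, position_deg, spacing, labels, constants) {
  dimnames(values) <- list(NULL, paste0("dir", labels))
  m <- list(values = values, position_deg = position_deg,
            position_spacing_deg = spacing, direction_labels_deg = labels,
            constants = constants)
  class(m) <- "direction_map"
  m
}

#' @rdname as_energy_map
#' @export
as_direction_map <- function(values,
                             positions_deg = seq(0, 4.97,
                                                 length.out = nrow(values)),
                             directions_deg = (seq_len(ncol(values)) - 1) *
                               360 / ncol(values)) {
  stopifnot(is.matrix(values), all(values >= 0),
            length(positions_deg) == nrow(values),
            length(directions_deg) == ncol(values))
  spacing <- if (nrow(values) > 1) positions_deg[2] - positions_deg[1] else 1
  new_direction_map(values, positions_deg, spacing, directions_deg,
                    normalization_constants())
}

#' @export
print.direction_map <- function(x, ...) {
  cat(sprintf("<direction_map> %d positions x %d directions, range [%.4g, %.4g]\n",
              nrow(x$values), ncol(x$values), min(x$values), max(x$values)))
  invisible(x)
}

#' Opponent cosine direction weighting
#'
#' The pre-rectification response of a unit preferring direction `alpha` is
#' `L(alpha) = sum_o cos(dir_o - alpha) * E(o)`: the cosine's negative lobe
#' subtracts energy from opposing directions (motion opponency). `L` is
#' antisymmetric under a 180 deg shift of `alpha`.
#'
#' @param pooled A (pooled) `energy_map`.
#' @param directions_deg Preferred directions of the output units; default
#'   the input's 24 channel directions.
#' @return Matrix positions x directions of signed opponent responses.
#' @export
opponent_sum <- function(pooled, directions_deg = NULL) {
  stopifnot(inherits(pooled, "energy_map"))
  if (is.null(directions_deg)) directions_deg <- pooled$direction_labels_deg
  W <- cos(outer(pooled$direction_labels_deg, directions_deg, "-") * pi / 180)
  pooled$values %*% W
}

#' Direction-selective responses
#'
#' Opponent cosine weighting over the 24 energy channels, half-wave
#' rectification, and divisive normalization across the 24 preferred
#' directions (same constants contract as the V1 stage).
#'
#' @param pooled A (pooled) `energy_map`.
#' @param constants A [normalization_constants()]; defaults to the constants
#'   stored in the map.
#' @param rectify If `FALSE`, return the signed opponent responses without
#'   rectification or normalization (for inspecting opponency).
#' @return A `direction_map` (positions x 24 directions, values >= 0), or a
#'   signed matrix when `rectify = FALSE`.
#' @export
direction_tuning <- function(pooled, constants = NULL, rectify = TRUE) {
  stopifnot(inherits(pooled, "energy_map"))
  if (is.null(constants)) constants <- pooled$constants
  if (is.null(constants)) constants <- normalization_constants()
  L <- opponent_sum(pooled)
  if (!rectify) return(L)
  A <- pmax(L, 0)
  R <- constants$max_response * A /
    (rowSums(A) + constants$semi_saturation)
  new_direction_map(R, pooled$position_deg, pooled$position_spacing_deg,
                    pooled$direction_labels_deg, constants)
}

#' Run the full model on a stimulus clip
#'
#' End-to-end composition: extract the analysis strip, build and apply the
#' spatiotemporal filter bank, rectify and normalize (motion energy), pool
#' spatially, and compute direction-selective responses. Deterministic:
#' identical inputs and parameters give bit-identical outputs.
#'
#' @param clip A `stimulus_clip`.
#' @param params A [model_params()] list.
#' @return A list with elements `energy` (the V1-stage `energy_map`),
#'   `pooled`, and `direction` (the MT-stage `direction_map`).
#' @export
compute_model_maps <- function(clip, params = model_params()) {
  strip <- extract_analysis_strip(clip, params$strip_width_deg,
                                  params$strip_height_deg)
  if (identical(params$offset_policy, "single")) {
    nt <- params$temporal_extent_frames
    i0 <- params$offset_index
    if (i0 < 1 || i0 + nt - 1 > dim(strip$frames)[3]) {
      stop(sprintf("offset_index %d with %d-frame filters exceeds the %d-frame clip",
                   i0, nt, dim(strip$frames)[3]), call. = FALSE)
    }
    strip$frames <- strip$frames[, , i0:(i0 + nt - 1), drop = FALSE]
    strip$geometry$n_frames <- nt
  }
  fspec <- filter_bank_spec(filter_size_deg = params$filter_size_deg,
                            n_orientations = params$n_orientations,
                            phases = params$phases,
                            temporal_extent_frames = params$temporal_extent_frames,
                            temporal_freq = params$temporal_freq)
  bank <- build_filter_bank(fspec, strip$geometry)
  raw <- apply_filters(strip, bank, n_positions = params$n_positions)
  energy <- rectify_and_normalize(raw, params$constants)
  pooled <- pool_responses(energy, params$pooling)
  direction <- direction_tuning(pooled, params$constants)
  list(energy = energy, pooled = pooled, direction = direction)
}

#' Convenience wrapper returning only the MT-stage map
#'
#' @inheritParams compute_model_maps
#' @return A `direction_map`.
#' @export
compute_direction_map <- function(clip, params = model_params()) {
  compute_model_maps(clip, params)$direction
}

#' Model-stage parameters
#'
#' Bundles every knob of the V1 and MT stages. The filter spatial support
#' equals the analysis-strip width, and `n_positions` fixes the number of
#' vertical filter placements (64 for the 0.08 deg strip; 32/64/128 for the
#' 0.16/0.08/0.04 deg strips).
#'
#' @param strip_width_deg Analysis strip width (deg); also the filter size
#'   unless `filter_size_deg` overrides it.
#' @param n_positions Number of filter placements.
#' @param strip_height_deg Strip height (deg).
#' @param filter_size_deg Filter support (deg); defaults to the strip width.
#' @param n_orientations,phases,temporal_extent_frames,temporal_freq See
#'   [filter_bank_spec()].
#' @param constants A [normalization_constants()].
#' @param pooling A [pooling_spec()].
#' @param offset_policy How responses are aggregated over time. `"single"`
#'   (default) evaluates one 6-frame window starting at `offset_index`: the
#'   resulting map is a motion snapshot whose arbitrary spatial phase the
#'   kernel's 32-phase search absorbs. `"average"` averages the rectified,
#'   normalized energies over every fully-supported window; note that over a
#'   full period of an oscillating deformation this cancels the
#'   leftward/rightward alternation exactly (each edge segment spends equal
#'   time moving each way), leaving only the net drift component.
#' @param offset_index Starting frame of the analysis window under
#'   `"single"`.
#' @return A `model_params` list.
#' @export
model_params <- function(strip_width_deg = 0.08, n_positions = 64,
                         strip_height_deg = 4.97, filter_size_deg = NULL,
                         n_orientations = 24, phases = c(0, pi),
                         temporal_extent_frames = 6, temporal_freq = 0.4,
                         constants = normalization_constants(),
                         pooling = pooling_spec(),
                         offset_policy = c("single", "average"),
                         offset_index = 1L) {
  if (is.null(filter_size_deg)) filter_size_deg <- strip_width_deg
  offset_policy <- match.arg(offset_policy)
  p <- list(strip_width_deg = strip_width_deg,
            strip_height_deg = strip_height_deg,
            filter_size_deg = filter_size_deg,
            n_positions = n_positions,
            n_orientations = n_orientations, phases = phases,
            temporal_extent_frames = temporal_extent_frames,
            temporal_freq = temporal_freq,
            constants = constants, pooling = pooling,
            offset_policy = offset_policy,
            offset_index = as.integer(offset_index))
  class(p) <- "model_params"
  p
}
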