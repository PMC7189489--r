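#' Write a stimulus clip as multi-page TIFF with JSON sidecar
#'
#' Frames are stored as 32-bit float pages scaled to `[0, 1]`; the luminance
#' scale (cd/m^2 per unit) lives in the sidecar together with the clip
#' geometry and provenance metadata, so the round trip is lossless up to
#' float precision.
#'
#' @param clip A `stimulus_clip`.
#' @param path Output TIFF path; the sidecar is written at `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_clip <- function(clip, path) {
  stopifnot(inherits(clip, "stimulus_clip"))
  scale <- max(max(clip$frames), 1e-12)
  pages <- lapply(seq_len(dim(clip$frames)[3]),
                  function(k) clip$frames[, , k] / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, compression = "none",
                  reduce = FALSE)
  side <- list(
    luminance_scale = scale,
    geometry = unclass(clip$geometry),
    metadata = .serializable_metadata(clip$metadata)
  )
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

.serializable_metadata <- function(md) {
  strip <- function(x) {
    if (is.list(x)) lapply(unclass(x), strip) else x
  }
  strip(md)
}

#' Read a stimulus clip written by [write_clip()]
#'
#' @param path TIFF path with `<path>.json` sidecar alongside.
#' @return A `stimulus_clip`.
#' @export
read_clip <- function(path) {
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  g <- side$geometry
  geom <- clip_geometry(pixels_per_degree = g$pixels_per_degree,
                        frame_rate = g$frame_rate,
                        width_deg = g$width_deg, height_deg = g$height_deg,
                        n_frames = g$n_frames)
  geom$width_px <- as.integer(g$width_px)
  geom$height_px <- as.integer(g$height_px)
  frames <- array(0, c(geom$height_px, geom$width_px, geom$n_frames))
  for (k in seq_along(pages)) frames[, , k] <- pages[[k]] * side$luminance_scale
  new_stimulus_clip(frames, geom, side$metadata)
}

.map_to_long <- function(map) {
  v <- map$values
  data.frame(
    position_index = rep(seq_len(nrow(v)), times = ncol(v)),
    position_deg = rep(map$position_deg, times = ncol(v)),
    direction_deg = rep(map$direction_labels_deg, each = nrow(v)),
    response = as.vector(v)
  )
}

#' Write an energy or direction map as long-format CSV
#'
#' Columns: `position_index`, `position_deg`, `direction_deg`, `response`.
#'
#' @param map An `energy_map` or `direction_map`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_map_csv <- function(map, path) {
  stopifnot(inherits(map, c("energy_map", "direction_map")))
  utils::write.csv(.map_to_long(map), path, row.names = FALSE)
  invisible(path)
}

#' Read a long-format map CSV back into a map object
#'
#' @param path CSV written by [write_map_csv()].
#' @param type `"energy"` or `"direction"`.
#' @return An `energy_map` or `direction_map`.
#' @export
read_map_csv <- function(path, type = c("direction", "energy")) {
  type <- match.arg(type)
  d <- utils::read.csv(path)
  pos <- sort(unique(d$position_index))
  dirs <- sort(unique(d$direction_deg))
  v <- matrix(0, length(pos), length(dirs))
  v[cbind(match(d$position_index, pos), match(d$direction_deg, dirs))] <-
    d$response
  pdeg <- d$position_deg[match(pos, d$position_index)]
  spacing <- if (length(pdeg) > 1) stats::median(diff(pdeg)) else 1
  if (type == "direction") {
    new_direction_map(v, pdeg, spacing, dirs, NULL)
  } else {
    new_energy_map(v, pdeg, spacing, dirs, NULL)
  }
}

#' Write a psychophysical dataset as CSV
#'
#' Columns: `condition`, `ncc`, `n_trials`, `n_reports`, `proportion`.
#'
#' @param dataset A [psycho_dataset()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_dataset_csv <- function(dataset, path) {
  utils::write.csv(as.data.frame(dataset), path, row.names = FALSE)
  invisible(path)
}

#' Read a psychophysical dataset CSV
#'
#' @param path CSV with columns `condition`, `ncc`, `n_trials`, `n_reports`.
#' @return A [psycho_dataset()].
#' @export
read_dataset_csv <- function(path) {
  d <- utils::read.csv(path)
  psycho_dataset(d$condition, d$ncc, d$n_trials, d$n_reports)
}

#' Density plot of a response map
#'
#' Draws the positions x directions response matrix as an image (positions
#' down the vertical axis, as along the bar), for visual comparison of the
#' alternating leftward/rightward structure.
#'
#' @param map An `energy_map` or `direction_map`.
#' @param main Plot title.
#' @param ... Passed to [graphics::image()].
#' @return The map, invisibly.
#' @export
plot_map <- function(map, main = NULL, ...) {
  v <- map$values
  if (is.null(main)) main <- class(map)[1]
  graphics::image(x = map$direction_labels_deg, y = map$position_deg,
                  z = t(v)[, rev(seq_len(nrow(v))), drop = FALSE],
                  col = grDevices::hcl.colors(64, "viridis"),
                  xlab = "preferred direction (deg)",
                  ylab = "position along strip (deg)", main = main, ...)
  invisible(map)
}
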