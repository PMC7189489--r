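#' Higher-order kernel parameters
#'
#' The hypothesized deformation detector is a template over space and motion
#' direction: sinusoidal along position, cosine-tuned in direction around a
#' preferred direction `alpha` (0 deg = leftward).
#'
#' @param f Kernel spatial frequency (cpd).
#' @param phi Kernel phase (radians) in `[0, 2*pi)`.
#' @param alpha Preferred direction (deg), default 0 (leftward).
#' @return A `kernel_spec` object.
#' @export
kernel_spec <- function(f, phi = 0, alpha = 0) {
  stopifnot(f >= 0, is.finite(phi))
  s <- list(f = f, phi = phi %% (2 * pi), alpha = alpha)
  class(s) <- "kernel_spec"
  s
}

#' Build the space-by-direction kernel
#'
#' `K(x, theta) = sin(2*pi*f*x + phi) * cos(theta - alpha)` with `x` in
#' degrees (position along the strip, top to bottom) and `theta`, `alpha` in
#' degrees of motion direction. When the directions sample the full circle
#' uniformly the kernel is exactly zero-mean along the direction axis at
#' every position.
#'
#' @param spec A [kernel_spec()].
#' @param positions_deg Strictly increasing position coordinates (deg).
#' @param directions_deg Direction labels (deg), uniform on the circle.
#' @return A `deform_kernel` object with a `values` matrix positions x
#'   directions.
#' @export
build_kernel <- function(spec, positions_deg, directions_deg) {
  stopifnot(inherits(spec, "kernel_spec"),
            length(positions_deg) >= 1, length(directions_deg) >= 1,
            !is.unsorted(positions_deg, strictly = TRUE))
  S <- sin(2 * pi * spec$f * positions_deg + spec$phi)
  D <- cos((directions_deg - spec$alpha) * pi / 180)
  values <- outer(S, D)
  dimnames(values) <- list(NULL, paste0("dir", directions_deg))
  k <- list(values = values, spec = spec, position_deg = positions_deg,
            direction_labels_deg = directions_deg)
  class(k) <- "deform_kernel"
  k
}

.as_field_matrix <- function(x) {
  if (inherits(x, c("deform_kernel", "energy_map", "direction_map"))) {
    x$values
  } else if (is.matrix(x)) {
    x
  } else {
    stop("expected a kernel, energy_map, direction_map or matrix", call. = FALSE)
  }
}

#' Zero-mean normalized cross-correlation
#'
#' `ZNCC(K, I) = sum((K - mean(K)) * (I - mean(I))) /
#' sqrt(sum((K - mean(K))^2) * sum((I - mean(I))^2))`, computed jointly over
#' the whole grid; bounded in `[-1, 1]`, symmetric in its arguments, and
#' invariant to positive affine rescaling of either field. Returns 0 when
#' either field is constant (zero variance).
#'
#' @param kernel A `deform_kernel` (or matrix).
#' @param map An `energy_map`, `direction_map`, or matrix of the same shape.
#' @return A scalar in `[-1, 1]`.
#' @export
zncc <- function(kernel, map) {
  K <- .as_field_matrix(kernel)
  I <- .as_field_matrix(map)
  if (!identical(dim(K), dim(I))) {
    stop(sprintf("shape mismatch: kernel %d x %d vs map %d x %d",
                 nrow(K), ncol(K), nrow(I), ncol(I)), call. = FALSE)
  }
  Kc <- K - mean(K)
  Ic <- I - mean(I)
  denom <- sqrt(sum(Kc^2) * sum(Ic^2))
  if (denom == 0) return(0)
  sum(Kc * Ic) / denom
}

#' Kernel phase grid
#'
#' 32 phases in steps of 0.0625*pi, tiling `[0, 2*pi)` exactly.
#'
#' @param n_phases Number of phase steps (default 32).
#' @return Numeric vector of phases (radians).
#' @export
kernel_phase_grid <- function(n_phases = 32) {
  (seq_len(n_phases) - 1) * 2 * pi / n_phases
}

#' Best kernel match over the phase grid
#'
#' Evaluates the ZNCC between the map and the kernel at every phase on the
#' 32-step grid and returns the maximum; that maximum is the kernel's score
#' for the map.
#'
#' @param f Kernel spatial frequency (cpd).
#' @param map An `energy_map` or `direction_map` (or matrix with attributes
#'   supplied via `positions_deg`/`directions_deg`).
#' @param alpha Preferred direction (deg), default 0.
#' @param n_phases Phase-grid size (default 32).
#' @param positions_deg,directions_deg Grid coordinates; default those stored
#'   in the map.
#' @return A list with `ncc` (the maximum), `phase` (argmax, radians), and
#'   the full `profile` of per-phase ZNCC values.
#' @export
max_ncc_over_phase <- function(f, map, alpha = 0, n_phases = 32,
                               positions_deg = NULL, directions_deg = NULL) {
  if (is.null(positions_deg)) positions_deg <- map$position_deg
  if (is.null(directions_deg)) directions_deg <- map$direction_labels_deg
  stopifnot(!is.null(positions_deg), !is.null(directions_deg))
  phases <- kernel_phase_grid(n_phases)
  vals <- vapply(phases, function(phi) {
    zncc(build_kernel(kernel_spec(f, phi, alpha), positions_deg,
                      directions_deg), map)
  }, numeric(1))
  i <- which.max(vals)
  list(ncc = vals[i], phase = phases[i], profile = vals)
}

#' NCC profile across kernel spatial frequencies
#'
#' @param map An `energy_map` or `direction_map`.
#' @param fs Kernel spatial frequencies (cpd); default the seven modulation
#'   frequencies 0.1--6.4 cpd in octave steps.
#' @param alpha Preferred direction (deg).
#' @param n_phases Phase-grid size.
#' @return A data frame with columns `f`, `best_ncc`, `argmax_phase`.
#' @export
ncc_profile <- function(map, fs = c(0.1, 0.2, 0.4, 0.8, 1.6, 3.2, 6.4),
                        alpha = 0, n_phases = 32) {
  stopifnot(length(fs) >= 1)
  rows <- lapply(fs, function(f) {
    m <- max_ncc_over_phase(f, map, alpha = alpha, n_phases = n_phases)
    data.frame(f = f, best_ncc = m$ncc, argmax_phase = m$phase)
  })
  do.call(rbind, rows)
}
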