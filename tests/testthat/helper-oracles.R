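# Independent oracles and small fixture builders. The brute-force routines
# deliberately use explicit loops and share no code with the package paths
# they check.

zncc_bruteforce <- function(K, I) {
  n <- length(K)
  mk <- 0; mi <- 0
  for (v in K) mk <- mk + v / n
  for (v in I) mi <- mi + v / n
  num <- 0; dk <- 0; di <- 0
  for (j in seq_len(n)) {
    num <- num + (K[[j]] - mk) * (I[[j]] - mi)
    dk <- dk + (K[[j]] - mk)^2
    di <- di + (I[[j]] - mi)^2
  }
  if (dk == 0 || di == 0) return(0)
  num / sqrt(dk * di)
}

# full-field sinusoid drifting along `dir_deg`, matched by default to the
# filter bank's carrier (wavelength = 0.08 deg, 0.4 Hz)
make_drift_clip <- function(dir_deg, geom, fs = 1 / 0.08, ft = 0.4,
                            mean_lum = 50, amp = 40) {
  v <- direction_vector(dir_deg)
  x <- (seq_len(geom$width_px) - 0.5) / geom$pixels_per_degree
  y <- (seq_len(geom$height_px) - 0.5) / geom$pixels_per_degree
  U <- outer(y * v[1, "vy"], x * v[1, "vx"], "+")
  fr <- array(0, c(geom$height_px, geom$width_px, geom$n_frames))
  for (k in seq_len(geom$n_frames)) {
    t <- (k - 1) / geom$frame_rate
    fr[, , k] <- mean_lum + amp * cos(2 * pi * fs * U - 2 * pi * ft * t)
  }
  stimulus_clip(fr, geom, list(kind = "drift_probe", dir_deg = dir_deg))
}

uniform_clip <- function(geom, lum = 50) {
  stimulus_clip(array(lum, c(geom$height_px, geom$width_px, geom$n_frames)),
                geom, list(kind = "uniform"))
}

# interpolated zero-crossing locations of a profile along position
crossing_locations <- function(prof, pos) {
  s <- sign(prof)
  idx <- which(diff(s) != 0 & s[-length(s)] != 0 & s[-1] != 0)
  pos[idx] - prof[idx] * (pos[idx + 1] - pos[idx]) / (prof[idx + 1] - prof[idx])
}

# left-minus-right opponent profile of a direction map
lr_profile <- function(dmap) {
  dmap$values[, dmap$direction_labels_deg == 0] -
    dmap$values[, dmap$direction_labels_deg == 180]
}

expect_all_close <- function(x, y, tol = 1e-12) {
  expect_lt(max(abs(x - y)), tol)
}

# family of condition maps whose structure is a kernel at f0 mixed with
# seeded noise at condition-dependent weights; used by the sweep and
# synthetic-observer tests
make_kernel_maps <- function(f0, n_cond = 7, seed = 42, noise_sd = 0.3) {
  pos <- seq(0, 4.97, length.out = 61)
  w <- seq(0.15, 1, length.out = n_cond)
  withr::with_seed(seed, lapply(seq_len(n_cond), function(c) {
    K <- build_kernel(kernel_spec(f0, phi = 0.4 * c), pos, (0:23) * 15)$values
    N <- matrix(stats::rnorm(61 * 24, sd = noise_sd), 61, 24)
    as_direction_map(pmax(w[c] * K + (1 - w[c]) * N + 1, 0), pos)
  }))
}
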