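dirs24 <- (0:23) * 15
pos61 <- seq(0, 4.97, length.out = 61)

test_that("kernel equals its closed form pointwise", {
  k <- build_kernel(kernel_spec(0.1, phi = 0.7, alpha = 0), pos61, dirs24)
  for (i in c(1, 17, 61)) for (j in c(1, 5, 13, 24)) {
    expect_equal(unname(k$values[i, j]),
                 sin(2 * pi * 0.1 * pos61[i] + 0.7) *
                   cos((dirs24[j] - 0) * pi / 180),
                 tolerance = 1e-14)
  }
  # direction at alpha reproduces the spatial factor alone
  expect_equal(unname(k$values[, dirs24 == 0]),
               sin(2 * pi * 0.1 * pos61 + 0.7), tolerance = 1e-14)
  # phase + pi negates
  k2 <- build_kernel(kernel_spec(0.1, phi = 0.7 + pi), pos61, dirs24)
  expect_all_close(k2$values, -k$values)
  # zero mean over the direction axis at every position
  expect_lt(max(abs(rowMeans(k$values))), 1e-12)
})

test_that("zncc: hand value, self/anti match, symmetry, affine invariance", {
  K <- matrix(c(1, -1, 2, 0), 2, 2)
  I <- matrix(c(0, 1, 1, 2), 2, 2)
  # hand arithmetic: centered K = {.5,-1.5,1.5,-.5}, centered I = {-1,0,0,1}
  # numerator -1, denominators 5 and 2
  expect_equal(zncc(K, I), -1 / sqrt(10), tolerance = 1e-14)

  k <- build_kernel(kernel_spec(0.4, 0.3), pos61, dirs24)
  expect_equal(zncc(k, k$values), 1, tolerance = 1e-12)
  expect_equal(zncc(k, -k$values), -1, tolerance = 1e-12)
  set.seed(21)
  M <- matrix(runif(61 * 24), 61, 24)
  expect_equal(zncc(k, M), zncc(M, k$values), tolerance = 1e-14)
  expect_equal(zncc(k, 3.7 * M - 2), zncc(k, M), tolerance = 1e-12)
  expect_identical(zncc(k, matrix(5, 61, 24)), 0)
  expect_error(zncc(k, M[1:10, ]), "shape mismatch")
})

test_that("zncc agrees with the brute-force oracle on random grids", {
  set.seed(99)
  for (r in 1:20) {
    K <- matrix(rnorm(61 * 24), 61, 24)
    I <- matrix(rnorm(61 * 24), 61, 24)
    expect_equal(zncc(K, I), zncc_bruteforce(K, I), tolerance = 1e-12)
  }
})

test_that("phase grid tiles the circle and self-match is exact on-grid", {
  g <- kernel_phase_grid()
  expect_length(g, 32)
  expect_all_close(diff(g), 0.0625 * pi)
  expect_equal(g[32] + 0.0625 * pi, 2 * pi, tolerance = 1e-14)

  for (r in 1:5) {
    set.seed(r)
    f <- stats::runif(1, 0.1, 1.5)
    phi_star <- sample(g, 1)
    m <- build_kernel(kernel_spec(f, phi_star), pos61, dirs24)$values
    res <- max_ncc_over_phase(f, m, positions_deg = pos61,
                              directions_deg = dirs24)
    expect_equal(res$ncc, 1, tolerance = 1e-12)
    expect_equal(res$phase, phi_star, tolerance = 1e-12)
  }
})

test_that("circular position shifts move the argmax phase, not the best NCC", {
  n <- 50; s <- 0.1; f <- 0.4; phi_star <- 0.9
  pos <- (0:(n - 1)) * s                 # f * span = 2 full cycles
  m0 <- build_kernel(kernel_spec(f, phi_star), pos, dirs24)$values
  for (k in c(3, 10, 17)) {
    m <- m0[c((k + 1):n, 1:k), ]
    res <- max_ncc_over_phase(f, m, positions_deg = pos,
                              directions_deg = dirs24)
    expect_gt(res$ncc, 0.995)
    predicted <- (phi_star + 2 * pi * f * k * s) %% (2 * pi)
    dphi <- abs((res$phase - predicted + pi) %% (2 * pi) - pi)
    expect_lt(dphi, 0.0625 * pi)
  }
})

test_that("max over the phase grid equals exhaustive recomputation", {
  set.seed(31)
  m <- matrix(runif(61 * 24), 61, 24)
  res <- max_ncc_over_phase(0.8, m, positions_deg = pos61,
                            directions_deg = dirs24)
  ex <- vapply(kernel_phase_grid(), function(phi) {
    zncc_bruteforce(build_kernel(kernel_spec(0.8, phi), pos61, dirs24)$values,
                    m)
  }, numeric(1))
  expect_equal(res$ncc, max(ex), tolerance = 1e-12)
  expect_equal(res$phase, kernel_phase_grid()[which.max(ex)])
  expect_equal(res$profile, ex, tolerance = 1e-12)
})

test_that("ncc profile identifies the generating frequency", {
  map <- as_direction_map(1 + build_kernel(kernel_spec(0.4, 5 * 0.0625 * pi),
                                           pos61, dirs24)$values)
  prof <- ncc_profile(map)
  expect_identical(prof$f, c(0.1, 0.2, 0.4, 0.8, 1.6, 3.2, 6.4))
  expect_identical(prof$f[which.max(prof$best_ncc)], 0.4)
  expect_gt(max(prof$best_ncc), 0.999)
  # frequency mismatch with many cycles stays well below self-match
  expect_lt(prof$best_ncc[prof$f == 6.4], 0.5)
  # profile rows equal independent per-frequency calls
  one <- max_ncc_over_phase(0.8, map)
  expect_identical(prof$best_ncc[prof$f == 0.8], one$ncc)
  expect_identical(prof$argmax_phase[prof$f == 0.8], one$phase)
})
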