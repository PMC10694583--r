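test_that("phasor transform matches the monoexponential closed form", {
  # oracle: g = 1/(1+(wt)^2), s = wt/(1+(wt)^2) for periodic excitation
  taus <- c(0.0199, 0.1, 0.37, 1, 4, 9, 50, 198.9)  # omega*tau ~ 0.01..100
  for (tau in taus) {
    d <- wrapped_decay(tau, n_bins = 2048L)
    p <- phasor_of_decay(d$counts, d$centers, pr80)
    wt <- pr80$omega * tau * 1e-9
    expect_lt(abs(p$g - 1 / (1 + wt^2)), 1e-4)
    expect_lt(abs(p$s - wt / (1 + wt^2)), 1e-4)
  }
})

test_that("limiting decays map to the semicircle endpoints", {
  n <- 1024L
  tc <- seq(0, pr80$period, length.out = n + 1L)[seq_len(n)]
  # all photons in the bin at t = 0: zero-lifetime corner (1, 0)
  p0 <- phasor_of_decay(c(1000, rep(0, n - 1L)), tc, pr80)
  expect_phasor_equal(p0, 1, 0, tol = 1e-12)
  # constant emission over the full period: cos/sin average out to (0, 0)
  pc <- phasor_of_decay(rep(7, n), tc, pr80)
  expect_equal(abs(pc$g), 0, tolerance = 1e-12)
  expect_equal(abs(pc$s), 0, tolerance = 1e-12)
})

test_that("empty decays are rejected", {
  tc <- (1:64 - 0.5) * pr80$period / 64
  expect_error(phasor_of_decay(rep(0, 64), tc, pr80), "no photons")
})

test_that("noiseless mixtures stay on or inside the universal semicircle", {
  set.seed(42)
  for (i in 1:50) {
    k <- sample(1:3, 1)
    taus <- runif(k, 0.05, 12)
    amps <- runif(k, 0.1, 2)
    p <- phasor_mixture(taus, amps, pr80)$point
    expect_lte(semicircle_distance(p$g, p$s), 0.5 + 1e-9)
  }
  # pure species sit exactly on the circle
  mono <- phasor_mono(c(0.1, 1, 4, 9), pr80)
  expect_equal(semicircle_distance(mono$g, mono$s), rep(0.5, 4),
               tolerance = 1e-12)
})

test_that("phasor of a summed decay is the intensity-weighted combination", {
  d1 <- wrapped_decay(1); d2 <- wrapped_decay(4)
  a <- 0.3; b <- 1.7
  p1 <- phasor_of_decay(d1$counts, d1$centers, pr80)
  p2 <- phasor_of_decay(d2$counts, d2$centers, pr80)
  psum <- phasor_of_decay(a * d1$counts + b * d2$counts, d1$centers, pr80)
  w1 <- a * sum(d1$counts) / (a * sum(d1$counts) + b * sum(d2$counts))
  expect_equal(psum$g, w1 * p1$g + (1 - w1) * p2$g, tolerance = 1e-12)
  expect_equal(psum$s, w1 * p1$s + (1 - w1) * p2$s, tolerance = 1e-12)
})

test_that("phasor_field applies the transform per pixel", {
  sim <- make_decay_stack(4, shape = c(8, 8), n_bins = 256L, params = pr80)
  fld <- phasor_field(sim$stack)
  # shift invariance: uniform image gives constant rasters
  expect_equal(max(fld$g) - min(fld$g), 0, tolerance = 1e-14)
  expect_true(all(fld$valid))
  # checkerboard of two lifetimes gives exactly two phasor values
  sim2 <- make_decay_stack(c(1, 4), shape = c(8, 8), n_bins = 256L,
                           layout = "checkerboard", params = pr80)
  fld2 <- phasor_field(sim2$stack)
  expect_equal(length(unique(round(as.numeric(fld2$g), 10))), 2L)
  # an all-zero pixel is invalid, others untouched
  st <- sim$stack
  st$counts[, 3, 5] <- 0
  fld3 <- phasor_field(st)
  expect_false(fld3$valid[3, 5])
  expect_true(is.na(fld3$g[3, 5]))
  expect_equal(fld3$g[1, 1], fld$g[1, 1])
})

test_that("calibration corrections are fitted and inverted exactly", {
  theo <- phasor_mono(4, pr80)
  # identity
  c0 <- fit_calibration(theo, 4, pr80)
  expect_equal(c0$phase_offset, 0, tolerance = 1e-12)
  expect_equal(c0$mod_factor, 1, tolerance = 1e-12)
  # rotation by -0.1 rad is undone by +0.1
  m <- phasor_mod(theo); ph <- phasor_phase(theo)
  rot <- phasor_point(m * cos(ph - 0.1), m * sin(ph - 0.1))
  expect_equal(fit_calibration(rot, 4, pr80)$phase_offset, 0.1,
               tolerance = 1e-12)
  # halved modulation needs factor 2
  half <- phasor_point(theo$g / 2, theo$s / 2)
  expect_equal(fit_calibration(half, 4, pr80)$mod_factor, 2,
               tolerance = 1e-12)
  expect_error(fit_calibration(phasor_point(0, 0), 4, pr80), "degenerate")
})

test_that("apply_calibration is a group action on phasor fields", {
  sim <- make_decay_stack(c(1, 4), shape = c(6, 6), n_bins = 128L,
                          layout = "checkerboard", params = pr80)
  fld <- phasor_field(sim$stack)
  ident <- structure(list(phase_offset = 0, mod_factor = 1),
                     class = "calibration")
  expect_equal(apply_calibration(fld, ident)$g, fld$g, tolerance = 1e-14)
  corr <- structure(list(phase_offset = 0.23, mod_factor = 1.4),
                    class = "calibration")
  back <- apply_calibration(apply_calibration(fld, corr),
                            invert_calibration(corr))
  expect_equal(back$g, fld$g, tolerance = 1e-12)
  expect_equal(back$s, fld$s, tolerance = 1e-12)
})

test_that("a distorted field recalibrates onto the semicircle", {
  # simulate an instrument error, fit on the field's own 4-ns reference
  sim <- make_decay_stack(4, shape = c(4, 4), n_bins = 1024L, params = pr80)
  fld <- phasor_field(sim$stack)
  err <- structure(list(phase_offset = -0.17, mod_factor = 0.8),
                   class = "calibration")
  distorted <- apply_calibration(fld, err)
  meas <- phasor_point(distorted$g[1, 1], distorted$s[1, 1])
  corr <- fit_calibration(meas, 4, pr80)
  cal <- apply_calibration(distorted, corr)
  expect_equal(semicircle_distance(cal$g[1, 1], cal$s[1, 1]), 0.5,
               tolerance = 1e-4)
  expect_equal(tau_phase(cal$g[1, 1], cal$s[1, 1], pr80), 4,
               tolerance = 1e-3)
})
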