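free_sp <- flim_species("free", 0.37, epsilon = 1, qy = 0.05, params = pr80)
bound_sp <- flim_species("bound", 3.0, epsilon = 1, qy = 0.5, params = pr80)

test_that("two-component fractions are exact at vertices and midpoints", {
  fa <- fractions_two(free_sp$phasor, free_sp, bound_sp)
  expect_equal(unname(fa$intensity_fractions), c(1, 0), tolerance = 1e-12)
  expect_true(fa$in_gamut)
  mid <- phasor_point((free_sp$phasor$g + bound_sp$phasor$g) / 2,
                      (free_sp$phasor$s + bound_sp$phasor$s) / 2)
  fm <- fractions_two(mid, free_sp, bound_sp)
  expect_equal(unname(fm$intensity_fractions), c(0.5, 0.5),
               tolerance = 1e-12)
})

test_that("off-segment points project orthogonally onto the mixing line", {
  set.seed(10)
  a <- c(free_sp$phasor$g, free_sp$phasor$s)
  b <- c(bound_sp$phasor$g, bound_sp$phasor$s)
  u <- (a - b) / sqrt(sum((a - b)^2))
  perp <- c(-u[2], u[1])
  for (t in c(0.1, 0.5, 0.9)) {
    base <- b + t * (a - b)
    off <- base + 0.01 * perp
    fr <- fractions_two(phasor_point(off[1], off[2]), free_sp, bound_sp)
    # oracle: least-squares projection leaves the parameter unchanged
    expect_equal(unname(fr$intensity_fractions[1]), t, tolerance = 1e-10)
    expect_true(fr$in_gamut)  # 0.01 < default gamut tolerance
  }
  far <- phasor_point(0.9, 0.05)
  expect_false(fractions_two(far, free_sp, bound_sp)$in_gamut)
  expect_error(fractions_two(mid <- free_sp$phasor, free_sp, free_sp),
               "coincide")
})

test_that("three-component unmixing inverts barycentric composition", {
  sps <- list(
    flim_species("crystal", 0.8, params = pr80),
    flim_species("free", 1.9, params = pr80),
    flim_species("membrane", 5.5, params = pr80)
  )
  V <- vapply(sps, function(sp) c(sp$phasor$g, sp$phasor$s), numeric(2))
  # vertices and centroid
  fv <- fractions_three(sps[[2]]$phasor, sps)
  expect_equal(unname(fv$intensity_fractions), c(0, 1, 0), tolerance = 1e-12)
  cen <- phasor_point(mean(V[1, ]), mean(V[2, ]))
  fc <- fractions_three(cen, sps)
  expect_equal(unname(fc$intensity_fractions), rep(1 / 3, 3),
               tolerance = 1e-12)
  # property: forward-compose with random weights, recover within 1e-10
  set.seed(11)
  for (i in 1:25) {
    w <- stats::rgamma(3, 1); w <- w / sum(w)
    p <- phasor_point(sum(w * V[1, ]), sum(w * V[2, ]))
    fr <- fractions_three(p, sps)
    expect_equal(unname(fr$intensity_fractions), w, tolerance = 1e-10)
    expect_true(fr$in_gamut)
  }
  # out-of-triangle points clip, renormalise and lose gamut
  outside <- phasor_point(0.99, 0.01)
  fo <- fractions_three(outside, sps)
  expect_false(fo$in_gamut)
  expect_equal(sum(fo$intensity_fractions), 1, tolerance = 1e-9)
  expect_true(all(fo$intensity_fractions >= 0))
  # collinear vertices are rejected
  col <- list(flim_species("a", 1, params = pr80),
              flim_species("b", 1, params = pr80),
              flim_species("c", 4, params = pr80))
  expect_error(fractions_three(cen, col), "collinear")
})

test_that("molar fractions rescale intensity fractions by brightness", {
  expect_equal(unname(molar_from_intensity(c(0.4, 0.6), c(1, 1))),
               c(0.4, 0.6))
  expect_equal(unname(molar_from_intensity(c(0.5, 0.5), c(2, 1))),
               c(1 / 3, 2 / 3), tolerance = 1e-12)
  # round trip with arbitrary positive brightnesses
  set.seed(12)
  for (i in 1:20) {
    B <- stats::rgamma(3, 2) + 0.05
    f <- stats::rgamma(3, 1); f <- f / sum(f)
    x <- molar_from_intensity(f, B)
    expect_equal(unname(intensity_from_molar(x, B)), unname(f),
                 tolerance = 1e-12)
    expect_equal(sum(x), 1, tolerance = 1e-12)
  }
  expect_error(molar_from_intensity(c(0.5, 0.5), c(1, 0)), "brightness")
})

test_that("liposomal-doxorubicin brightness ratios transfer across storage", {
  # day-0 measurements fix the relative brightnesses B_i ~ f_i / x_i;
  # they must convert the 120-day 37C intensity fractions to the
  # published molar fractions
  f_day0 <- c(crystal = 0.459, free = 0.125, bound = 0.416)
  x_day0 <- c(crystal = 0.988, free = 0.007, bound = 0.005)
  B <- f_day0 / x_day0
  x_37 <- molar_from_intensity(c(0.024, 0.227, 0.749), unname(B))
  expect_lt(abs(x_37[1] - 0.701), 0.01)
  expect_lt(abs(x_37[2] - 0.173), 0.01)
  expect_lt(abs(x_37[3] - 0.126), 0.01)
  # consistency check on the 4C row (its published bound entry is
  # inconsistent with the row sum, so only crystal/free are compared)
  x_4 <- molar_from_intensity(c(0.373, 0.163, 0.464), unname(B))
  expect_lt(abs(x_4[1] - 0.982), 0.01)
  expect_lt(abs(x_4[2] - 0.011), 0.01)
})

test_that("the NADH metabolic fit recovers the bound state", {
  set.seed(13)
  fp <- phasor_mono(0.37, pr80); bp <- phasor_mono(3, pr80)
  fr <- stats::runif(4000)
  g <- fr * bp$g + (1 - fr) * fp$g
  s <- fr * bp$s + (1 - fr) * fp$s
  # noiseless: bound lifetime within 0.1 ns, fractions recovered
  fit0 <- nadh_bound_fit(g, s, params = pr80)
  expect_equal(fit0$bound_lifetime_ns, 3, tolerance = 0.1)
  expect_equal(fit0$bound_fraction, fr, tolerance = 1e-6)
  # phasor jitter at the scale of ~100 photons/pixel: within 0.3 ns
  gn <- g + stats::rnorm(4000, 0, 0.03)
  sn <- s + stats::rnorm(4000, 0, 0.03)
  fitn <- nadh_bound_fit(gn, sn, params = pr80)
  expect_equal(fitn$bound_lifetime_ns, 3, tolerance = 0.3)
  expect_equal(mean(fitn$bound_fraction), mean(fr), tolerance = 0.05)
})

test_that("degenerate and single-point NADH clouds behave as specified", {
  fp <- phasor_mono(0.37, pr80)
  expect_error(nadh_bound_fit(rep(fp$g, 10), rep(fp$s, 10), params = pr80),
               "degenerate")
  # all points at one 60%-bound mixture: mean bound fraction 0.6
  bp <- phasor_mono(3, pr80)
  gx <- 0.6 * bp$g + 0.4 * fp$g
  sx <- 0.6 * bp$s + 0.4 * fp$s
  fit <- nadh_bound_fit(rep(gx, 50), rep(sx, 50), params = pr80)
  expect_equal(fit$mean_bound_fraction, 0.6, tolerance = 1e-6)
  expect_equal(fit$bound_lifetime_ns, 3, tolerance = 0.05)
  # implausible bound lifetimes only warn
  short <- phasor_mono(0.6, pr80)
  fr2 <- c(0.3, 0.7)
  expect_warning(
    nadh_bound_fit(fr2 * short$g + (1 - fr2) * fp$g,
                   fr2 * short$s + (1 - fr2) * fp$s, params = pr80),
    "outside the literature range")
})
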