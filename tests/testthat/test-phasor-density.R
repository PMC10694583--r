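test_that("2D histograms conserve points and bin exactly", {
  h <- build_histogram(rep(0.4, 50), rep(0.3, 50), bins = 10L)
  expect_equal(max(h$counts), 50L)
  expect_equal(h$total, 50L)
  expect_equal(sum(h$counts), 50L)
  # points at 4 distinct bin centres land in 4 distinct bins
  h2 <- build_histogram(c(0.05, 0.15, 0.25, 0.95), c(0.03, 0.09, 0.15, 0.57),
                        bins = 10L)
  expect_equal(sum(h2$counts == 1L), 4L)
  expect_equal(sum(h2$counts), 4L)
  # edge inclusion: g = 1, s = 0.6 are kept in the last bins
  h3 <- build_histogram(c(0, 1), c(0, 0.6), bins = 10L)
  expect_equal(h3$total, 2L)
  cl <- make_phasor_cloud(c(0.5, 0.3), sds = 0.02, n_points = 10000, seed = 1)
  expect_equal(sum(build_histogram(cl$g, cl$s)$counts), 10000L)
  expect_error(build_histogram(numeric(0), numeric(0)), "empty")
})

test_that("noise-floor levels default to min nonzero and 95th percentile", {
  h <- build_histogram(rep(0.4, 10), rep(0.3, 10), bins = 10L)
  h$counts[2, 2] <- 1L; h$counts[3, 3] <- 5L; h$counts[4, 4] <- 100L
  lv <- noise_floor_levels(h)
  expect_equal(lv$bottom, 1)
  expect_equal(lv$top, unname(quantile(c(1, 5, 10, 100), 0.95)))
  # overrides clamp into [0, max]
  expect_equal(noise_floor_levels(h, top_override = 1e6)$top, 100)
  # degenerate: uniform nonzero counts
  hu <- build_histogram(c(0.1, 0.5), c(0.1, 0.5), bins = 4L)
  expect_error(noise_floor_levels(hu), "degenerate")
})

test_that("a single dense cluster yields one ROI with nested phasors", {
  cl <- make_phasor_cloud(c(0.5, 0.3), sds = 0.02, n_points = 8000, seed = 2)
  h <- build_histogram(cl$g, cl$s)
  rs <- detect_regions(h)
  expect_length(rs$perimeters, 1L)
  expect_gte(length(rs$phasors), 1L)
  # nesting: phasor counts never exceed their parent perimeter's
  for (p in rs$phasors) {
    expect_lte(p$count, rs$perimeters[[p$parent]]$count)
  }
  # perimeter captures nearly the whole cloud
  expect_gte(rs$perimeters[[1]]$count, 5000L)
})

test_that("polygon point counts agree with direct point-in-polygon counting", {
  cl <- make_phasor_cloud(c(0.5, 0.3), sds = 0.02, n_points = 8000, seed = 2)
  h <- build_histogram(cl$g, cl$s)
  rs <- detect_regions(h)
  poly <- rs$perimeters[[1]]$polygon
  direct <- sum(pracma::inpolygon(cl$g, cl$s, poly[, 1], poly[, 2],
                                  boundary = TRUE))
  # allowed discrepancy: counts in the one-bin ring around the boundary
  gm <- rep(h$g_mids, times = length(h$s_mids))
  sm <- rep(h$s_mids, each = length(h$g_mids))
  ins <- matrix(pracma::inpolygon(gm, sm, poly[, 1], poly[, 2],
                                  boundary = TRUE), length(h$g_mids))
  shift <- function(m, di, dj) {
    out <- matrix(FALSE, nrow(m), ncol(m))
    si <- seq_len(nrow(m)) + di; sj <- seq_len(ncol(m)) + dj
    ok_i <- si >= 1 & si <= nrow(m); ok_j <- sj >= 1 & sj <= ncol(m)
    out[ok_i, ok_j] <- m[si[ok_i], sj[ok_j]]
    out
  }
  ring <- (ins & !(shift(ins, 1, 0) & shift(ins, -1, 0) &
                   shift(ins, 0, 1) & shift(ins, 0, -1))) |
          (!ins & (shift(ins, 1, 0) | shift(ins, -1, 0) |
                   shift(ins, 0, 1) | shift(ins, 0, -1)))
  allowance <- sum(h$counts[ring])
  expect_lte(abs(direct - rs$perimeters[[1]]$count), allowance)
})

test_that("sparse clusters fall below the ROI point criterion", {
  cl <- make_phasor_cloud(c(0.5, 0.3), sds = 0.02, n_points = 400, seed = 3)
  h <- build_histogram(cl$g, cl$s)
  expect_warning(rs <- detect_regions(h), "min_roi_points")
  expect_length(rs$perimeters, 0L)
  expect_length(rs$phasors, 0L)
})

test_that("well-separated clusters produce one ROI each", {
  cl <- make_phasor_cloud(rbind(c(0.35, 0.25), c(0.65, 0.35)),
                          sds = 0.015, n_points = c(8000, 6000), seed = 4)
  h <- build_histogram(cl$g, cl$s)
  rs <- detect_regions(h)
  expect_length(rs$perimeters, 2L)
  counts <- sort(vapply(rs$perimeters, `[[`, numeric(1), "count"),
                 decreasing = TRUE)
  expect_gte(counts[1], 5000L)
  expect_gte(counts[2], 5000L)
})

test_that("raising min_roi_points never increases the number of ROIs", {
  cl <- make_phasor_cloud(rbind(c(0.35, 0.25), c(0.65, 0.35)),
                          sds = 0.015, n_points = c(8000, 6000), seed = 4)
  h <- build_histogram(cl$g, cl$s)
  thresholds <- c(500L, 5000L, 7000L, 20000L)
  n_rois <- vapply(thresholds, function(m) {
    rs <- suppressWarnings(detect_regions(h, min_roi_points = m))
    length(rs$perimeters)
  }, integer(1))
  expect_true(all(diff(n_rois) <= 0))
})

test_that("region detection is deterministic", {
  cl <- make_phasor_cloud(c(0.5, 0.3), sds = 0.02, n_points = 8000, seed = 5)
  h <- build_histogram(cl$g, cl$s)
  expect_identical(detect_regions(h), detect_regions(h))
})

test_that("points are assigned to their innermost region", {
  cl <- make_phasor_cloud(c(0.5, 0.3), sds = 0.02, n_points = 8000, seed = 2)
  h <- build_histogram(cl$g, cl$s)
  rs <- detect_regions(h)
  asg <- assign_regions(cl$g, cl$s, rs)
  expect_true(all(asg$roi %in% c(0L, seq_along(rs$perimeters))))
  # every point inside a phasor polygon is also inside its parent ROI
  expect_true(all(asg$roi[asg$phasor > 0] > 0))
  # assignment roughly matches the stored point counts (one-bin-ring slack)
  expect_equal(sum(asg$roi == 1L), rs$perimeters[[1]]$count,
               tolerance = 0.05)
})
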