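test_that("decay-stack containers round-trip losslessly", {
  sim <- make_decay_stack(c(1, 4), shape = c(8, 8), n_bins = 64L,
                          noise = "poisson", params = pr80, seed = 7)
  path <- withr::local_tempfile(fileext = ".flim")
  write_container(sim$stack, path)
  back <- read_container(path)
  expect_identical(back$counts, sim$stack$counts)  # bit-level
  expect_equal(back$bin_centers, sim$stack$bin_centers)
  expect_equal(back$params$rep_rate, pr80$rep_rate)
})

test_that("phasor-field containers round-trip and select harmonics", {
  tau <- matrix(2.5, 16, 16)
  tau[1, ] <- NA  # invalid border
  f1 <- make_phasor_field(tau, params = pr80)
  f2 <- make_phasor_field(tau, params = acquisition_params(80e6, 2L))
  path <- withr::local_tempfile(fileext = ".flim")
  write_container(list(f1, f2), path)
  b1 <- read_container(path, harmonic = 1)
  b2 <- read_container(path, harmonic = 2)
  expect_equal(b1$g[f1$valid], f1$g[f1$valid], tolerance = 1e-12)
  expect_equal(b2$s[f2$valid], f2$s[f2$valid], tolerance = 1e-12)
  expect_equal(b2$params$harmonic, 2L)
  expect_false(any(b1$valid[1, ]))
  expect_error(read_container(path, harmonic = 3), "not stored")
})

test_that("corrupt containers raise named format errors", {
  path <- withr::local_tempfile(fileext = ".flim")
  writeBin(charToRaw("NOTAFILE"), path)
  expect_error(read_container(path), "bad magic")
  # rep_rate <= 0 must be refused on write (constructor) and read
  expect_error(acquisition_params(0), "positive")
  con <- file(path, "wb")
  meta <- charToRaw('{"kind":"decay_stack","rep_rate":-1,"dims":[4,2,2]}')
  writeChar("PHFLIM01", con, eos = NULL)
  writeBin(length(meta), con, size = 4L, endian = "little")
  writeBin(meta, con)
  close(con)
  expect_error(read_container(path), "rep_rate")
})

test_that("the .ref dialect reader inverts Eq. 2 per pixel", {
  # phase 45 degrees, modulation 0.707 -> g = s = 0.707*cos(45) ~ 0.49992
  path <- withr::local_tempfile(fileext = ".ref")
  np <- 16L * 16L
  con <- file(path, "wb")
  writeBin(rep(100, np), con, size = 4L, endian = "little")  # intensity
  writeBin(rep(45, np), con, size = 4L, endian = "little")   # phase (deg)
  writeBin(rep(0.707, np), con, size = 4L, endian = "little")
  close(con)
  fld <- read_ref(path, dims = c(16L, 16L), rep_rate = 80e6)
  expect_true(all(abs(fld$g - 0.707 * cos(pi / 4)) < 1e-6))
  expect_true(all(abs(fld$s - 0.707 * sin(pi / 4)) < 1e-6))
  expect_equal(unname(fld$g[1, 1]), 0.4999, tolerance = 1e-4)
})

test_that(".ref files of the wrong length are rejected with plane counts", {
  path <- withr::local_tempfile(fileext = ".ref")
  writeBin(rep(1, 100), path, size = 4L)
  expect_error(read_ref(path, dims = c(16L, 16L)), "dialect error")
})

test_that("write_ref / read_ref round-trips within float32 precision", {
  set.seed(11)
  tau <- matrix(runif(64, 0.5, 6), 8, 8)
  tau[, 1] <- NA  # zero-intensity border column
  fld <- make_phasor_field(tau, intensity = matrix(runif(64, 1, 5), 8, 8),
                           params = pr80)
  path <- withr::local_tempfile(fileext = ".ref")
  write_ref(fld, path)
  back <- read_ref(path, dims = c(8L, 8L), rep_rate = 80e6)
  expect_equal(back$g[fld$valid], fld$g[fld$valid], tolerance = 1e-6)
  expect_equal(back$s[fld$valid], fld$s[fld$valid], tolerance = 1e-6)
  expect_false(any(back$valid[, 1]))  # border stays invalid
  # truncated file -> dialect error
  sz <- file.size(path)
  raw <- readBin(path, "raw", sz)
  writeBin(raw[1:(sz - 40)], path)
  expect_error(read_ref(path, dims = c(8L, 8L)), "dialect error")
})

test_that("vendor formats without a decoder point to the adapter hook", {
  p <- withr::local_tempfile(fileext = ".R64")
  writeBin(raw(16), p)
  expect_error(read_flim_input(p), "unsupported dialect")
  register_flim_reader("r64", function(path, ...) "stub result")
  expect_equal(read_flim_input(p), "stub result")
  rm(list = "r64", envir = phasorflim:::.flim_readers)
})

test_that("date_name_replica file names parse from the outside in", {
  m <- parse_sample_name("2023_experiment 1_1.ref")
  expect_equal(m$date, "2023")
  expect_equal(m$sample_name, "experiment 1")
  expect_equal(m$replica, 1L)
  # underscores inside the sample name stay with the name
  m2 <- parse_sample_name("/data/2024_drug_screen A_12.flim")
  expect_equal(m2$sample_name, "drug_screen A")
  expect_equal(m2$replica, 12L)
  expect_error(parse_sample_name("noseparators.ref"), "date_name_replica")
  expect_error(parse_sample_name("2023_x_zero.ref"), "positive integer")
})

test_that("masks round-trip through single-plane TIFF", {
  mask <- matrix(FALSE, 12, 12); mask[3:8, 2:11] <- TRUE
  path <- withr::local_tempfile(fileext = ".tif")
  write_mask(mask, path)
  expect_identical(read_mask(path), mask)
})

test_that("species tables read with closed-form or measured phasors", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("name,tau_ns,epsilon,qy,g,s",
               "free,0.37,1,0.05,,",
               "bound,3.2,1,0.5,0.31,0.44"), path)
  sps <- read_species_table(path, pr80)
  expect_equal(names(sps), c("free", "bound"))
  thf <- phasor_mono(0.37, pr80)
  expect_phasor_equal(sps$free$phasor, thf$g, thf$s)
  expect_equal(sps$bound$phasor$g, 0.31)  # measured override wins
  writeLines("name,tau_ns\nx,1", path)
  expect_error(read_species_table(path, pr80), "missing column")
})

test_that("region sets serialize with a versioned header", {
  cl <- make_phasor_cloud(c(0.5, 0.3), sds = 0.02, n_points = 8000, seed = 2)
  rs <- detect_regions(build_histogram(cl$g, cl$s))
  path <- withr::local_tempfile(fileext = ".csv")
  write_regions(rs, path)
  expect_match(readLines(path, n = 1), "phasorflim-regions v1")
  df <- read_regions(path)
  expect_setequal(unique(df$kind), c("perimeter", "phasor"))
  expect_equal(max(df$point_count[df$kind == "perimeter"]),
               rs$perimeters[[1]]$count)
})
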