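#' Simulate a time-binned FLIM decay stack with known ground truth
#'
#' Generates per-pixel photon-count decay histograms for a mixture of
#' monoexponential species under periodic pulsed excitation. The expected
#' decay in each pixel is the period-wrapped mixture
#' `I(t) = sum_i A_i * exp(-t/tau_i) / (1 - exp(-T/tau_i))`, sampled at
#' the bin centres, so the continuous-limit phasor equals the closed form
#' `1/(1 - i*omega*tau)` combined by fractional intensities. Optional
#' Poisson noise emulates shot noise.
#'
#' Spatial layouts:
#' \describe{
#'   \item{uniform}{every pixel carries the full mixture;}
#'   \item{checkerboard}{pixels alternate between the first and second
#'     species (requires >= 2 species);}
#'   \item{two_blobs}{two discs, one per species, on a dark (zero photon)
#'     background (requires >= 2 species).}
#' }
#'
#' @param tau_ns Component lifetimes (ns).
#' @param amplitudes Pre-exponential amplitudes; default all equal.
#' @param photons_per_pixel Expected photon count per lit pixel. Default 1000.
#' @param noise `"none"` (expected counts, real-valued) or `"poisson"`.
#' @param shape `c(rows, cols)` image shape. Default `c(64, 64)`.
#' @param layout One of `"uniform"`, `"checkerboard"`, `"two_blobs"`.
#' @param n_bins Number of time bins (>= 64). Default 256.
#' @param params [acquisition_params()]; default 80 MHz, harmonic 1.
#' @param seed Integer seed for the Poisson draw.
#' @return A list with `stack` (a [decay_stack()]) and `truth`, a list
#'   carrying per-pixel true `g`, `s`, `tau_phase`, `tau_mod` matrices,
#'   the per-pixel species index matrix (`species`, NA for mixtures /
#'   background) and the mixture `intensity_fractions`.
#' @export
make_decay_stack <- function(tau_ns, amplitudes = rep(1, length(tau_ns)),
                             photons_per_pixel = 1000,
                             noise = c("none", "poisson"),
                             shape = c(64L, 64L),
                             layout = c("uniform", "checkerboard", "two_blobs"),
                             n_bins = 256L,
                             params = acquisition_params(),
                             seed = 1L) {
  noise <- match.arg(noise)
  layout <- match.arg(layout)
  stopifnot_params(params)
  if (n_bins < 64L) stop("`n_bins` must be >= 64", call. = FALSE)
  if (any(tau_ns <= 0) || any(amplitudes <= 0)) {
    stop("lifetimes and amplitudes must be positive", call. = FALSE)
  }
  if (layout != "uniform" && length(tau_ns) < 2L) {
    stop("layout '", layout, "' needs at least 2 species", call. = FALSE)
  }
  rows <- shape[1]; cols <- shape[2]
  tc <- (seq_len(n_bins) - 0.5) * params$period / n_bins
  dt <- params$period / n_bins

  # period-wrapped, unit-integral decay shape per species (one column each)
  tau_s <- tau_ns * 1e-9
  shapes <- vapply(tau_s, function(tau) {
    w <- exp(-tc / tau) / (tau * (1 - exp(-params$period / tau)))
    w * dt
  }, numeric(n_bins))
  shapes <- shapes / rep(colSums(shapes), each = n_bins)  # exact unit mass

  frac <- amplitudes * tau_ns
  frac <- frac / sum(frac)

  # per-pixel species mixture weights (columns = pixels)
  npix <- rows * cols
  species_ix <- matrix(NA_integer_, rows, cols)
  if (layout == "uniform") {
    wpix <- matrix(frac, nrow = length(tau_ns), ncol = npix)
    lit <- rep(TRUE, npix)
  } else if (layout == "checkerboard") {
    chk <- outer(seq_len(rows), seq_len(cols), function(i, j) (i + j) %% 2L)
    species_ix[] <- ifelse(chk == 0L, 1L, 2L)
    wpix <- matrix(0, length(tau_ns), npix)
    wpix[cbind(as.integer(species_ix), seq_len(npix))] <- 1
    lit <- rep(TRUE, npix)
  } else { # two_blobs
    r <- min(rows, cols) / 5
    c1 <- c(rows / 3, cols / 3); c2 <- c(2 * rows / 3, 2 * cols / 3)
    ri <- matrix(seq_len(rows), rows, cols)
    ci <- matrix(seq_len(cols), rows, cols, byrow = TRUE)
    in1 <- (ri - c1[1])^2 + (ci - c1[2])^2 <= r^2
    in2 <- (ri - c2[1])^2 + (ci - c2[2])^2 <= r^2
    species_ix[in1] <- 1L; species_ix[in2] <- 2L
    wpix <- matrix(0, length(tau_ns), npix)
    sel <- which(!is.na(species_ix))
    wpix[cbind(as.integer(species_ix[sel]), sel)] <- 1
    lit <- !is.na(as.vector(species_ix))
  }

  expected <- shapes %*% wpix * photons_per_pixel  # n_bins x npix
  expected[, !lit] <- 0
  if (noise == "poisson") {
    set.seed(as.integer(seed))
    counts <- array(as.numeric(stats::rpois(length(expected),
                                            lambda = expected)),
                    dim = c(n_bins, rows, cols))
  } else {
    counts <- array(expected, dim = c(n_bins, rows, cols))
  }
  stack <- decay_stack(counts, tc, params)

  # ground truth from closed forms
  pure <- phasor_mono(tau_ns, params)
  if (inherits(pure, "phasor_point")) pure <- data.frame(g = pure$g, s = pure$s)
  gtrue <- matrix(as.numeric(crossprod(wpix, pure$g)), rows, cols)
  strue <- matrix(as.numeric(crossprod(wpix, pure$s)), rows, cols)
  gtrue[!lit] <- NA_real_; strue[!lit] <- NA_real_
  truth <- list(
    g = gtrue, s = strue,
    tau_phase = tau_phase(gtrue, strue, params),
    tau_mod   = tau_mod(gtrue, strue, params),
    species = species_ix,
    intensity_fractions = frac,
    lit = matrix(lit, rows, cols)
  )
  list(stack = stack, truth = truth)
}

#' Simulate a Gaussian phasor cloud with known cluster labels
#'
#' @param centers A `k x 2` matrix (or 2-vector for one cluster) of
#'   cluster centres in `(g, s)`, inside `[0,1] x [0, 0.6]`.
#' @param sds Per-cluster isotropic standard deviation(s); recycled.
#' @param n_points Points per cluster; recycled.
#' @param seed Integer seed.
#' @return A data frame with columns `g`, `s`, `label`.
#' @export
make_phasor_cloud <- function(centers, sds = 0.02, n_points = 1000L,
                              seed = 1L) {
  if (is.null(dim(centers))) centers <- matrix(centers, ncol = 2)
  k <- nrow(centers)
  if (any(centers[, 1] < 0 | centers[, 1] > 1 |
          centers[, 2] < 0 | centers[, 2] > 0.6)) {
    stop("centres must lie inside [0,1] x [0,0.6]", call. = FALSE)
  }
  sds <- rep_len(sds, k)
  n_points <- rep_len(as.integer(n_points), k)
  set.seed(as.integer(seed))
  out <- do.call(rbind, lapply(seq_len(k), function(i) {
    if (n_points[i] == 0L) return(NULL)
    data.frame(
      g = stats::rnorm(n_points[i], centers[i, 1], sds[i]),
      s = stats::rnorm(n_points[i], centers[i, 2], sds[i]),
      label = i
    )
  }))
  if (is.null(out)) out <- data.frame(g = numeric(0), s = numeric(0),
                                      label = integer(0))
  out
}

#' Build a synthetic phasor field at given per-pixel lifetimes
#'
#' Convenience generator used for raster-level fixtures: every pixel gets
#' the closed-form phasor of its lifetime, with optional Gaussian jitter.
#'
#' @param tau_ns Matrix of per-pixel lifetimes (ns); NA = invalid pixel.
#' @param intensity Optional intensity matrix; default 1 on valid pixels.
#' @param jitter Gaussian sd added to g and s. Default 0.
#' @param params [acquisition_params()].
#' @param seed Integer seed (used when `jitter > 0`).
#' @return A `phasor_field`.
#' @export
make_phasor_field <- function(tau_ns, intensity = NULL, jitter = 0,
                              params = acquisition_params(), seed = 1L) {
  valid <- is.finite(tau_ns)
  wt <- params$omega * tau_ns * 1e-9
  g <- 1 / (1 + wt^2)
  s <- wt / (1 + wt^2)
  if (jitter > 0) {
    set.seed(as.integer(seed))
    g <- g + stats::rnorm(length(g), 0, jitter)
    s <- s + stats::rnorm(length(s), 0, jitter)
  }
  if (is.null(intensity)) intensity <- matrix(1, nrow(tau_ns), ncol(tau_ns))
  intensity[!valid] <- 0
  g[!valid] <- NA_real_; s[!valid] <- NA_real_
  phasor_field_new(g, s, intensity, valid, params)
}

#' Write a complete synthetic demo dataset to a directory
#'
#' Emits the inputs a full pipeline run needs: canonical containers for
#' three replicas of a two-blob sample, a `.ref` raster fixture, a binary
#' TIFF mask and a species definition table.
#'
#' @param dir Output directory (created if missing).
#' @param seed Integer seed.
#' @param shape Image shape; default `c(64, 64)`.
#' @return Invisibly, a named list of the written file paths.
#' @export
make_demo_dataset <- function(dir, seed = 1L, shape = c(64L, 64L)) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  params <- acquisition_params()
  paths <- list()
  for (rep_i in 1:3) {
    sim <- make_decay_stack(
      tau_ns = c(1, 4), photons_per_pixel = 500, noise = "poisson",
      shape = shape, layout = "two_blobs", n_bins = 128L, params = params,
      seed = as.integer(seed) + rep_i
    )
    p <- file.path(dir, sprintf("2026_demo sample_%d.flim", rep_i))
    write_container(sim$stack, p)
    paths[[sprintf("replica_%d", rep_i)]] <- p
  }
  fld <- phasor_field(make_decay_stack(
    tau_ns = 2.5, photons_per_pixel = 800, noise = "poisson", shape = shape,
    layout = "uniform", n_bins = 128L, params = params,
    seed = as.integer(seed) + 10L
  )$stack)
  refp <- file.path(dir, "2026_uniform ref_1.ref")
  write_ref(fld, refp)
  paths$ref <- refp

  mask <- matrix(0L, shape[1], shape[2])
  mask[seq_len(shape[1] %/% 2), ] <- 1L
  maskp <- file.path(dir, "mask_top_half.tif")
  write_mask(mask, maskp)
  paths$mask <- maskp

  sp <- data.frame(
    name = c("free", "bound", "precipitate"),
    tau_ns = c(0.37, 3.0, 6.0),
    epsilon = c(1, 1, 1),
    qy = c(0.05, 0.5, 0.8)
  )
  spp <- file.path(dir, "species_table.csv")
  write.csv(sp, spp, row.names = FALSE)
  paths$species <- spp
  invisible(paths)
}
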