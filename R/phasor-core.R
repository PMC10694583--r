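#' Time-binned decay stack
#'
#' Container for per-pixel photon-count decay histograms: a
#' `(time_bin, row, col)` array of nonnegative counts, the time at the
#' centre of each bin, and the acquisition parameters.
#'
#' @param counts Numeric array with dim `(n_bins, rows, cols)`, all
#'   entries >= 0.
#' @param bin_centers Strictly increasing times (s) in `[0, period)`;
#'   length `n_bins`, at least 4 bins.
#' @param params [acquisition_params()].
#' @return An object of class `decay_stack`.
#' @export
decay_stack <- function(counts, bin_centers, params) {
  stopifnot_params(params)
  if (!is.array(counts) || length(dim(counts)) != 3L) {
    stop("`counts` must be a 3D array (time_bin, row, col)", call. = FALSE)
  }
  if (any(counts < 0) || any(!is.finite(counts))) {
    stop("`counts` must be finite and nonnegative", call. = FALSE)
  }
  nb <- dim(counts)[1L]
  if (nb < 4L) stop("need at least 4 time bins", call. = FALSE)
  if (length(bin_centers) != nb) {
    stop("`bin_centers` length must match the first dim of `counts`",
         call. = FALSE)
  }
  if (any(diff(bin_centers) <= 0)) {
    stop("`bin_centers` must be strictly increasing", call. = FALSE)
  }
  if (min(bin_centers) < 0 || max(bin_centers) >= params$period) {
    stop("`bin_centers` must lie in [0, period)", call. = FALSE)
  }
  structure(
    list(counts = counts, bin_centers = as.numeric(bin_centers),
         params = params),
    class = "decay_stack"
  )
}

#' @export
print.decay_stack <- function(x, ...) {
  d <- dim(x$counts)
  cat(sprintf("decay stack: %d time bins, %d x %d pixels, %.3g photons total\n",
              d[1], d[2], d[3], sum(x$counts)))
  print(x$params)
  invisible(x)
}

#' Per-pixel phasor rasters
#'
#' Holds `g`, `s` and intensity rasters plus a validity mask. Pixels with
#' zero intensity carry no phasor meaning and are flagged invalid.
#'
#' @param g,s Numeric matrices of phasor coordinates.
#' @param intensity Nonnegative matrix of per-pixel total counts.
#' @param valid Logical matrix; invalid pixels have undefined `g`, `s`.
#' @param params [acquisition_params()].
#' @return An object of class `phasor_field`.
#' @export
phasor_field_new <- function(g, s, intensity, valid, params) {
  stopifnot_params(params)
  dims <- dim(g)
  if (is.null(dims) ||
      !identical(dims, dim(s)) ||
      !identical(dims, dim(intensity)) ||
      !identical(dims, dim(valid))) {
    stop("g, s, intensity and valid must be matrices of one shape",
         call. = FALSE)
  }
  if (any(intensity < 0, na.rm = TRUE)) {
    stop("intensity must be nonnegative", call. = FALSE)
  }
  structure(
    list(g = g, s = s, intensity = intensity, valid = valid, params = params),
    class = "phasor_field"
  )
}

#' @export
print.phasor_field <- function(x, ...) {
  cat(sprintf("phasor field: %d x %d pixels, %d valid (%.1f%%)\n",
              nrow(x$g), ncol(x$g), sum(x$valid),
              100 * mean(x$valid)))
  print(x$params)
  invisible(x)
}

#' Phasor transform of a single decay histogram
#'
#' Discrete version of the normalised first-harmonic Fourier transform:
#' `g = sum(I_k * cos(omega * t_k)) / sum(I_k)` and the analogous sine
#' component, evaluated by the rectangle rule at the bin centres `t_k`.
#'
#' @param counts Nonnegative counts per time bin.
#' @param bin_centers Bin-centre times (s), strictly increasing.
#' @param params [acquisition_params()].
#' @return A [phasor_point()].
#' @examples
#' pr <- acquisition_params(80e6)
#' tc <- ((1:256) - 0.5) * pr$period / 256
#' dk <- exp(-tc / 4e-9)  # ~4 ns decay
#' phasor_of_decay(dk, tc, pr)
#' @export
phasor_of_decay <- function(counts, bin_centers, params) {
  stopifnot_params(params)
  tot <- sum(counts)
  if (!is.finite(tot) || tot <= 0) {
    stop("undefined phasor: decay has no photons", call. = FALSE)
  }
  wt <- params$omega * bin_centers
  phasor_point(sum(counts * cos(wt)) / tot, sum(counts * sin(wt)) / tot)
}

#' Phasor transform of a full decay stack
#'
#' Applies the discrete phasor transform to every pixel of a
#' [decay_stack()]. The per-pixel intensity is the total photon count;
#' zero-intensity pixels are marked invalid and get `NA` coordinates.
#'
#' @param stack A [decay_stack()].
#' @return A [phasor_field_new()] object.
#' @export
phasor_field <- function(stack) {
  if (!inherits(stack, "decay_stack")) {
    stop("`stack` must be a decay_stack", call. = FALSE)
  }
  d <- dim(stack$counts)
  flat <- matrix(stack$counts, nrow = d[1])          # time x pixels
  intensity <- colSums(flat)
  wt <- stack$params$omega * stack$bin_centers
  gnum <- as.numeric(crossprod(flat, cos(wt)))
  snum <- as.numeric(crossprod(flat, sin(wt)))
  valid <- intensity > 0
  g <- s <- rep(NA_real_, length(intensity))
  g[valid] <- gnum[valid] / intensity[valid]
  s[valid] <- snum[valid] / intensity[valid]
  shape <- d[2:3]
  phasor_field_new(
    g = matrix(g, shape[1], shape[2]),
    s = matrix(s, shape[1], shape[2]),
    intensity = matrix(intensity, shape[1], shape[2]),
    valid = matrix(valid, shape[1], shape[2]),
    params = stack$params
  )
}

#' Fit a calibration correction from a reference measurement
#'
#' Frequency-domain FLIM instruments add a phase offset and modulation
#' scaling to every pixel; both are removed by measuring a reference with
#' a known monoexponential lifetime (classically fluorescein at pH 11,
#' 4.0 ns). The correction maps the measured reference phasor onto the
#' closed-form phasor at the known lifetime.
#'
#' @param measured The measured reference [phasor_point()].
#' @param known_lifetime_ns The reference's true lifetime (ns); default 4.0.
#' @param params [acquisition_params()].
#' @return An object of class `calibration`: list with `phase_offset`
#'   (rad) and `mod_factor` (ratio > 0).
#' @export
fit_calibration <- function(measured, known_lifetime_ns = 4.0, params) {
  stopifnot_params(params)
  measured <- as_phasor_point(measured)
  m_meas <- phasor_mod(measured)
  if (m_meas <= 0) {
    stop("degenerate reference: measured modulation is zero", call. = FALSE)
  }
  theo <- phasor_mono(known_lifetime_ns, params)
  structure(
    list(
      phase_offset = phasor_phase(theo) - phasor_phase(measured),
      mod_factor   = phasor_mod(theo) / m_meas
    ),
    class = "calibration"
  )
}

#' @export
print.calibration <- function(x, ...) {
  cat(sprintf("calibration: phase offset %+.5f rad, modulation factor %.5f\n",
              x$phase_offset, x$mod_factor))
  invisible(x)
}

#' Apply a calibration correction to a phasor field
#'
#' Per-pixel: `m <- m * mod_factor`, `phi <- phi + phase_offset`, then
#' `g`, `s` are recomputed. Invalid pixels are untouched.
#'
#' @param field A [phasor_field_new()] object.
#' @param corr A `calibration` from [fit_calibration()].
#' @return The calibrated `phasor_field`.
#' @export
apply_calibration <- function(field, corr) {
  if (!inherits(field, "phasor_field")) {
    stop("`field` must be a phasor_field", call. = FALSE)
  }
  if (!inherits(corr, "calibration")) {
    stop("`corr` must come from fit_calibration()", call. = FALSE)
  }
  if (corr$mod_factor <= 0) stop("mod_factor must be > 0", call. = FALSE)
  m <- sqrt(field$g^2 + field$s^2) * corr$mod_factor
  phi <- atan2(field$s, field$g) + corr$phase_offset
  out <- field
  out$g <- m * cos(phi)
  out$s <- m * sin(phi)
  out$g[!field$valid] <- NA_real_
  out$s[!field$valid] <- NA_real_
  out
}

#' Invert a calibration correction
#'
#' @param corr A `calibration` object.
#' @return The inverse `calibration` (negated phase offset, reciprocal
#'   modulation factor).
#' @export
invert_calibration <- function(corr) {
  structure(
    list(phase_offset = -corr$phase_offset, mod_factor = 1 / corr$mod_factor),
    class = "calibration"
  )
}
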