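#' Acquisition parameters for frequency-domain FLIM
#'
#' Bundles the pulsed-excitation timing quantities every phasor computation
#' needs: the laser repetition rate, the analysis harmonic `n`, the pulse
#' period `T = 1/rep_rate` and the angular frequency `omega = 2*pi*n*rep_rate`.
#'
#' @param rep_rate Laser repetition rate in Hz. Default 80e6 (80 MHz,
#'   typical of two-photon Ti:sapphire sources).
#' @param harmonic Analysis harmonic, a positive integer. Default 1.
#' @return An object of class `acq_params`: a list with elements
#'   `rep_rate`, `harmonic`, `period` (s) and `omega` (rad/s).
#' @examples
#' p <- acquisition_params(80e6)
#' p$omega / (2 * pi)  # back to Hz
#' @export
acquisition_params <- function(rep_rate = 80e6, harmonic = 1L) {
  if (!is.numeric(rep_rate) || length(rep_rate) != 1L || !is.finite(rep_rate) ||
      rep_rate <= 0) {
    stop("`rep_rate` must be a single positive number (Hz)", call. = FALSE)
  }
  harmonic <- as.integer(harmonic)
  if (is.na(harmonic) || harmonic < 1L) {
    stop("`harmonic` must be a positive integer", call. = FALSE)
  }
  structure(
    list(
      rep_rate = rep_rate,
      harmonic = harmonic,
      period   = 1 / rep_rate,
      omega    = 2 * pi * harmonic * rep_rate
    ),
    class = "acq_params"
  )
}

#' @export
print.acq_params <- function(x, ...) {
  cat(sprintf(
    "FLIM acquisition: rep rate %.4g MHz, harmonic %d, period %.4g ns, omega %.4g rad/s\n",
    x$rep_rate / 1e6, x$harmonic, x$period * 1e9, x$omega
  ))
  invisible(x)
}

is_acq_params <- function(x) inherits(x, "acq_params")

stopifnot_params <- function(params) {
  if (!is_acq_params(params)) {
    stop("`params` must be created by acquisition_params()", call. = FALSE)
  }
  invisible(params)
}

#' A single phasor point
#'
#' @param g,s Real phasor coordinates (first-harmonic cosine and sine
#'   Fourier components of the normalised decay).
#' @return An object of class `phasor_point` with elements `g` and `s`.
#' @export
phasor_point <- function(g, s) {
  if (!is.finite(g) || !is.finite(s)) {
    stop("phasor coordinates must be finite", call. = FALSE)
  }
  structure(list(g = as.numeric(g), s = as.numeric(s)), class = "phasor_point")
}

#' @export
print.phasor_point <- function(x, ...) {
  cat(sprintf("phasor (g = %.5f, s = %.5f), m = %.5f, phi = %.5f rad\n",
              x$g, x$s, phasor_mod(x), phasor_phase(x)))
  invisible(x)
}

as_phasor_point <- function(p) {
  if (inherits(p, "phasor_point")) return(p)
  if (is.numeric(p) && length(p) == 2L) return(phasor_point(p[[1]], p[[2]]))
  stop("expected a phasor_point or a numeric (g, s) pair", call. = FALSE)
}

#' Modulation and phase of a phasor
#'
#' `phasor_mod` returns `m = sqrt(g^2 + s^2)`; `phasor_phase` returns
#' `phi = atan2(s, g)`.
#'
#' @param p A [phasor_point()] or numeric `(g, s)` pair.
#' @return A single number.
#' @export
phasor_mod <- function(p) {
  p <- as_phasor_point(p)
  sqrt(p$g^2 + p$s^2)
}

#' @rdname phasor_mod
#' @export
phasor_phase <- function(p) {
  p <- as_phasor_point(p)
  atan2(p$s, p$g)
}

#' Closed-form phasor of a monoexponential decay
#'
#' For a periodically excited monoexponential decay with lifetime `tau`,
#' the phasor is `1 / (1 - i * omega * tau)`, i.e.
#' `g = 1 / (1 + (omega*tau)^2)` and `s = omega*tau / (1 + (omega*tau)^2)`.
#' These points make up the universal semicircle of centre (1/2, 0) and
#' radius 1/2; the zero-lifetime limit sits at (1, 0) and the
#' infinite-lifetime limit at (0, 0).
#'
#' @param tau_ns Lifetime in nanoseconds (scalar or vector).
#' @param params [acquisition_params()].
#' @return A `phasor_point` for scalar input, otherwise a data frame with
#'   columns `g` and `s`.
#' @examples
#' phasor_mono(4, acquisition_params(80e6))  # fluorescein-like reference
#' @export
phasor_mono <- function(tau_ns, params) {
  stopifnot_params(params)
  if (any(!is.finite(tau_ns)) || any(tau_ns < 0)) {
    stop("`tau_ns` must be finite and >= 0", call. = FALSE)
  }
  wt <- params$omega * tau_ns * 1e-9
  g <- 1 / (1 + wt^2)
  s <- wt / (1 + wt^2)
  if (length(tau_ns) == 1L) phasor_point(g, s) else data.frame(g = g, s = s)
}

#' Closed-form phasor of a mixture of monoexponential species
#'
#' The phasor of a sum of decays is the fractional-intensity-weighted sum
#' of the component phasors (the phasor composition rule). For amplitudes
#' `A_i` and lifetimes `tau_i`, the fractional intensity of species `i` is
#' `A_i * tau_i / sum_j(A_j * tau_j)`.
#'
#' @param tau_ns Vector of component lifetimes (ns).
#' @param amplitudes Vector of pre-exponential amplitudes (same length).
#' @param params [acquisition_params()].
#' @return A list with `point` (the mixture `phasor_point`) and
#'   `intensity_fractions` (named by component index).
#' @export
phasor_mixture <- function(tau_ns, amplitudes, params) {
  stopifnot_params(params)
  if (length(tau_ns) != length(amplitudes)) {
    stop("`tau_ns` and `amplitudes` must have equal length", call. = FALSE)
  }
  if (any(tau_ns <= 0) || any(amplitudes <= 0)) {
    stop("lifetimes and amplitudes must be positive", call. = FALSE)
  }
  f <- amplitudes * tau_ns
  f <- f / sum(f)
  comp <- phasor_mono(c(tau_ns), params)
  if (inherits(comp, "phasor_point")) comp <- data.frame(g = comp$g, s = comp$s)
  list(
    point = phasor_point(sum(f * comp$g), sum(f * comp$s)),
    intensity_fractions = f
  )
}

#' Distance of a phasor from the universal semicircle centre
#'
#' @param g,s Numeric vectors of phasor coordinates.
#' @return `sqrt((g - 1/2)^2 + s^2)`; equals 1/2 on the semicircle.
#' @export
semicircle_distance <- function(g, s) {
  sqrt((g - 0.5)^2 + s^2)
}
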