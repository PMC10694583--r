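ns_per_s <- 1e9

#' Phase and modulation lifetimes of a phasor
#'
#' `tau_phase` computes the phase lifetime `(1/omega) * tan(phi) =
#' (1/omega) * s/g`; `tau_mod` computes the modulation lifetime
#' `(1/omega) * sqrt(1/m^2 - 1)`. For a monoexponential decay the two are
#' identical; for mixtures they differ, which is itself a multiexponential
#' diagnostic.
#'
#' Out-of-range pixels are flagged rather than erroring: `tau_phase`
#' returns `NA` where `g <= 0` (phasor outside the first quadrant);
#' `tau_mod` returns `NA` where `m > 1` (unphysical, calibration suspect)
#' and `Inf` where `m = 0`.
#'
#' @param g,s Numeric vectors/matrices of phasor coordinates, or a single
#'   [phasor_point()] passed as `g` with `s` missing.
#' @param params [acquisition_params()].
#' @return Lifetimes in ns, same shape as the input.
#' @examples
#' pr <- acquisition_params(80e6)
#' tau_phase(phasor_mono(4, pr), params = pr)  # 4 ns
#' @export
tau_phase <- function(g, s, params) {
  if (inherits(g, "phasor_point")) { s <- g$s; g <- g$g }
  stopifnot_params(params)
  out <- (s / g) / params$omega * ns_per_s
  out[!is.na(g) & g <= 0] <- NA_real_
  out
}

#' @rdname tau_phase
#' @export
tau_mod <- function(g, s, params) {
  if (inherits(g, "phasor_point")) { s <- g$s; g <- g$g }
  stopifnot_params(params)
  m2 <- g^2 + s^2
  out <- sqrt(pmax(1 / m2 - 1, 0)) / params$omega * ns_per_s
  out[!is.na(m2) & m2 > 1 + 1e-12] <- NA_real_
  out[!is.na(m2) & m2 == 0] <- Inf
  out
}

#' Summary statistics of a phasor population
#'
#' Computes the barycenter (mean `g`, `s`), the intensity-weighted
#' barycenter, standard errors, and the principal-component variability
#' ratio of a set of phasor points — the metrics used to judge whether a
#' detected phasor region is well sampled and how directional it is.
#'
#' The PCA ratio is defined as `lambda_1 / (lambda_1 + lambda_2)` of the
#' 2x2 covariance of the `(g, s)` points: 0.5 for an isotropic cloud, 1
#' for points on a line.
#'
#' @param g,s Numeric vectors of phasor coordinates.
#' @param intensity Optional nonnegative weights (per-pixel photon counts).
#' @param params Optional [acquisition_params()]; when given, phase and
#'   modulation lifetime means and standard deviations (over points) are
#'   included.
#' @return An object of class `phasor_summary`: list with `n_points`,
#'   `barycenter`, `weighted_barycenter`, `g_err`, `s_err`, `pca_ratio`
#'   and (with `params`) `tau_phase`, `tau_mod`, `sd_phase`, `sd_mod`.
#'   Quantities undefined for a singleton (errors, PCA ratio, sds) are NA.
#' @export
summarize_phasor <- function(g, s, intensity = NULL, params = NULL) {
  keep <- is.finite(g) & is.finite(s)
  g <- g[keep]; s <- s[keep]
  n <- length(g)
  if (n < 1L) stop("no finite phasor points to summarise", call. = FALSE)
  bary <- phasor_point(mean(g), mean(s))
  if (!is.null(intensity)) {
    w <- intensity[keep]
    if (any(w < 0)) stop("intensity weights must be nonnegative", call. = FALSE)
    wbary <- phasor_point(sum(w * g) / sum(w), sum(w * s) / sum(w))
  } else {
    wbary <- bary
  }
  if (n >= 2L) {
    g_err <- sd(g) / sqrt(n)
    s_err <- sd(s) / sqrt(n)
    cv <- cov(cbind(g, s))
    ev <- eigen(cv, symmetric = TRUE, only.values = TRUE)$values
    pca_ratio <- if (sum(ev) <= 0) NA_real_ else ev[1] / sum(ev)
  } else {
    g_err <- s_err <- pca_ratio <- NA_real_
  }
  out <- list(
    n_points = n, barycenter = bary, weighted_barycenter = wbary,
    g_err = g_err, s_err = s_err, pca_ratio = pca_ratio
  )
  if (!is.null(params)) {
    tp <- tau_phase(g, s, params)
    tm <- tau_mod(g, s, params)
    out$tau_phase <- mean(tp, na.rm = TRUE)
    out$tau_mod   <- mean(tm, na.rm = TRUE)
    out$sd_phase  <- if (n >= 2L) sd(tp, na.rm = TRUE) else NA_real_
    out$sd_mod    <- if (n >= 2L) sd(tm, na.rm = TRUE) else NA_real_
  }
  structure(out, class = "phasor_summary")
}

#' @export
print.phasor_summary <- function(x, ...) {
  cat(sprintf("phasor summary: n = %d, barycenter (%.4f, %.4f), PCA ratio %.3f\n",
              x$n_points, x$barycenter$g, x$barycenter$s, x$pca_ratio))
  if (!is.null(x$tau_mod)) {
    cat(sprintf("  tau_phi = %.3f +/- %.3f ns, tau_m = %.3f +/- %.3f ns\n",
                x$tau_phase, x$sd_phase, x$tau_mod, x$sd_mod))
  }
  invisible(x)
}

#' Per-pixel lifetime map
#'
#' @param field A calibrated `phasor_field`.
#' @param selection Optional logical matrix of pixels to map; defaults to
#'   the field's validity mask.
#' @param type `"mod"` (default, modulation lifetime) or `"phase"`.
#' @return A matrix of lifetimes in ns; unselected pixels are `NA`.
#' @export
lifetime_map <- function(field, selection = NULL, type = c("mod", "phase")) {
  type <- match.arg(type)
  if (!inherits(field, "phasor_field")) {
    stop("`field` must be a phasor_field", call. = FALSE)
  }
  if (is.null(selection)) selection <- field$valid
  if (!identical(dim(selection), dim(field$g))) {
    stop("`selection` shape must match the field", call. = FALSE)
  }
  tau <- if (type == "mod") tau_mod(field$g, field$s, field$params)
         else tau_phase(field$g, field$s, field$params)
  tau[!(selection & field$valid)] <- NA_real_
  tau
}
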