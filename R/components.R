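#' Define a fluorescent species / physical state
#'
#' A species is characterised by its name, monoexponential lifetime,
#' molar extinction coefficient and quantum yield. Its pure-state phasor
#' defaults to the closed form at `tau_ns`, but a measured pure-species
#' phasor can be supplied instead (encapsulation and environment shift
#' phasors empirically, so measured references are often preferable).
#'
#' @param name Species name.
#' @param tau_ns Lifetime in ns (> 0).
#' @param epsilon Molar extinction coefficient (any consistent relative
#'   scale; > 0).
#' @param qy Quantum yield in (0, 1].
#' @param params [acquisition_params()] for the closed-form phasor.
#' @param g,s Optional measured phasor override.
#' @return An object of class `flim_species` with a `brightness` field
#'   `epsilon * qy`.
#' @export
flim_species <- function(name, tau_ns, epsilon = 1, qy = 1,
                         params = acquisition_params(), g = NULL, s = NULL) {
  if (tau_ns <= 0) stop("`tau_ns` must be > 0", call. = FALSE)
  if (epsilon <= 0) stop("`epsilon` must be > 0", call. = FALSE)
  if (qy <= 0 || qy > 1) stop("`qy` must be in (0, 1]", call. = FALSE)
  phasor <- if (!is.null(g) && !is.null(s)) phasor_point(g, s)
            else phasor_mono(tau_ns, params)
  structure(
    list(name = name, tau_ns = tau_ns, epsilon = epsilon, qy = qy,
         brightness = epsilon * qy, phasor = phasor),
    class = "flim_species"
  )
}

#' @export
print.flim_species <- function(x, ...) {
  cat(sprintf("species '%s': tau = %.3g ns, brightness = %.3g, phasor (%.4f, %.4f)\n",
              x$name, x$tau_ns, x$brightness, x$phasor$g, x$phasor$s))
  invisible(x)
}

species_phasor <- function(sp) c(sp$phasor$g, sp$phasor$s)

new_fraction_result <- function(f, names, in_gamut, molar = NULL) {
  f <- pmin(pmax(f, 0), 1)
  f <- f / sum(f)
  names(f) <- names
  structure(list(intensity_fractions = f, molar_fractions = molar,
                 in_gamut = in_gamut),
            class = "fraction_result")
}

#' @export
print.fraction_result <- function(x, ...) {
  cat("intensity fractions:",
      paste(sprintf("%s = %.3f", names(x$intensity_fractions),
                    x$intensity_fractions), collapse = ", "), "\n")
  if (!is.null(x$molar_fractions)) {
    cat("molar fractions:    ",
        paste(sprintf("%s = %.3f", names(x$molar_fractions),
                      x$molar_fractions), collapse = ", "), "\n")
  }
  if (!x$in_gamut) cat("(point outside the pure-species gamut; clipped)\n")
  invisible(x)
}

#' Two-component fractional intensities
#'
#' All mixtures of two species lie on the segment joining their pure
#' phasors; an observed phasor is orthogonally projected onto that
#' segment and the fractional intensity of species `a` is the relative
#' distance of the projection from `b`'s phasor. Values are clipped to
#' `[0, 1]`; `in_gamut` is FALSE when the projection parameter leaves
#' `[0, 1]` or the perpendicular residual exceeds `gamut_tol`.
#'
#' @param p Observed [phasor_point()] (or `(g, s)` pair).
#' @param a,b [flim_species()] with distinct phasors.
#' @param gamut_tol Perpendicular distance tolerated before the point is
#'   flagged out of gamut. Default 0.05 phasor units.
#' @return A `fraction_result` with fractions named after the species.
#' @export
fractions_two <- function(p, a, b, gamut_tol = 0.05) {
  p <- as_phasor_point(p)
  pa <- species_phasor(a); pb <- species_phasor(b)
  ab <- pa - pb
  len2 <- sum(ab^2)
  if (len2 < 1e-20) {
    stop("degenerate geometry: the two species phasors coincide",
         call. = FALSE)
  }
  v <- c(p$g, p$s) - pb
  t <- sum(v * ab) / len2                 # 1 at a, 0 at b
  perp <- sqrt(max(sum(v^2) - t^2 * len2, 0))
  in_gamut <- t >= 0 && t <= 1 && perp <= gamut_tol
  new_fraction_result(c(t, 1 - t), c(a$name, b$name), in_gamut)
}

#' Three-component fractional intensities (barycentric unmixing)
#'
#' Mixtures of three species fill the triangle whose vertices are the
#' pure-species phasors; the fractional intensities are the barycentric
#' coordinates of the observed phasor, obtained from the linear system
#' `[g; s; 1] = M f` with `M`'s columns the vertex phasors augmented
#' with 1. Negative components (noise pushing the point outside the
#' triangle) are clipped to zero and the rest renormalised, with
#' `in_gamut = FALSE`.
#'
#' @param p Observed [phasor_point()].
#' @param species List of three [flim_species()] with non-collinear
#'   phasors.
#' @return A `fraction_result`.
#' @export
fractions_three <- function(p, species) {
  if (length(species) != 3L) stop("need exactly 3 species", call. = FALSE)
  p <- as_phasor_point(p)
  M <- rbind(
    vapply(species, function(sp) sp$phasor$g, numeric(1)),
    vapply(species, function(sp) sp$phasor$s, numeric(1)),
    rep(1, 3)
  )
  if (abs(det(M)) < 1e-12) {
    stop("degenerate geometry: species phasors are collinear", call. = FALSE)
  }
  f <- solve(M, c(p$g, p$s, 1))
  in_gamut <- all(f >= -1e-9)
  new_fraction_result(f, vapply(species, `[[`, character(1), "name"),
                      in_gamut)
}

#' Convert intensity fractions to molar fractions (and back)
#'
#' Fractional intensities weight species by brightness `B = epsilon*QY`;
#' molar fractions remove that weighting:
#' `x_i = (f_i / B_i) / sum_j (f_j / B_j)`.
#'
#' @param f Intensity fractions (vector summing to 1) or a
#'   `fraction_result`.
#' @param species List of [flim_species()] supplying brightnesses, or a
#'   numeric vector of brightnesses.
#' @return Named molar fractions summing to 1 (for a `fraction_result`
#'   input, the updated `fraction_result`).
#' @export
molar_from_intensity <- function(f, species) {
  if (inherits(f, "fraction_result")) {
    x <- molar_from_intensity(f$intensity_fractions, species)
    f$molar_fractions <- x
    return(f)
  }
  B <- species_brightness(species, length(f))
  x <- (f / B) / sum(f / B)
  names(x) <- names(f)
  x
}

#' @rdname molar_from_intensity
#' @param x Molar fractions summing to 1.
#' @export
intensity_from_molar <- function(x, species) {
  B <- species_brightness(species, length(x))
  f <- (x * B) / sum(x * B)
  names(f) <- names(x)
  f
}

species_brightness <- function(species, n) {
  B <- if (is.numeric(species)) species
       else vapply(species, `[[`, numeric(1), "brightness")
  if (length(B) != n) {
    stop("need one brightness per fraction", call. = FALSE)
  }
  if (any(B <= 0)) stop("brightness must be > 0 for every species",
                        call. = FALSE)
  B
}

#' Free/bound NADH metabolic fit
#'
#' Cellular NAD(P)H phasor clouds are modelled as two-component mixtures
#' of free NADH (literature lifetime ~0.37 ns, a fixed vertex on the
#' universal semicircle) and enzyme-bound NADH (unknown lifetime between
#' about 1 and 9 ns, depending on the enzyme). The cloud is fitted by a
#' total-least-squares line constrained through the free-NADH vertex;
#' the bound-state phasor is the intersection of that line with the
#' semicircle farther from the free vertex (smaller `g`, longer
#' lifetime), and the bound lifetime its phase lifetime. Each point's
#' bound fraction is then its two-component fractional intensity along
#' the free-bound segment.
#'
#' @param g,s Cloud coordinates (at least 2 distinct points).
#' @param weights Optional nonnegative per-point weights (e.g. histogram
#'   counts).
#' @param free_tau_ns Free-NADH literature lifetime. Default 0.37 ns.
#' @param params [acquisition_params()].
#' @param bound_range Plausible bound-lifetime range; outside it a
#'   warning is issued. Default `c(1, 9)` ns.
#' @return An object of class `nadh_fit`: list with `bound_lifetime_ns`,
#'   `free_species`, `bound_species`, `line` (list `point`, `direction`),
#'   `bound_fraction` (per point) and `mean_bound_fraction`.
#' @export
nadh_bound_fit <- function(g, s, weights = NULL, free_tau_ns = 0.37,
                           params = acquisition_params(),
                           bound_range = c(1, 9)) {
  keep <- is.finite(g) & is.finite(s)
  g <- g[keep]; s <- s[keep]
  if (is.null(weights)) weights <- rep(1, length(g)) else {
    weights <- weights[keep]
    if (any(weights < 0)) stop("weights must be nonnegative", call. = FALSE)
  }
  if (length(g) < 2L) {
    stop("need at least 2 cloud points for the metabolic fit", call. = FALSE)
  }
  p0 <- phasor_mono(free_tau_ns, params)
  dx <- g - p0$g; dy <- s - p0$s
  # weighted scatter about the fixed free vertex; principal axis =
  # constrained total-least-squares direction
  Sxx <- sum(weights * dx * dx)
  Syy <- sum(weights * dy * dy)
  Sxy <- sum(weights * dx * dy)
  if (Sxx + Syy < 1e-16) {
    stop("metabolic fit failed: cloud is degenerate at the free-NADH vertex",
         call. = FALSE)
  }
  ev <- eigen(matrix(c(Sxx, Sxy, Sxy, Syy), 2, 2), symmetric = TRUE)
  dir <- ev$vectors[, 1]

  # intersect p0 + t*dir with the universal semicircle
  # (x - 1/2)^2 + y^2 = 1/4
  cx <- p0$g - 0.5
  A <- sum(dir^2)
  B <- 2 * (cx * dir[1] + p0$s * dir[2])
  C <- cx^2 + p0$s^2 - 0.25
  disc <- B^2 - 4 * A * C
  if (disc < -1e-12) {
    stop("metabolic fit failed: fitted line misses the universal ",
         "semicircle; review thresholding and filtering", call. = FALSE)
  }
  disc <- max(disc, 0)
  t12 <- (-B + c(-1, 1) * sqrt(disc)) / (2 * A)
  cand <- rbind(c(p0$g, p0$s) + t12[1] * dir,
                c(p0$g, p0$s) + t12[2] * dir)
  # free vertex is itself on the semicircle: take the other root
  # (smaller g = longer lifetime), requiring the upper half-plane
  ok <- cand[, 2] >= -1e-9 &
    sqrt((cand[, 1] - p0$g)^2 + (cand[, 2] - p0$s)^2) > 1e-6
  if (!any(ok)) {
    stop("metabolic fit failed: no bound-state intersection distinct from ",
         "the free vertex; review thresholding and filtering", call. = FALSE)
  }
  cand <- cand[ok, , drop = FALSE]
  bound_p <- cand[which.min(cand[, 1]), ]
  bound_tau <- tau_phase(bound_p[1], bound_p[2], params)
  if (!is.finite(bound_tau) ||
      bound_tau < bound_range[1] || bound_tau > bound_range[2]) {
    warning(sprintf(
      "bound NADH lifetime %.2f ns outside the literature range [%g, %g] ns",
      bound_tau, bound_range[1], bound_range[2]))
  }
  free_sp <- flim_species("NADH free", free_tau_ns, params = params)
  bound_sp <- flim_species("NADH bound", max(bound_tau, 1e-6),
                           params = params,
                           g = bound_p[1], s = bound_p[2])
  bf <- vapply(seq_along(g), function(i) {
    fractions_two(c(g[i], s[i]), bound_sp, free_sp)$intensity_fractions[1]
  }, numeric(1))
  structure(
    list(bound_lifetime_ns = bound_tau,
         free_species = free_sp, bound_species = bound_sp,
         line = list(point = c(p0$g, p0$s), direction = dir),
         bound_fraction = bf,
         mean_bound_fraction = sum(weights * bf) / sum(weights)),
    class = "nadh_fit"
  )
}

#' @export
print.nadh_fit <- function(x, ...) {
  cat(sprintf(
    "NADH metabolic fit: bound lifetime %.2f ns, mean bound fraction %.3f (n = %d)\n",
    x$bound_lifetime_ns, x$mean_bound_fraction, length(x$bound_fraction)))
  invisible(x)
}
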