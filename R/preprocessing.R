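#' Intensity-threshold specification
#'
#' @param method `"custom"`, `"otsu"` (two-class) or `"multi_otsu"` (the
#'   pipeline default): all operate on intensity normalised to `[0, 1]`.
#' @param custom_value Threshold in `[0, 1]`; required (and only allowed)
#'   for `method = "custom"`. A value of 0 keeps every unmasked pixel,
#'   the recommended setting when an imported mask already delimits the
#'   analysis region.
#' @param classes Number of classes for multi-Otsu (>= 3); pixels above
#'   the lowest class boundary are kept.
#' @return An object of class `threshold_spec`.
#' @export
threshold_spec <- function(method = c("multi_otsu", "otsu", "custom"),
                           custom_value = NULL, classes = 3L) {
  method <- match.arg(method)
  if (method == "custom") {
    if (is.null(custom_value) || !is.numeric(custom_value) ||
        custom_value < 0 || custom_value > 1) {
      stop("`custom_value` in [0,1] is required for method = 'custom'",
           call. = FALSE)
    }
  } else if (!is.null(custom_value)) {
    stop("`custom_value` is only meaningful for method = 'custom'",
         call. = FALSE)
  }
  classes <- as.integer(classes)
  if (method == "multi_otsu" && classes < 3L) {
    stop("multi-Otsu needs `classes` >= 3", call. = FALSE)
  }
  structure(list(method = method, custom_value = custom_value,
                 classes = classes),
            class = "threshold_spec")
}

#' Spatial-filter specification
#'
#' @param kind `"median"` (default, 3x3 — common phasor-FLIM practice),
#'   `"gaussian"` or `"none"`.
#' @param window Odd integer >= 3, median window side.
#' @param sigma Positive Gaussian standard deviation in pixels.
#' @return An object of class `filter_spec`.
#' @export
filter_spec <- function(kind = c("median", "gaussian", "none"),
                        window = 3L, sigma = 1) {
  kind <- match.arg(kind)
  window <- as.integer(window)
  if (kind == "median" && (window < 3L || window %% 2L == 0L)) {
    stop("median `window` must be an odd integer >= 3", call. = FALSE)
  }
  if (kind == "gaussian" && (!is.numeric(sigma) || sigma <= 0)) {
    stop("gaussian `sigma` must be > 0", call. = FALSE)
  }
  structure(list(kind = kind, window = window, sigma = sigma),
            class = "filter_spec")
}

#' Normalise an intensity raster to [0, 1]
#'
#' Intensity is divided by its maximum before any thresholding, so
#' custom thresholds are always on a 0-1 scale.
#'
#' @param intensity Nonnegative numeric matrix.
#' @return The matrix divided by its maximum.
#' @export
normalize_intensity <- function(intensity) {
  mx <- max(intensity, na.rm = TRUE)
  if (!is.finite(mx) || mx <= 0) {
    stop("empty image: maximum intensity is not positive", call. = FALSE)
  }
  intensity / mx
}

#' Multi-Otsu class boundaries
#'
#' Generalisation of Otsu's method to `classes` classes: thresholds are
#' chosen to maximise the between-class variance of a 256-bin histogram
#' of values in `[0, 1]` (exhaustive search over boundary pairs for 3
#' classes).
#'
#' @param x Numeric values in `[0, 1]`.
#' @param classes Number of classes; currently 3 is supported.
#' @param levels Histogram discretisation. Default 256.
#' @return Sorted numeric vector of `classes - 1` boundaries.
#' @export
multi_otsu_thresholds <- function(x, classes = 3L, levels = 256L) {
  if (classes != 3L) {
    stop("multi-Otsu is implemented for 3 classes", call. = FALSE)
  }
  x <- x[is.finite(x)]
  breaks <- seq(0, 1, length.out = levels + 1L)
  h <- tabulate(pmin(pmax(findInterval(x, breaks, rightmost.closed = TRUE),
                          1L), levels), nbins = levels)
  p <- h / sum(h)
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  P <- cumsum(p)            # class mass up to bin k
  M <- cumsum(p * mids)     # partial first moments
  mu_t <- M[levels]
  csum <- function(a, b) {  # mass / moment of bins (a, b]
    w <- P[b] - if (a >= 1) P[a] else 0
    m <- M[b] - if (a >= 1) M[a] else 0
    c(w, m)
  }
  best <- -Inf; best_kl <- c(1L, 2L)
  for (k1 in 1:(levels - 2L)) {
    wm1 <- csum(0L, k1)
    if (wm1[1] <= 0) next
    for (k2 in (k1 + 1L):(levels - 1L)) {
      wm2 <- csum(k1, k2)
      wm3 <- csum(k2, levels)
      if (wm2[1] <= 0 || wm3[1] <= 0) next
      v <- wm1[1] * (wm1[2] / wm1[1] - mu_t)^2 +
           wm2[1] * (wm2[2] / wm2[1] - mu_t)^2 +
           wm3[1] * (wm3[2] / wm3[1] - mu_t)^2
      if (v > best) { best <- v; best_kl <- c(k1, k2) }
    }
  }
  breaks[best_kl + 1L]
}

#' Resolve the numeric intensity threshold of a spec
#'
#' @param norm_intensity Intensity normalised to `[0, 1]`.
#' @param spec A [threshold_spec()].
#' @return The threshold value in `[0, 1]`.
#' @export
resolve_threshold <- function(norm_intensity, spec) {
  switch(spec$method,
    custom = spec$custom_value,
    otsu = EBImage::otsu(matrix(norm_intensity), range = c(0, 1),
                         levels = 256L),
    multi_otsu = multi_otsu_thresholds(as.numeric(norm_intensity),
                                       classes = spec$classes)[1]
  )
}

#' Select relevant pixels by intensity threshold and mask
#'
#' A pixel is kept iff its normalised intensity is `>=` the resolved
#' threshold AND the mask (when given) is nonzero there.
#'
#' @param intensity Raw intensity matrix (normalised internally).
#' @param spec A [threshold_spec()]; default multi-Otsu.
#' @param mask Optional logical/0-1 matrix of the same shape.
#' @return A logical matrix of selected pixels, with the resolved
#'   threshold attached as attribute `"threshold"`.
#' @export
select_pixels <- function(intensity, spec = threshold_spec(), mask = NULL) {
  norm <- normalize_intensity(intensity)
  if (!is.null(mask)) {
    if (!identical(dim(mask), dim(intensity))) {
      stop("mask shape ", paste(dim(mask), collapse = "x"),
           " does not match image shape ",
           paste(dim(intensity), collapse = "x"), call. = FALSE)
    }
    mask <- mask != 0
  } else {
    mask <- matrix(TRUE, nrow(intensity), ncol(intensity))
  }
  thr <- resolve_threshold(norm[mask], spec)
  sel <- (norm >= thr) & mask
  attr(sel, "threshold") <- thr
  sel
}

#' Spatially filter the g/s rasters of a phasor field
#'
#' Filters `g` and `s` independently with a median or Gaussian kernel.
#' Only valid, selected pixels enter a window (invalid or unselected
#' neighbours are excluded) and windows are clipped at image borders, so
#' no values are invented at edges. Filtering on `g`/`s` rather than on
#' phase avoids phase-wrap artefacts. Intensity and pixel membership are
#' untouched.
#'
#' @param field A `phasor_field`.
#' @param spec A [filter_spec()]; default 3x3 median.
#' @param selection Optional logical matrix restricting both the filtered
#'   pixels and the window contents; defaults to the validity mask.
#' @return The filtered `phasor_field`.
#' @export
smooth_phasors <- function(field, spec = filter_spec(), selection = NULL) {
  if (!inherits(field, "phasor_field")) {
    stop("`field` must be a phasor_field", call. = FALSE)
  }
  if (!inherits(spec, "filter_spec")) {
    stop("`spec` must come from filter_spec()", call. = FALSE)
  }
  if (is.null(selection)) selection <- field$valid
  if (!identical(dim(selection), dim(field$g))) {
    stop("`selection` shape must match the field", call. = FALSE)
  }
  msk <- selection & field$valid
  out <- field
  if (spec$kind == "median") {
    out$g <- .masked_median_filter(field$g, msk, spec$window)
    out$s <- .masked_median_filter(field$s, msk, spec$window)
  } else if (spec$kind == "gaussian") {
    out$g <- .masked_gaussian_filter(field$g, msk, spec$sigma)
    out$s <- .masked_gaussian_filter(field$s, msk, spec$sigma)
  }
  out
}
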