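#' 2D phasor histogram
#'
#' Bins `(g, s)` points on a regular grid (default 100 bins per
#' dimension over `g` in `[0, 1]`, `s` in `[0, 0.6]` — the universal
#' semicircle bounding box with headroom). The last bin is
#' right-inclusive so points exactly on the upper edge are kept.
#'
#' @param g,s Finite numeric vectors of equal length.
#' @param bins Bins per dimension. Default 100.
#' @param g_range,s_range Axis limits. Points outside are dropped with a
#'   warning.
#' @return An object of class `phasor_histogram`: list with `counts`
#'   (`bins x bins` integer matrix, g along rows), `g_edges`, `s_edges`,
#'   `g_mids`, `s_mids`, `total`.
#' @export
build_histogram <- function(g, s, bins = 100L,
                            g_range = c(0, 1), s_range = c(0, 0.6)) {
  keep <- is.finite(g) & is.finite(s)
  g <- g[keep]; s <- s[keep]
  if (length(g) == 0L) {
    stop("empty histogram: no finite phasor points", call. = FALSE)
  }
  inside <- g >= g_range[1] & g <= g_range[2] &
            s >= s_range[1] & s <= s_range[2]
  if (!all(inside)) {
    warning(sum(!inside), " point(s) outside the histogram range dropped")
    g <- g[inside]; s <- s[inside]
  }
  g_edges <- seq(g_range[1], g_range[2], length.out = bins + 1L)
  s_edges <- seq(s_range[1], s_range[2], length.out = bins + 1L)
  gi <- pmin(findInterval(g, g_edges, rightmost.closed = TRUE), bins)
  si <- pmin(findInterval(s, s_edges, rightmost.closed = TRUE), bins)
  counts <- matrix(0L, bins, bins)
  tab <- table(factor(gi, levels = seq_len(bins)),
               factor(si, levels = seq_len(bins)))
  counts[] <- as.integer(tab)
  structure(
    list(counts = counts,
         g_edges = g_edges, s_edges = s_edges,
         g_mids = (g_edges[-1] + g_edges[-(bins + 1)]) / 2,
         s_mids = (s_edges[-1] + s_edges[-(bins + 1)]) / 2,
         total = length(g)),
    class = "phasor_histogram"
  )
}

#' @export
print.phasor_histogram <- function(x, ...) {
  cat(sprintf("phasor histogram: %d x %d bins, %d points, max bin count %d\n",
              nrow(x$counts), ncol(x$counts), x$total, max(x$counts)))
  invisible(x)
}

#' Frequency-level specification for contour analysis
#'
#' @param bottom,top Count levels bounding the level-set scan,
#'   `0 <= bottom < top`.
#' @param n_levels Number of linearly spaced levels (>= 2). Default 10.
#' @return An object of class `level_spec`.
#' @export
level_spec <- function(bottom, top, n_levels = 10L) {
  if (!is.numeric(bottom) || !is.numeric(top) || bottom < 0 ||
      bottom >= top) {
    stop("need 0 <= bottom < top", call. = FALSE)
  }
  n_levels <- as.integer(n_levels)
  if (n_levels < 2L) stop("`n_levels` must be >= 2", call. = FALSE)
  structure(list(bottom = bottom, top = top, n_levels = n_levels),
            class = "level_spec")
}

#' Default frequency levels from the histogram noise floor
#'
#' The bottom level defaults to the smallest nonzero bin count (the
#' lowest frequency attainable after intensity thresholding); the top
#' level to the 95th percentile of nonzero bin counts. Overrides are
#' clamped into `[0, max count]`; both levels can be tuned to suppress
#' frequency noise.
#'
#' @param hist A [build_histogram()] result.
#' @param bottom_override,top_override Optional numeric overrides.
#' @param n_levels Number of levels. Default 10.
#' @return A [level_spec()].
#' @export
noise_floor_levels <- function(hist, bottom_override = NULL,
                               top_override = NULL, n_levels = 10L) {
  nz <- hist$counts[hist$counts > 0]
  if (length(nz) == 0L) stop("histogram is empty", call. = FALSE)
  mx <- max(nz)
  bottom <- if (is.null(bottom_override)) min(nz) else
    min(max(bottom_override, 0), mx)
  top <- if (is.null(top_override)) as.numeric(quantile(nz, 0.95)) else
    min(max(top_override, 0), mx)
  if (bottom >= top) {
    stop("degenerate levels: bottom (", bottom, ") >= top (", top, ")",
         call. = FALSE)
  }
  level_spec(bottom, top, n_levels)
}

polygon_area <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  n <- length(x)
  abs(sum(x * y[c(2:n, 1)] - x[c(2:n, 1)] * y)) / 2
}

points_in_polygon <- function(px, py, poly) {
  pracma::inpolygon(px, py, poly[, 1], poly[, 2], boundary = TRUE)
}

# A point guaranteed to represent the polygon interior: the vertex
# centroid when it falls inside, otherwise the densest histogram bin
# centre contained in the polygon.
representative_point <- function(poly, hist) {
  cx <- mean(poly[, 1]); cy <- mean(poly[, 2])
  if (points_in_polygon(cx, cy, poly)) return(c(cx, cy))
  gm <- rep(hist$g_mids, times = length(hist$s_mids))
  sm <- rep(hist$s_mids, each = length(hist$g_mids))
  ins <- which(points_in_polygon(gm, sm, poly))
  if (length(ins) == 0L) return(c(cx, cy))
  best <- ins[which.max(hist$counts[ins])]
  c(gm[best], sm[best])
}

# number of raw data points represented by a polygon: sum of counts of
# bins whose centres lie inside it
polygon_point_count <- function(poly, hist) {
  grng <- range(poly[, 1]); srng <- range(poly[, 2])
  gi <- which(hist$g_mids >= grng[1] & hist$g_mids <= grng[2])
  si <- which(hist$s_mids >= srng[1] & hist$s_mids <= srng[2])
  if (length(gi) == 0L || length(si) == 0L) return(0L)
  gm <- rep(hist$g_mids[gi], times = length(si))
  sm <- rep(hist$s_mids[si], each = length(gi))
  ins <- points_in_polygon(gm, sm, poly)
  sum(hist$counts[gi, si, drop = FALSE][ins])
}

contains_polygon <- function(outer, inner, hist) {
  rp <- representative_point(inner, hist)
  points_in_polygon(rp[1], rp[2], outer) &&
    polygon_area(inner) < polygon_area(outer)
}

#' Level-set detection of ROIs and nested phasors
#'
#' Scans the 2D phasor histogram as a count surface through a fixed grid
#' of frequency levels (ascending from the noise floor to the top level)
#' and extracts closed iso-count contours by marching squares. Contours
#' touching the histogram boundary are closed along it (the surface is
#' padded below the lowest level before contouring). Each contour is
#' classified:
#' \itemize{
#'   \item disjoint from every stored perimeter and holding at least
#'     `min_roi_points` data points: a new ROI perimeter (which also
#'     seeds its first nested phasor);
#'   \item inside a stored perimeter and inside one of its stored
#'     phasors: replaces the innermost containing phasor (refining it
#'     toward the density mode);
#'   \item inside a stored perimeter, outside all its phasors, with at
#'     least `min_phasor_points` points: appended as a new phasor (a
#'     secondary mode).
#' }
#' A polygon's point count is the sum of counts of bins whose centres it
#' contains.
#'
#' @param hist A [build_histogram()] result.
#' @param levels A [level_spec()]; default [noise_floor_levels()].
#' @param min_roi_points Minimum data points for a new ROI. Default 5000.
#' @param min_phasor_points Minimum data points for a new nested phasor.
#'   Default 500.
#' @return An object of class `region_set`: list with `perimeters` (each
#'   `list(polygon, count, level)`) and `phasors` (each
#'   `list(polygon, count, parent, level, depth)`). Empty (with a
#'   warning) if no contour reaches `min_roi_points`.
#' @export
detect_regions <- function(hist, levels = NULL, min_roi_points = 5000L,
                           min_phasor_points = 500L) {
  if (!inherits(hist, "phasor_histogram")) {
    stop("`hist` must be a phasor_histogram", call. = FALSE)
  }
  if (is.null(levels)) levels <- noise_floor_levels(hist)
  if (levels$top > max(hist$counts)) {
    stop("top level exceeds the maximum bin count", call. = FALSE)
  }
  lv <- seq(levels$bottom, levels$top, length.out = levels$n_levels)

  # pad the count surface with a ring below every level so marching
  # squares always returns closed loops (boundary-touching contours are
  # closed along the histogram edge)
  nb_g <- length(hist$g_mids); nb_s <- length(hist$s_mids)
  dg <- diff(hist$g_mids[1:2]); ds <- diff(hist$s_mids[1:2])
  z <- matrix(min(lv) - 1, nb_g + 2L, nb_s + 2L)
  z[2:(nb_g + 1L), 2:(nb_s + 1L)] <- hist$counts
  xg <- c(hist$g_mids[1] - dg, hist$g_mids, hist$g_mids[nb_g] + dg)
  xs <- c(hist$s_mids[1] - ds, hist$s_mids, hist$s_mids[nb_s] + ds)

  perimeters <- list()
  phasors <- list()
  for (lev in lv) {
    cl <- contourLines(x = xg, y = xs, z = z, levels = lev)
    for (cc in cl) {
      poly <- cbind(cc$x, cc$y)
      if (nrow(poly) < 4L) next
      cnt <- polygon_point_count(poly, hist)
      if (cnt == 0L) next
      parent <- 0L
      for (i in seq_along(perimeters)) {
        if (contains_polygon(perimeters[[i]]$polygon, poly, hist)) {
          parent <- i; break
        }
      }
      if (parent == 0L) {
        if (cnt >= min_roi_points) {
          perimeters[[length(perimeters) + 1L]] <-
            list(polygon = poly, count = cnt, level = lev)
          phasors[[length(phasors) + 1L]] <-
            list(polygon = poly, count = cnt,
                 parent = length(perimeters), level = lev, depth = 1L)
        }
      } else {
        # innermost stored phasor of this ROI containing the contour
        own <- which(vapply(phasors, function(p) p$parent == parent,
                            logical(1)))
        containing <- own[vapply(own, function(i) {
          contains_polygon(phasors[[i]]$polygon, poly, hist)
        }, logical(1))]
        if (length(containing) > 0L) {
          # refine toward the mode, but never below the phasor validity
          # criterion: a core smaller than min_phasor_points keeps the
          # previous polygon
          if (cnt >= min_phasor_points) {
            areas <- vapply(containing,
                            function(i) polygon_area(phasors[[i]]$polygon),
                            numeric(1))
            inner <- containing[which.min(areas)]
            phasors[[inner]]$polygon <- poly
            phasors[[inner]]$count <- cnt
            phasors[[inner]]$level <- lev
            phasors[[inner]]$depth <- phasors[[inner]]$depth + 1L
          }
        } else if (cnt >= min_phasor_points) {
          phasors[[length(phasors) + 1L]] <-
            list(polygon = poly, count = cnt, parent = parent,
                 level = lev, depth = 1L)
        }
      }
    }
  }
  if (length(perimeters) == 0L) {
    warning("no contour reached min_roi_points = ", min_roi_points,
            "; returning an empty region set")
  }
  structure(list(perimeters = perimeters, phasors = phasors,
                 levels = lv, hist_total = hist$total),
            class = "region_set")
}

#' @export
print.region_set <- function(x, ...) {
  cat(sprintf("region set: %d ROI perimeter(s), %d nested phasor(s)\n",
              length(x$perimeters), length(x$phasors)))
  for (i in seq_along(x$perimeters)) {
    cat(sprintf("  ROI %d: %d points\n", i, x$perimeters[[i]]$count))
  }
  for (i in seq_along(x$phasors)) {
    p <- x$phasors[[i]]
    cat(sprintf("  phasor %d (ROI %d): %d points, refinement depth %d\n",
                i, p$parent, p$count, p$depth))
  }
  invisible(x)
}

#' Assign phasor points to detected regions
#'
#' @param g,s Point coordinates.
#' @param regions A `region_set`.
#' @return A data frame with integer columns `roi` and `phasor` (0 =
#'   unassigned); points in several nested polygons get the innermost
#'   phasor.
#' @export
assign_regions <- function(g, s, regions) {
  n <- length(g)
  roi <- integer(n); pha <- integer(n)
  for (i in seq_along(regions$perimeters)) {
    ins <- points_in_polygon(g, s, regions$perimeters[[i]]$polygon)
    roi[ins & roi == 0L] <- i
  }
  if (length(regions$phasors)) {
    areas <- vapply(regions$phasors, function(p) polygon_area(p$polygon),
                    numeric(1))
    for (i in order(areas, decreasing = TRUE)) {
      ins <- points_in_polygon(g, s, regions$phasors[[i]]$polygon)
      pha[ins] <- i
    }
  }
  data.frame(roi = roi, phasor = pha)
}
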