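#' Simple polygons for vessel annotation geometry
#'
#' A polygon is an ordered ring of vertices in pixel coordinates (x right,
#' y down, matching the image convention), stored *without* a repeated
#' closing vertex. Polygons must be simple (non-self-intersecting); holes
#' are not supported — an island of plaque inside a lumen channel is
#' expressed by the annotator as channel polygons around it.
#'
#' @param x Numeric vector of x coordinates, a 2-column matrix, or a
#'   `list(x=, y=)` pair.
#' @param y Numeric vector of y coordinates when `x` is a vector.
#' @return An object of class `vessel_polygon`: a `list(x, y)` of vertices.
#' @examples
#' p <- vessel_polygon(c(0, 1, 1, 0), c(0, 0, 1, 1))
#' polygon_area(p)
#' @export
vessel_polygon <- function(x, y = NULL) {
  p <- as_xy(x, y)
  validate_polygon(p)
  structure(p, class = "vessel_polygon")
}

as_xy <- function(x, y = NULL) {
  if (is.null(y)) {
    if (is.matrix(x) && ncol(x) == 2) {
      p <- list(x = as.numeric(x[, 1]), y = as.numeric(x[, 2]))
    } else if (is.list(x) && all(c("x", "y") %in% names(x))) {
      p <- list(x = as.numeric(x$x), y = as.numeric(x$y))
    } else {
      abort_validation("polygon must be given as (x, y) vectors, a 2-column matrix, or list(x, y)")
    }
  } else {
    p <- list(x = as.numeric(x), y = as.numeric(y))
  }
  if (length(p$x) != length(p$y)) {
    abort_validation("polygon x and y coordinate vectors differ in length")
  }
  # drop a GeoJSON-style repeated closing vertex; closure is implicit
  n <- length(p$x)
  if (n >= 2 && p$x[1] == p$x[n] && p$y[1] == p$y[n]) {
    p$x <- p$x[-n]
    p$y <- p$y[-n]
  }
  p
}

#' @export
print.vessel_polygon <- function(x, ...) {
  cat(sprintf("<vessel_polygon: %d vertices, area %.6g>\n",
              length(x$x), polygon_area(x)))
  invisible(x)
}

# Signed shoelace area (positive for counter-clockwise rings in a y-up
# frame; sign is irrelevant downstream, only |area| is used).
shoelace_area <- function(p) {
  x <- p$x
  y <- p$y
  n <- length(x)
  xn <- x[c(2:n, 1)]
  yn <- y[c(2:n, 1)]
  sum(x * yn - xn * y) / 2
}

validate_polygon <- function(p) {
  if (!all(is.finite(p$x)) || !all(is.finite(p$y))) {
    abort_validation("polygon has non-finite vertex coordinates")
  }
  # collapse exactly repeated consecutive vertices before counting
  n <- length(p$x)
  if (n >= 2) {
    keep <- c(TRUE, !(p$x[-1] == p$x[-n] & p$y[-1] == p$y[-n]))
    p$x <- p$x[keep]
    p$y <- p$y[keep]
    n <- length(p$x)
  }
  if (n < 3) {
    abort_validation("degenerate polygon: fewer than 3 distinct vertices")
  }
  a <- abs(shoelace_area(p))
  if (a == 0) {
    abort_validation("degenerate polygon: zero area (collinear or self-cancelling ring)")
  }
  # Simplicity check: resolving the ring with an even-odd fill must return
  # a single contour whose area equals the |shoelace| area. A bowtie or any
  # self-intersecting ring either splits into several contours or loses
  # (self-cancelling) area.
  simp <- polyclip::polysimplify(list(x = p$x, y = p$y), filltype = "evenodd")
  tot <- sum(vapply(simp, function(q) abs(shoelace_area(q)), numeric(1)))
  if (length(simp) != 1L || abs(tot - a) > 1e-6 * a) {
    abort_validation("polygon is self-intersecting; annotations must be simple rings")
  }
  invisible(TRUE)
}

#' Absolute area of a simple polygon
#'
#' Shoelace (Gauss trapezoid) area, independent of vertex orientation.
#' Units are the square of the coordinate units (pixel^2 for pixel input).
#'
#' @param p A polygon acceptable to [vessel_polygon()].
#' @return A single non-negative number.
#' @export
polygon_area <- function(p) {
  if (!inherits(p, "vessel_polygon")) p <- vessel_polygon(p)
  abs(shoelace_area(p))
}

#' Residual-lumen region sets
#'
#' The residual lumen of a sub-occluded vessel is in general not a single
#' channel but a set of recanalization channels through the plaque; a region
#' set holds zero or more simple polygons (empty means a fully occluded
#' vessel).
#'
#' @param ... Polygons (each acceptable to [vessel_polygon()]), or a single
#'   list of them.
#' @return An object of class `region_set`.
#' @export
region_set <- function(...) {
  polys <- list(...)
  if (length(polys) == 1 && is.list(polys[[1]]) &&
      !is.matrix(polys[[1]]) &&
      (length(polys[[1]]) == 0 || !all(c("x", "y") %in% names(polys[[1]])))) {
    polys <- polys[[1]]
  }
  polys <- lapply(polys, function(p) {
    if (inherits(p, "vessel_polygon")) p else vessel_polygon(p)
  })
  structure(polys, class = "region_set")
}

#' @export
print.region_set <- function(x, ...) {
  cat(sprintf("<region_set: %d region(s), total area %.6g>\n",
              length(x), region_area(x)))
  invisible(x)
}

#' Total area of a region set
#'
#' Sum of member areas. Only meaningful after [canonicalize_regions()] has
#' made the members pairwise disjoint.
#'
#' @param rs A [region_set()].
#' @return Total area (non-negative).
#' @export
region_area <- function(rs) {
  if (length(rs) == 0) return(0)
  sum(vapply(rs, polygon_area, numeric(1)))
}

as_polyclip <- function(rs) lapply(rs, function(p) list(x = p$x, y = p$y))

from_polyclip <- function(contours) {
  # polyclip may emit micro-contours at its integer-grid resolution; drop them
  contours <- Filter(function(q) abs(shoelace_area(q)) > 1e-9, contours)
  structure(lapply(contours, function(q) {
    structure(list(x = q$x, y = q$y), class = "vessel_polygon")
  }), class = "region_set")
}

#' Canonicalize a region set by merging overlaps
#'
#' Hand-drawn residual channels routinely overlap; the canonical form is the
#' geometric union, so that the total area equals the area of the union of
#' the inputs and the members are pairwise disjoint.
#'
#' @param rs A [region_set()] (each member individually valid).
#' @return A `region_set` of pairwise-disjoint polygons.
#' @export
canonicalize_regions <- function(rs) {
  if (!inherits(rs, "region_set")) rs <- region_set(rs)
  if (length(rs) <= 1) return(rs)
  pcs <- as_polyclip(rs)
  merged <- polyclip::polyclip(pcs, pcs, op = "union",
                               fillA = "nonzero", fillB = "nonzero")
  from_polyclip(merged)
}

#' Clip residual regions to the ideal lumen
#'
#' Each residual region is replaced by its intersection with the ideal-lumen
#' contour; empty intersections are dropped. This enforces the defining
#' containment: the residual lumen is part of the ideal lumen.
#'
#' @param residual A [region_set()].
#' @param ideal The ideal-lumen polygon.
#' @return A clipped `region_set`.
#' @export
clip_regions <- function(residual, ideal) {
  if (!inherits(residual, "region_set")) residual <- region_set(residual)
  if (!inherits(ideal, "vessel_polygon")) ideal <- vessel_polygon(ideal)
  if (length(residual) == 0) return(residual)
  clipped <- polyclip::polyclip(as_polyclip(residual),
                                list(list(x = ideal$x, y = ideal$y)),
                                op = "intersection", fillA = "nonzero")
  from_polyclip(clipped)
}

# Douglas-Peucker ring simplification (used on traced raster contours to
# bound vertex counts). tol is the maximum perpendicular deviation in px.
simplify_ring <- function(p, tol = 0.5) {
  x <- p$x
  y <- p$y
  n <- length(x)
  if (n <= 4 || tol <= 0) return(p)
  # anchor the ring at the two mutually farthest of four spread points
  i0 <- 1L
  i1 <- which.max((x - x[i0])^2 + (y - y[i0])^2)
  keep <- logical(n)
  keep[c(i0, i1)] <- TRUE
  dp <- function(a, b) {
    idx <- if (a < b) seq(a, b) else c(seq(a, n), seq_len(b))
    if (length(idx) <= 2) return()
    inner <- idx[-c(1, length(idx))]
    dx <- x[b] - x[a]
    dy <- y[b] - y[a]
    len <- sqrt(dx^2 + dy^2)
    d <- if (len == 0) {
      sqrt((x[inner] - x[a])^2 + (y[inner] - y[a])^2)
    } else {
      abs(dx * (y[inner] - y[a]) - dy * (x[inner] - x[a])) / len
    }
    k <- which.max(d)
    if (d[k] > tol) {
      m <- inner[k]
      keep[m] <<- TRUE
      dp(a, m)
      dp(m, b)
    }
  }
  dp(i0, i1)
  dp(i1, i0)
  structure(list(x = x[keep], y = y[keep]), class = "vessel_polygon")
}
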