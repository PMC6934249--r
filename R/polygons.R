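# Polygon primitives.
#
# Geometry representation used throughout the package:
#   ring     : an n x 2 numeric matrix of (x, y) vertices, not closed
#              (the last vertex is implicitly joined to the first);
#   part     : a list of rings, the first exterior, the rest holes;
#   geometry : a list of parts (a multipolygon when length > 1).
# All coordinates are metres in one shared projected CRS.

# shoelace signed area of one ring (positive = counter-clockwise, y up)
ring_area_signed <- function(ring) {
  x <- ring[, 1]; y <- ring[, 2]
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  sum(x * y2 - x2 * y) / 2
}

check_ring <- function(ring) {
  if (!is.matrix(ring) || ncol(ring) != 2 || nrow(ring) < 3 ||
      anyNA(ring) || !is.numeric(ring)) {
    stop("invalid geometry: each ring must be a numeric n x 2 matrix, n >= 3",
         call. = FALSE)
  }
  invisible(ring)
}

#' Polygon area in hectares
#'
#' Shoelace area of a geometry (exterior rings minus interior rings),
#' converted from square metres to hectares.
#'
#' @param geom A geometry (list of parts; each part a list of rings, the
#'   first exterior and the rest holes).
#' @return Area in hectares.
#' @export
geom_area_ha <- function(geom) {
  a <- 0
  for (part in geom) {
    for (k in seq_along(part)) {
      check_ring(part[[k]])
      ra <- abs(ring_area_signed(part[[k]]))
      a <- a + if (k == 1L) ra else -ra
    }
  }
  a / 1e4
}

geom_bbox <- function(geom) {
  xs <- unlist(lapply(geom, function(p) lapply(p, function(r) r[, 1])))
  ys <- unlist(lapply(geom, function(p) lapply(p, function(r) r[, 2])))
  c(xmin = min(xs), ymin = min(ys), xmax = max(xs), ymax = max(ys))
}

# Even-odd ray-cast of many points against one ring, plus an on-boundary
# flag (within eps of any edge). Vectorised over points; loops over edges.
pip_ring <- function(px, py, ring, eps = 1e-6) {
  n <- nrow(ring)
  xs <- ring[, 1]; ys <- ring[, 2]
  xs2 <- c(xs[-1], xs[1]); ys2 <- c(ys[-1], ys[1])
  inside <- rep(FALSE, length(px))
  onb <- rep(FALSE, length(px))
  for (i in seq_len(n)) {
    x1 <- xs[i]; y1 <- ys[i]; x2 <- xs2[i]; y2 <- ys2[i]
    dx <- x2 - x1; dy <- y2 - y1
    l2 <- dx * dx + dy * dy
    if (l2 == 0) next
    tt <- pmin(1, pmax(0, ((px - x1) * dx + (py - y1) * dy) / l2))
    d2 <- (x1 + tt * dx - px)^2 + (y1 + tt * dy - py)^2
    onb <- onb | d2 <= eps * eps
    if (dy != 0) {
      crosses <- ((y1 > py) != (y2 > py)) &
        (px < x1 + (py - y1) * dx / dy)
      inside <- xor(inside, crosses)
    }
  }
  list(inside = inside, on_boundary = onb)
}

# Membership of points in a geometry: even-odd across every ring (which
# makes holes subtract automatically), boundary-inclusive.
point_in_geom <- function(px, py, geom, eps = 1e-6) {
  inside <- rep(FALSE, length(px))
  onb <- rep(FALSE, length(px))
  for (part in geom) {
    for (ring in part) {
      r <- pip_ring(px, py, ring, eps = eps)
      inside <- xor(inside, r$inside)
      onb <- onb | r$on_boundary
    }
  }
  inside | onb
}

# convenience: a rectangle ring (counter-clockwise)
rect_ring <- function(xmin, ymin, xmax, ymax) {
  rbind(c(xmin, ymin), c(xmax, ymin), c(xmax, ymax), c(xmin, ymax))
}

#' Drop interior rings from polygons
#'
#' Replaces every polygon part by its exterior ring only, so that areas
#' completely enclosed by a polygon (former holes) become part of it. Area
#' never decreases and the input geometry is contained in the output. The
#' operation is idempotent.
#'
#' @param geoms A list of geometries (see [geom_area_ha()] for the
#'   representation), or a settlement tibble with a `geometry` list-column.
#' @return The same structure with interior rings removed.
#' @export
fill_holes <- function(geoms) {
  if (is.data.frame(geoms)) {
    geoms$geometry <- fill_holes(geoms$geometry)
    return(geoms)
  }
  lapply(geoms, function(geom) {
    lapply(geom, function(part) {
      check_ring(part[[1]])
      part[1]
    })
  })
}
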