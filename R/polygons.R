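# Planar polygon helpers used throughout the morphometrics and geometry code.
# Polygons are data.frames / matrices with columns x, y in micrometres; the
# vertex chain is implicitly closed (last vertex joins the first).

as_poly <- function(p) {
  if (is.data.frame(p)) p <- as.matrix(p[, c("x", "y")])
  storage.mode(p) <- "double"
  if (ncol(p) != 2L) stopf("polygon must have two columns (x, y)")
  colnames(p) <- c("x", "y")
  p
}

#' Signed polygon area (shoelace rule)
#'
#' Positive for counter-clockwise vertex order in a y-up frame. Use
#' [poly_area()] for the absolute area.
#' @param p polygon vertices (matrix or data.frame with columns `x`, `y`).
#' @return signed area in squared input units.
#' @keywords internal
poly_area_signed <- function(p) {
  p <- as_poly(p)
  x <- p[, 1L]; y <- p[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  sum(x * yn - xn * y) / 2
}

poly_area <- function(p) abs(poly_area_signed(p))

poly_perimeter <- function(p) {
  p <- as_poly(p)
  xn <- c(p[-1L, 1L], p[1L, 1L]); yn <- c(p[-1L, 2L], p[1L, 2L])
  sum(sqrt((xn - p[, 1L])^2 + (yn - p[, 2L])^2))
}

# Area centroid of a simple polygon.
poly_centroid <- function(p) {
  p <- as_poly(p)
  x <- p[, 1L]; y <- p[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  cr <- x * yn - xn * y
  a <- sum(cr) / 2
  c(x = sum((x + xn) * cr) / (6 * a), y = sum((y + yn) * cr) / (6 * a))
}

# Minimum Euclidean distance from each query point to a vertex chain.
# `closed = TRUE` treats the chain as a polygon boundary.
dist_to_chain <- function(px, py, chain, closed = TRUE) {
  chain <- as_poly(chain)
  x1 <- chain[, 1L]; y1 <- chain[, 2L]
  if (closed) {
    x2 <- c(x1[-1L], x1[1L]); y2 <- c(y1[-1L], y1[1L])
  } else {
    x2 <- x1[-1L]; y2 <- y1[-1L]
    x1 <- x1[-length(x1)]; y1 <- y1[-length(y1)]
  }
  ex <- x2 - x1; ey <- y2 - y1
  el2 <- ex * ex + ey * ey
  el2[el2 == 0] <- .Machine$double.eps
  vapply(seq_along(px), function(i) {
    t <- ((px[i] - x1) * ex + (py[i] - y1) * ey) / el2
    t <- pmin(1, pmax(0, t))
    qx <- x1 + t * ex; qy <- y1 + t * ey
    sqrt(min((px[i] - qx)^2 + (py[i] - qy)^2))
  }, numeric(1L))
}

points_in_polygon <- function(px, py, poly) {
  poly <- as_poly(poly)
  pracma::inpolygon(px, py, poly[, 1L], poly[, 2L], boundary = TRUE)
}

# Pairwise proper-intersection test over non-adjacent edges; O(n^2) but the
# contours handled here have at most a few hundred vertices.
is_simple_polygon <- function(p) {
  p <- as_poly(p)
  n <- nrow(p)
  if (n < 3L) return(FALSE)
  x <- p[, 1L]; y <- p[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  orient <- function(ax, ay, bx, by, cx, cy)
    sign((bx - ax) * (cy - ay) - (by - ay) * (cx - ax))
  for (i in seq_len(n - 2L)) {
    js <- (i + 2L):n
    js <- js[!(i == 1L & js == n)]      # skip edges sharing a vertex
    if (!length(js)) next
    o1 <- orient(x[i], y[i], xn[i], yn[i], x[js], y[js])
    o2 <- orient(x[i], y[i], xn[i], yn[i], xn[js], yn[js])
    o3 <- orient(x[js], y[js], xn[js], yn[js], x[i], y[i])
    o4 <- orient(x[js], y[js], xn[js], yn[js], xn[i], yn[i])
    if (any(o1 != o2 & o3 != o4 & o1 != 0 & o2 != 0 & o3 != 0 & o4 != 0))
      return(FALSE)
  }
  TRUE
}

# Regular-polygon outlines for micropattern shapes, centred at the origin,
# sized to the area of a circle with the given equivalent diameter (µm).
shape_polygon <- function(shape, equivalent_diameter, n_circle = 360L,
                          annulus_inner_fraction = 0.5) {
  area <- pi * (equivalent_diameter / 2)^2
  th <- seq(0, 2 * pi, length.out = n_circle + 1L)[-(n_circle + 1L)]
  switch(shape,
    circle = {
      r <- equivalent_diameter / 2
      data.frame(x = r * cos(th), y = r * sin(th))
    },
    square = {
      s <- sqrt(area)
      data.frame(x = c(-s, s, s, -s) / 2, y = c(-s, -s, s, s) / 2)
    },
    rectangle = {
      w <- sqrt(2 * area); h <- area / w    # 2:1 aspect
      data.frame(x = c(-w, w, w, -w) / 2, y = c(-h, -h, h, h) / 2)
    },
    triangle = {
      s <- sqrt(4 * area / sqrt(3))         # equilateral side
      rc <- s / sqrt(3)
      a <- pi / 2 + c(0, 2, 4) * pi / 3
      data.frame(x = rc * cos(a), y = rc * sin(a))
    },
    annulus = {
      # outline = outer circle; the inner cut-out is carried by the colony
      # mask (cells are excluded from the hole), keeping the outline simple
      f <- annulus_inner_fraction
      ro <- sqrt(area / (pi * (1 - f^2)))
      data.frame(x = ro * cos(th), y = ro * sin(th))
    },
    stopf("unknown colony shape '%s'", shape))
}
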