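# Planar geometry primitives used throughout the package. All coordinates are
# metres in a local park frame (origin at the southwest fence corner). Bush
# polygons are simple rings stored as open n x 2 matrices (first vertex not
# repeated); hulls are convex.

#' Polygon area by the shoelace formula
#'
#' @param poly numeric matrix (n x 2) of ring vertices, open (first vertex not
#'   repeated). Orientation does not matter; the absolute area is returned.
#' @return area in squared input units
#' @export
polygon_area <- function(poly) {
  stopifnot(is.matrix(poly), ncol(poly) == 2, nrow(poly) >= 3)
  x <- poly[, 1]; y <- poly[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  abs(sum(x * yn - xn * y)) / 2
}

#' Polygon centroid (area-weighted)
#' @param poly open ring matrix (n x 2)
#' @return length-2 numeric (x, y)
#' @export
polygon_centroid <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cr <- x * yn - xn * y
  a <- sum(cr) / 2
  if (abs(a) < 1e-12) return(colMeans(poly))  # degenerate: vertex mean
  c(sum((x + xn) * cr), sum((y + yn) * cr)) / (6 * a)
}

#' Convex hull of a point set as an open ring
#' @param pts matrix (n x 2)
#' @return open ring matrix in counter-clockwise order
#' @export
convex_hull <- function(pts) {
  pts <- unique(pts[, 1:2, drop = FALSE])
  if (nrow(pts) < 3) return(pts)
  idx <- grDevices::chull(pts[, 1], pts[, 2])
  pts[rev(idx), , drop = FALSE]  # chull is clockwise; reverse to CCW
}

# Point-in-polygon by ray casting; boundary points count as inside.
point_in_polygon <- function(p, poly) {
  n <- nrow(poly)
  x <- p[1]; y <- p[2]
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    # on-segment check
    if (point_on_segment(p, c(xi, yi), c(xj, yj))) return(TRUE)
    if ((yi > y) != (yj > y)) {
      xint <- xi + (y - yi) * (xj - xi) / (yj - yi)
      if (x < xint) inside <- !inside
    }
    j <- i
  }
  inside
}

point_on_segment <- function(p, a, b, tol = 1e-9) {
  cross <- (b[1] - a[1]) * (p[2] - a[2]) - (b[2] - a[2]) * (p[1] - a[1])
  if (abs(cross) > tol * (1 + max(abs(c(a, b))))) return(FALSE)
  dot <- (p[1] - a[1]) * (b[1] - a[1]) + (p[2] - a[2]) * (b[2] - a[2])
  len2 <- (b[1] - a[1])^2 + (b[2] - a[2])^2
  dot >= -tol && dot <= len2 + tol
}

segments_intersect <- function(p1, p2, q1, q2) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(q1, q2, p1); d2 <- d(q1, q2, p2)
  d3 <- d(p1, p2, q1); d4 <- d(p1, p2, q2)
  if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
      ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))) return(TRUE)
  point_on_segment(p1, q1, q2) || point_on_segment(p2, q1, q2) ||
    point_on_segment(q1, p1, p2) || point_on_segment(q2, p1, p2)
}

#' Test whether two simple polygons intersect
#'
#' True when the polygons share any point (touching boundaries count).
#' @param a,b open ring matrices
#' @return logical
#' @export
polygons_intersect <- function(a, b) {
  if (point_in_polygon(a[1, ], b) || point_in_polygon(b[1, ], a)) return(TRUE)
  na <- nrow(a); nb <- nrow(b)
  for (i in seq_len(na)) {
    p1 <- a[i, ]; p2 <- a[if (i == na) 1 else i + 1, ]
    for (j in seq_len(nb)) {
      q1 <- b[j, ]; q2 <- b[if (j == nb) 1 else j + 1, ]
      if (segments_intersect(p1, p2, q1, q2)) return(TRUE)
    }
  }
  FALSE
}

# Nearest point on a polyline (m x 2, consecutive vertices joined) to p.
# Returns list(point, arc) where arc is the distance along the polyline from
# its first vertex to the projection.
project_on_polyline <- function(p, line) {
  best <- NULL; best_d2 <- Inf; arc0 <- 0
  for (i in seq_len(nrow(line) - 1)) {
    a <- line[i, ]; b <- line[i + 1, ]
    ab <- b - a
    len2 <- sum(ab^2)
    t <- if (len2 == 0) 0 else max(0, min(1, sum((p - a) * ab) / len2))
    q <- a + t * ab
    d2 <- sum((p - q)^2)
    if (d2 < best_d2) {
      best_d2 <- d2
      best <- list(point = q, arc = arc0 + t * sqrt(len2))
    }
    arc0 <- arc0 + sqrt(len2)
  }
  best$total <- arc0
  best
}
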