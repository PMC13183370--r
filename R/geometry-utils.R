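# Internal polygon helpers shared by the ROI and striatal modules.
# Polygons are n x 2 numeric matrices (columns x, y, micrometres), implicitly
# closed (last vertex joins the first). Image convention: y increases ventrally.

#' Polygon area
#'
#' Unsigned area of a simple closed polygon via the shoelace formula.
#'
#' @param poly numeric matrix with columns x, y (vertices, implicitly closed).
#' @return area in the square of the vertex units.
#' @export
polygon_area <- function(poly) {
  poly <- as_polygon(poly)
  abs(pracma::polyarea(poly[, 1], poly[, 2]))
}

as_polygon <- function(poly) {
  poly <- as.matrix(poly)
  if (!is.numeric(poly) || ncol(poly) != 2 || nrow(poly) < 3)
    stop("polygon must be a numeric matrix with >= 3 rows and 2 columns")
  if (any(!is.finite(poly))) stop("polygon vertices must be finite")
  # drop a duplicated closing vertex
  n <- nrow(poly)
  if (abs(poly[1, 1] - poly[n, 1]) < 1e-12 && abs(poly[1, 2] - poly[n, 2]) < 1e-12)
    poly <- poly[-n, , drop = FALSE]
  unname(poly)
}

#' Point-in-polygon membership
#'
#' Tests whether points fall inside or on the boundary of a simple polygon.
#' Boundary points (including vertices) count as inside, matching the cell
#' counting convention used throughout the package.
#'
#' @param x,y point coordinates.
#' @param poly polygon matrix (columns x, y).
#' @return logical vector.
#' @export
points_in_polygon <- function(x, y, poly) {
  poly <- as_polygon(poly)
  if (length(x) == 0) return(logical(0))
  pracma::inpolygon(x, y, poly[, 1], poly[, 2], boundary = TRUE)
}

# Clip a polygon to the half-plane { p : dot(p - point, normal) >= 0 }.
# Sutherland-Hodgman against a single edge; exact for any simple polygon.
# Fast paths: fully-inside polygons are returned untouched, fully-outside
# ones as NULL, without constructing anything.
clip_halfplane <- function(poly, point, normal) {
  poly <- as_polygon(poly)
  n <- nrow(poly)
  sgn <- (poly[, 1] - point[1]) * normal[1] + (poly[, 2] - point[2]) * normal[2]
  if (all(sgn >= 0)) return(poly)
  if (all(sgn < 0)) return(NULL)
  out <- matrix(NA_real_, nrow = 2L * n, ncol = 2)
  m <- 0L
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    sa <- sgn[i]; sb <- sgn[j]
    if (sa >= 0) { m <- m + 1L; out[m, ] <- poly[i, ] }
    if ((sa > 0 && sb < 0) || (sa < 0 && sb > 0)) {
      t <- sa / (sa - sb)
      m <- m + 1L
      out[m, ] <- poly[i, ] + t * (poly[j, ] - poly[i, ])
    }
  }
  if (m < 3) return(NULL)
  out <- out[seq_len(m), , drop = FALSE]
  # remove near-duplicate consecutive vertices introduced by clipping
  nxt <- c(seq_len(m)[-1], 1L)
  dup <- sqrt((out[, 1] - out[nxt, 1])^2 + (out[, 2] - out[nxt, 2])^2) < 1e-9
  if (any(dup)) out <- out[!c(dup[m], dup[-m]), , drop = FALSE]
  if (nrow(out) < 3) return(NULL)
  out
}

# Uniform points inside a disk (analytic, no rejection).
sample_in_disk <- function(n, center, radius) {
  r <- radius * sqrt(stats::runif(n))
  th <- stats::runif(n, 0, 2 * pi)
  cbind(center[1] + r * cos(th), center[2] + r * sin(th))
}

# Intersection points of an infinite line (through p with direction d) with the
# polygon boundary; returns the chord endpoints (extreme intersections) or NULL.
line_polygon_chord <- function(poly, p, d) {
  poly <- as_polygon(poly)
  n <- nrow(poly)
  # signed perpendicular distance of each vertex from the line
  nrm <- c(-d[2], d[1])
  sgn <- (poly[, 1] - p[1]) * nrm[1] + (poly[, 2] - p[2]) * nrm[2]
  pts <- matrix(numeric(0), ncol = 2)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    sa <- sgn[i]; sb <- sgn[j]
    if (sa == 0) pts <- rbind(pts, poly[i, ])
    if ((sa > 0 && sb < 0) || (sa < 0 && sb > 0)) {
      t <- sa / (sa - sb)
      pts <- rbind(pts, poly[i, ] + t * (poly[j, ] - poly[i, ]))
    }
  }
  if (nrow(pts) < 2) return(NULL)
  # project on the line direction, take the extremes
  proj <- (pts[, 1] - p[1]) * d[1] + (pts[, 2] - p[2]) * d[2]
  rbind(pts[which.min(proj), ], pts[which.max(proj), ])
}

# Uniform points inside a polygon by rejection sampling within the bounding box.
sample_in_polygon <- function(n, poly) {
  poly <- as_polygon(poly)
  if (n == 0) return(matrix(numeric(0), ncol = 2, dimnames = list(NULL, c("x", "y"))))
  xr <- range(poly[, 1]); yr <- range(poly[, 2])
  out <- matrix(NA_real_, nrow = 0, ncol = 2)
  guard <- 0L
  while (nrow(out) < n) {
    m <- max(2L * (n - nrow(out)), 16L)
    cx <- stats::runif(m, xr[1], xr[2])
    cy <- stats::runif(m, yr[1], yr[2])
    ok <- points_in_polygon(cx, cy, poly)
    out <- rbind(out, cbind(cx[ok], cy[ok]))
    guard <- guard + 1L
    if (guard > 10000L) stop("rejection sampling failed; polygon may be degenerate")
  }
  out <- out[seq_len(n), , drop = FALSE]
  colnames(out) <- c("x", "y")
  out
}

# Regular k-gon approximation of a disk.
disk_polygon <- function(center, radius, k = 24L) {
  th <- seq(0, 2 * pi, length.out = k + 1L)[-(k + 1L)]
  cbind(center[1] + radius * cos(th), center[2] + radius * sin(th))
}
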