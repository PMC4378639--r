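# Planar polygon primitives shared by the outline generator, the
# morphometry module, and the raster renderer. Polygons are n x 2
# matrices of vertices in order; the closing edge (last -> first) is
# implicit. No spatial-geometry package for simple features is relied
# upon: these few primitives are all the pipeline needs.

#' Signed area of a closed polygon (shoelace formula)
#'
#' Positive for counter-clockwise vertex order.
#'
#' @param xy numeric matrix with two columns (x, y).
#' @return Signed area in squared input units.
#' @export
polygon_signed_area <- function(xy) {
  xy <- as.matrix(xy)
  x <- xy[, 1]; y <- xy[, 2]
  j <- c(seq_len(nrow(xy))[-1], 1L)
  sum(x * y[j] - x[j] * y) / 2
}

#' Polygon area (absolute value of the shoelace formula)
#' @inheritParams polygon_signed_area
#' @export
polygon_area <- function(xy) abs(polygon_signed_area(xy))

#' Polygon boundary length
#' @inheritParams polygon_signed_area
#' @param closed include the closing edge (default TRUE).
#' @export
polygon_perimeter <- function(xy, closed = TRUE) {
  xy <- as.matrix(xy)
  d <- sqrt(rowSums((xy[c(seq_len(nrow(xy))[-1], 1L), , drop = FALSE] - xy)^2))
  if (!closed) d <- d[-length(d)]
  sum(d)
}

#' Area centroid of a polygon
#' @inheritParams polygon_signed_area
#' @export
polygon_centroid <- function(xy) {
  xy <- as.matrix(xy)
  x <- xy[, 1]; y <- xy[, 2]
  j <- c(seq_len(nrow(xy))[-1], 1L)
  cr <- x * y[j] - x[j] * y
  a <- sum(cr) / 2
  if (abs(a) < .Machine$double.eps) return(colMeans(xy))
  c(sum((x + x[j]) * cr), sum((y + y[j]) * cr)) / (6 * a)
}

# Second area moments about the centroid, for the principal (length) axis.
# Green's-theorem forms; independent of vertex density along the boundary.
polygon_moments <- function(xy) {
  xy <- as.matrix(xy)
  c0 <- polygon_centroid(xy)
  x <- xy[, 1] - c0[1]; y <- xy[, 2] - c0[2]
  j <- c(seq_len(nrow(xy))[-1], 1L)
  cr <- x * y[j] - x[j] * y
  a <- sum(cr) / 2
  ixx <- sum(cr * (y^2 + y * y[j] + y[j]^2)) / 12
  iyy <- sum(cr * (x^2 + x * x[j] + x[j]^2)) / 12
  ixy <- sum(cr * (x * y[j] + 2 * x * y + 2 * x[j] * y[j] + x[j] * y)) / 24
  s <- sign(a)
  list(area = abs(a), centroid = c0, ixx = s * ixx, iyy = s * iyy, ixy = s * ixy)
}

# Orientation of the principal axis of the polygon's area distribution,
# in radians; used as the proximo-distal (length) axis of a lamina.
polygon_principal_angle <- function(xy) {
  m <- polygon_moments(xy)
  0.5 * atan2(2 * m$ixy, m$iyy - m$ixx)
}

#' Test points for inclusion in a polygon
#'
#' Vectorised even-odd (ray casting) test. Points on the boundary may fall
#' on either side; callers that care use a tolerance.
#'
#' @param px,py point coordinates.
#' @inheritParams polygon_signed_area
#' @return Logical vector.
#' @export
points_in_polygon <- function(px, py, xy) {
  xy <- as.matrix(xy)
  n <- nrow(xy)
  inside <- logical(length(px))
  xv <- xy[, 1]; yv <- xy[, 2]
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((yv[i] > py) != (yv[j] > py)) &
      (px < (xv[j] - xv[i]) * (py - yv[i]) / (yv[j] - yv[i]) + xv[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

# TRUE if no two non-adjacent edges of the closed polygon intersect.
# O(n^2) vectorised over edge pairs; adequate for outlines up to a few
# thousand vertices.
polygon_is_simple <- function(xy) {
  xy <- as.matrix(xy)
  n <- nrow(xy)
  if (n < 3) return(FALSE)
  j <- c(seq_len(n)[-1], 1L)
  p1x <- xy[, 1]; p1y <- xy[, 2]
  p2x <- xy[j, 1]; p2y <- xy[j, 2]
  idx <- which(outer(seq_len(n), seq_len(n), function(a, b) b > a + 1 &
                       !(a == 1 & b == n)), arr.ind = TRUE)
  a <- idx[, 1]; b <- idx[, 2]
  # quick bounding-box rejection
  keep <- pmin(p1x[a], p2x[a]) <= pmax(p1x[b], p2x[b]) &
    pmax(p1x[a], p2x[a]) >= pmin(p1x[b], p2x[b]) &
    pmin(p1y[a], p2y[a]) <= pmax(p1y[b], p2y[b]) &
    pmax(p1y[a], p2y[a]) >= pmin(p1y[b], p2y[b])
  a <- a[keep]; b <- b[keep]
  if (!length(a)) return(TRUE)
  o <- function(ax, ay, bx, by, cx, cy) sign((bx - ax) * (cy - ay) - (by - ay) * (cx - ax))
  d1 <- o(p1x[a], p1y[a], p2x[a], p2y[a], p1x[b], p1y[b])
  d2 <- o(p1x[a], p1y[a], p2x[a], p2y[a], p2x[b], p2y[b])
  d3 <- o(p1x[b], p1y[b], p2x[b], p2y[b], p1x[a], p1y[a])
  d4 <- o(p1x[b], p1y[b], p2x[b], p2y[b], p2x[a], p2y[a])
  !any(d1 != d2 & d3 != d4)
}

# Clip a polygon to the half-plane {p : dot(p - pt, nrm) <= 0}
# (Sutherland-Hodgman). Returns a matrix, possibly with 0 rows.
clip_halfplane <- function(xy, pt, nrm) {
  xy <- as.matrix(xy)
  n <- nrow(xy)
  d <- (xy[, 1] - pt[1]) * nrm[1] + (xy[, 2] - pt[2]) * nrm[2]
  out_x <- numeric(0); out_y <- numeric(0)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    di <- d[i]; dj <- d[j]
    if (di <= 0) { out_x <- c(out_x, xy[i, 1]); out_y <- c(out_y, xy[i, 2]) }
    if ((di < 0 && dj > 0) || (di > 0 && dj < 0)) {
      t <- di / (di - dj)
      out_x <- c(out_x, xy[i, 1] + t * (xy[j, 1] - xy[i, 1]))
      out_y <- c(out_y, xy[i, 2] + t * (xy[j, 2] - xy[i, 2]))
    }
  }
  cbind(x = out_x, y = out_y)
}
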