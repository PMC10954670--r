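# Low-level planar geometry helpers.

#' Signed polygon area (shoelace formula)
#'
#' The 2D realization of cell "volume": the cross-sectional area enclosed
#' by the ordered membrane nodes.  Counterclockwise vertex order gives a
#' positive area.
#'
#' @param vertices numeric matrix with one `(x, y)` row per vertex, in
#'   order around the polygon (at least 3 rows).
#' @return signed area (positive for counterclockwise orientation).
#' @export
polygon_area <- function(vertices) {
  v <- as.matrix(vertices)
  if (nrow(v) < 3L) stop("polygon_area: need at least 3 vertices")
  if (!all(is.finite(v))) stop("polygon_area: non-finite vertex coordinates")
  x <- v[, 1L]; y <- v[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  sum(x * yn - xn * y) / 2
}

#' Polygon centroid (area-weighted)
#' @param vertices vertex matrix as in [polygon_area()].
#' @return length-2 numeric vector.
#' @keywords internal
polygon_centroid <- function(vertices) {
  v <- as.matrix(vertices)
  x <- v[, 1L]; y <- v[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  cr <- x * yn - xn * y
  a <- sum(cr) / 2
  if (abs(a) < 1e-14) return(colMeans(v))
  c(sum((x + xn) * cr), sum((y + yn) * cr)) / (6 * a)
}

#' Interior angle at the middle node of a triplet
#'
#' Angle between the edges (b -> a) and (b -> c), measured as the
#' counterclockwise rotation from `b->c` to `b->a`, mapped to `[0, 2*pi)`.
#' For a counterclockwise simple polygon this is the interior angle.
#'
#' @param a,b,c length-2 position vectors.
#' @return angle in radians in `[0, 2*pi)`.
#' @keywords internal
interior_angle <- function(a, b, c) {
  u <- a - b; v <- c - b
  if (sum(u * u) < 1e-24 || sum(v * v) < 1e-24) {
    stop("interior_angle: collocated nodes, angle undefined")
  }
  th <- atan2(u[2L], u[1L]) - atan2(v[2L], v[1L])
  th %% (2 * pi)
}

# Vectorized interior angles for triplet index sets.
interior_angles <- function(pos, ia, ib, ic) {
  ux <- pos[ia, 1L] - pos[ib, 1L]; uy <- pos[ia, 2L] - pos[ib, 2L]
  vx <- pos[ic, 1L] - pos[ib, 1L]; vy <- pos[ic, 2L] - pos[ib, 2L]
  (atan2(uy, ux) - atan2(vy, vx)) %% (2 * pi)
}

# Does segment (p1,p2) properly intersect (p3,p4)?  Shared endpoints do
# not count.  Used by the simple-polygon check.
segments_intersect <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) (b[1L] - a[1L]) * (c[2L] - a[2L]) -
    (b[2L] - a[2L]) * (c[1L] - a[1L])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
  d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  ((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
    ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))
}

#' Is a polygon simple (non-self-intersecting)?
#' @param vertices vertex matrix.
#' @return logical.
#' @keywords internal
is_simple_polygon <- function(vertices) {
  v <- as.matrix(vertices)
  n <- nrow(v)
  if (n < 3L) return(FALSE)
  idx <- cbind(seq_len(n), c(seq_len(n)[-1L], 1L))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      # skip adjacent edges (they share an endpoint)
      if (j == i + 1L || (i == 1L && j == n)) next
      if (segments_intersect(v[idx[i, 1L], ], v[idx[i, 2L], ],
                             v[idx[j, 1L], ], v[idx[j, 2L], ])) {
        return(FALSE)
      }
    }
  }
  TRUE
}

#' Point-in-polygon test (ray casting)
#' @keywords internal
point_in_polygon <- function(p, vertices) {
  v <- as.matrix(vertices)
  n <- nrow(v)
  j <- n
  inside <- FALSE
  for (i in seq_len(n)) {
    if ((v[i, 2L] > p[2L]) != (v[j, 2L] > p[2L])) {
      xint <- v[j, 1L] + (p[2L] - v[j, 2L]) / (v[i, 2L] - v[j, 2L]) *
        (v[i, 1L] - v[j, 1L])
      if (p[1L] < xint) inside <- !inside
    }
    j <- i
  }
  inside
}
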