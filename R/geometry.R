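# Planar geometry primitives used throughout the package.
#
# All coordinates are metres in a projected (planar) CRS. The shapes the
# indicator pipeline manipulates are simple: axis-aligned grid squares,
# convex hexagons, rectangles and straight street segments, so the handful
# of exact primitives below (shoelace area, ray casting, Sutherland-Hodgman
# clipping against a convex window, Liang-Barsky segment/box clipping)
# covers every geometric operation the pipeline needs.

#' Signed area of a polygon ring
#'
#' Positive for counter-clockwise rings, negative for clockwise.
#'
#' @param x,y Numeric vectors of ring vertex coordinates (metres). The ring
#'   must not repeat its first vertex at the end.
#' @return Signed area in square metres.
#' @keywords internal
polygon_signed_area <- function(x, y) {
  n <- length(x)
  if (n < 3) return(0)
  j <- c(n, seq_len(n - 1L))
  sum(x[j] * y - x * y[j]) / 2
}

#' Polygon area (absolute, shoelace formula)
#'
#' @inheritParams polygon_signed_area
#' @return Area in square metres.
#' @export
polygon_area <- function(x, y) abs(polygon_signed_area(x, y))

# Ensure counter-clockwise vertex order.
ensure_ccw <- function(poly) {
  if (polygon_signed_area(poly$x, poly$y) < 0) {
    poly <- list(x = rev(poly$x), y = rev(poly$y))
  }
  poly
}

# TRUE when a ring is convex (after orientation normalisation); collinear
# runs are tolerated.
is_convex <- function(x, y, tol = 1e-9) {
  n <- length(x)
  if (n < 4) return(TRUE)
  nxt <- c(seq(2, n), 1L)
  nx2 <- nxt[nxt]
  cross <- (x[nxt] - x) * (y[nx2] - y[nxt]) - (y[nxt] - y) * (x[nx2] - x[nxt])
  scale <- max(abs(cross), 1)
  all(cross >= -tol * scale) || all(cross <= tol * scale)
}

#' Point-in-polygon test (even-odd rule)
#'
#' Vectorised over points. Points exactly on the boundary are classified by
#' the crossing parity and should not be relied upon; callers that care about
#' boundary points use explicit tolerances.
#'
#' @param px,py Numeric vectors of point coordinates.
#' @param poly A list with numeric `x` and `y` ring coordinates.
#' @return Logical vector.
#' @export
point_in_polygon <- function(px, py, poly) {
  x <- poly$x; y <- poly$y
  n <- length(x)
  inside <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((y[i] > py) != (y[j] > py)) &
      (px < (x[j] - x[i]) * (py - y[i]) / (y[j] - y[i]) + x[i])
    inside <- xor(inside, crosses & !is.na(crosses))
    j <- i
  }
  inside
}

#' Clip a polygon by a convex window (Sutherland-Hodgman)
#'
#' The subject polygon may be any simple polygon; the clip window must be
#' convex (grid cells, hexagons and study-extent rectangles all are).
#'
#' @param subject List with `x`, `y`: the polygon to clip.
#' @param clip List with `x`, `y`: a convex clip window.
#' @return A list with `x`, `y` (possibly empty vectors when the
#'   intersection is empty or degenerate).
#' @export
clip_polygon <- function(subject, clip) {
  if (!is_convex(clip$x, clip$y)) {
    stop("clip window must be convex", call. = FALSE)
  }
  clip <- ensure_ccw(clip)
  out_x <- subject$x
  out_y <- subject$y
  nc <- length(clip$x)
  for (k in seq_len(nc)) {
    if (length(out_x) == 0) break
    ax <- clip$x[k]; ay <- clip$y[k]
    bx <- clip$x[if (k == nc) 1L else k + 1L]
    by <- clip$y[if (k == nc) 1L else k + 1L]
    # signed distance to clip edge; >= 0 is inside for CCW windows
    side <- (bx - ax) * (out_y - ay) - (by - ay) * (out_x - ax)
    n <- length(out_x)
    new_x <- numeric(0); new_y <- numeric(0)
    for (i in seq_len(n)) {
      j <- if (i == 1L) n else i - 1L
      cur_in <- side[i] >= 0
      prev_in <- side[j] >= 0
      if (cur_in != prev_in) {
        t <- side[j] / (side[j] - side[i])
        new_x <- c(new_x, out_x[j] + t * (out_x[i] - out_x[j]))
        new_y <- c(new_y, out_y[j] + t * (out_y[i] - out_y[j]))
      }
      if (cur_in) {
        new_x <- c(new_x, out_x[i])
        new_y <- c(new_y, out_y[i])
      }
    }
    out_x <- new_x; out_y <- new_y
  }
  list(x = out_x, y = out_y)
}

#' Overlap of a segment with an axis-aligned box (Liang-Barsky)
#'
#' Returns the parameter interval of the segment lying inside the closed box
#' and the overlap length in metres.
#'
#' @param x1,y1,x2,y2 Segment endpoints (metres).
#' @param xmin,xmax,ymin,ymax Box bounds (metres).
#' @return List with `t0`, `t1` (clip parameters in `[0, 1]`, `NA` when the
#'   segment misses the box) and `length` (metres of overlap, 0 on a miss).
#' @export
segment_box_overlap <- function(x1, y1, x2, y2, xmin, xmax, ymin, ymax) {
  dx <- x2 - x1
  dy <- y2 - y1
  t0 <- 0; t1 <- 1
  for (k in 1:4) {
    p <- switch(k, -dx, dx, -dy, dy)
    q <- switch(k, x1 - xmin, xmax - x1, y1 - ymin, ymax - y1)
    if (p == 0) {
      if (q < 0) return(list(t0 = NA_real_, t1 = NA_real_, length = 0))
    } else {
      r <- q / p
      if (p < 0) {
        if (r > t1) return(list(t0 = NA_real_, t1 = NA_real_, length = 0))
        if (r > t0) t0 <- r
      } else {
        if (r < t0) return(list(t0 = NA_real_, t1 = NA_real_, length = 0))
        if (r < t1) t1 <- r
      }
    }
  }
  list(t0 = t0, t1 = t1, length = (t1 - t0) * sqrt(dx^2 + dy^2))
}

#' Project a point onto a segment
#'
#' @param px,py Point coordinates.
#' @param ax,ay,bx,by Segment endpoints.
#' @return List with `t` (clamped parameter along the segment), `x`, `y`
#'   (foot of projection) and `dist` (metres from the point to the foot).
#'   Vectorised over segments.
#' @keywords internal
project_point_segment <- function(px, py, ax, ay, bx, by) {
  dx <- bx - ax
  dy <- by - ay
  len2 <- dx^2 + dy^2
  t <- ifelse(len2 > 0, ((px - ax) * dx + (py - ay) * dy) / len2, 0)
  t <- pmin(1, pmax(0, t))
  qx <- ax + t * dx
  qy <- ay + t * dy
  list(t = t, x = qx, y = qy, dist = sqrt((px - qx)^2 + (py - qy)^2))
}

# Rectangle ring helper (CCW).
rect_ring <- function(xmin, ymin, xmax, ymax) {
  list(x = c(xmin, xmax, xmax, xmin), y = c(ymin, ymin, ymax, ymax))
}
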