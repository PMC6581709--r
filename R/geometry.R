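# Low-level 2D polygon primitives used by the hand template and the geodesic
# engine. All polygons are plain n x 2 numeric matrices, vertices in order,
# closed implicitly (last vertex connects back to the first). The boundary is
# part of the polygon (closed set), so points on an edge count as inside.

# default tolerance for orientation / incidence predicates, template units
.tol <- 1e-9

poly_signed_area <- function(poly) {
  x <- poly[, 1]
  y <- poly[, 2]
  xn <- c(x[-1], x[1])
  yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

poly_is_ccw <- function(poly) poly_signed_area(poly) > 0

# cross product of (b - a) x (c - a)
cross2 <- function(ax, ay, bx, by, cx, cy) {
  (bx - ax) * (cy - ay) - (by - ay) * (cx - ax)
}

#' @noRd
poly_edges <- function(poly) {
  n <- nrow(poly)
  list(
    x1 = poly[, 1], y1 = poly[, 2],
    x2 = poly[c(2:n, 1), 1], y2 = poly[c(2:n, 1), 2]
  )
}

# TRUE if the closed polygon is simple: no two non-adjacent edges intersect
# and adjacent edges meet only at their shared vertex. O(n^2), used by
# validators only.
poly_is_simple <- function(poly, tol = .tol) {
  n <- nrow(poly)
  if (n < 3) return(FALSE)
  e <- poly_edges(poly)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      adjacent <- (j == i + 1) || (i == 1 && j == n)
      hit <- segments_intersect(
        e$x1[i], e$y1[i], e$x2[i], e$y2[i],
        e$x1[j], e$y1[j], e$x2[j], e$y2[j], tol
      )
      if (adjacent) {
        # adjacent edges must not overlap beyond the shared vertex
        if (hit$overlap) return(FALSE)
      } else if (hit$touch) {
        return(FALSE)
      }
    }
  }
  TRUE
}

# Segment intersection classifier. Returns list(touch=, overlap=):
# touch  - the two segments share at least one point
# overlap - they are collinear and share more than one point
segments_intersect <- function(ax, ay, bx, by, cx, cy, dx, dy, tol = .tol) {
  d1 <- cross2(cx, cy, dx, dy, ax, ay)
  d2 <- cross2(cx, cy, dx, dy, bx, by)
  d3 <- cross2(ax, ay, bx, by, cx, cy)
  d4 <- cross2(ax, ay, bx, by, dx, dy)
  scale <- max(abs(c(ax, ay, bx, by, cx, cy, dx, dy)), 1)
  eps <- tol * scale
  if (((d1 > eps & d2 < -eps) | (d1 < -eps & d2 > eps)) &&
      ((d3 > eps & d4 < -eps) | (d3 < -eps & d4 > eps))) {
    return(list(touch = TRUE, overlap = FALSE))
  }
  on_seg <- function(px, py, qx, qy, rx, ry) {
    # r collinear with pq assumed; is r within the box?
    rx >= min(px, qx) - eps & rx <= max(px, qx) + eps &
      ry >= min(py, qy) - eps & ry <= max(py, qy) + eps
  }
  touches <- c(
    abs(d1) <= eps && on_seg(ax, ay, bx, by, cx, cy),
    abs(d2) <= eps && on_seg(ax, ay, bx, by, dx, dy),
    abs(d3) <= eps && on_seg(cx, cy, dx, dy, ax, ay),
    abs(d4) <= eps && on_seg(cx, cy, dx, dy, bx, by)
  )
  collinear <- abs(d1) <= eps && abs(d2) <= eps && abs(d3) <= eps && abs(d4) <= eps
  overlap <- FALSE
  if (collinear && any(touches)) {
    # project onto the dominant axis and measure shared extent
    if (abs(bx - ax) >= abs(by - ay)) {
      lo <- max(min(ax, bx), min(cx, dx))
      hi <- min(max(ax, bx), max(cx, dx))
    } else {
      lo <- max(min(ay, by), min(cy, dy))
      hi <- min(max(ay, by), max(cy, dy))
    }
    overlap <- (hi - lo) > eps
  }
  list(touch = any(touches), overlap = overlap)
}

# Vectorized point-in-polygon, boundary inclusive (closed polygon).
# pts: m x 2 matrix. Returns logical vector of length m.
point_in_polygon <- function(poly, pts, tol = 1e-7) {
  pts <- rbind(pts)
  px <- pts[, 1]
  py <- pts[, 2]
  n <- nrow(poly)
  e <- poly_edges(poly)
  inside <- rep(FALSE, length(px))
  on_edge <- rep(FALSE, length(px))
  for (k in seq_len(n)) {
    x1 <- e$x1[k]; y1 <- e$y1[k]; x2 <- e$x2[k]; y2 <- e$y2[k]
    dx <- x2 - x1; dy <- y2 - y1
    L2 <- dx * dx + dy * dy
    t <- pmin(1, pmax(0, ((px - x1) * dx + (py - y1) * dy) / L2))
    on_edge <- on_edge | ((px - (x1 + t * dx))^2 + (py - (y1 + t * dy))^2) <= tol^2
    crosses <- ((y1 > py) != (y2 > py)) &
      (px < (x2 - x1) * (py - y1) / (y2 - y1) + x1)
    inside <- xor(inside, crosses)
  }
  inside | on_edge
}

# Nearest point on the polygon boundary to each row of pts. m x 2 -> m x 2.
closest_boundary_point <- function(poly, pts) {
  pts <- rbind(pts)
  px <- pts[, 1]
  py <- pts[, 2]
  e <- poly_edges(poly)
  best_d2 <- rep(Inf, length(px))
  bx <- px
  by <- py
  for (k in seq_len(nrow(poly))) {
    x1 <- e$x1[k]; y1 <- e$y1[k]; x2 <- e$x2[k]; y2 <- e$y2[k]
    dx <- x2 - x1; dy <- y2 - y1
    L2 <- dx * dx + dy * dy
    t <- pmin(1, pmax(0, ((px - x1) * dx + (py - y1) * dy) / L2))
    qx <- x1 + t * dx
    qy <- y1 + t * dy
    d2 <- (px - qx)^2 + (py - qy)^2
    better <- d2 < best_d2
    best_d2[better] <- d2[better]
    bx[better] <- qx[better]
    by[better] <- qy[better]
  }
  cbind(bx, by, deparse.level = 0)
}

# Parameters t in [0,1] at which segment a->b meets the polygon boundary.
# Collinear overlaps contribute both overlap endpoints.
segment_boundary_params <- function(poly, a, b, tol = .tol) {
  ax <- a[1]; ay <- a[2]; bx <- b[1]; by <- b[2]
  ux <- bx - ax; uy <- by - ay
  e <- poly_edges(poly)
  vx <- e$x2 - e$x1
  vy <- e$y2 - e$y1
  wx <- e$x1 - ax
  wy <- e$y1 - ay
  denom <- ux * vy - uy * vx
  scale <- max(abs(c(ax, ay, bx, by)), max(abs(poly)), 1)
  eps <- tol * scale
  ts <- numeric(0)
  # generic intersections
  gen <- abs(denom) > eps * eps
  if (any(gen)) {
    t <- (wx * vy - wy * vx)[gen] / denom[gen]
    s <- (wx * uy - wy * ux)[gen] / denom[gen]
    ok <- t >= -1e-9 & t <= 1 + 1e-9 & s >= -1e-9 & s <= 1 + 1e-9
    ts <- c(ts, pmin(1, pmax(0, t[ok])))
  }
  # collinear overlaps: edge endpoints projected onto a->b
  col <- !gen & abs(wx * uy - wy * ux) <= eps * max(sqrt(ux^2 + uy^2), 1)
  if (any(col)) {
    L2 <- ux * ux + uy * uy
    for (k in which(col)) {
      for (pt in list(c(e$x1[k], e$y1[k]), c(e$x2[k], e$y2[k]))) {
        t <- ((pt[1] - ax) * ux + (pt[2] - ay) * uy) / L2
        # only keep projections that actually lie on the edge point
        if (t >= -1e-9 && t <= 1 + 1e-9) {
          q <- c(ax + t * ux, ay + t * uy)
          if (sum((q - pt)^2) <= (eps * 10)^2) ts <- c(ts, min(1, max(0, t)))
        }
      }
    }
  }
  sort(unique(ts))
}

# TRUE if the closed segment a->b stays within the closed polygon.
# Strategy: collect all boundary-incidence parameters along the segment and
# test the midpoint of every sub-interval for containment; grazing contact
# with the boundary is allowed (closed-set convention).
segment_in_polygon <- function(poly, a, b, tol = .tol) {
  if (sum((a - b)^2) == 0) {
    return(point_in_polygon(poly, rbind(a))[1])
  }
  ts <- c(0, segment_boundary_params(poly, a, b, tol), 1)
  ts <- sort(unique(ts))
  mids <- (ts[-length(ts)] + ts[-1]) / 2
  mids <- unique(c(0, mids, 1))
  pts <- cbind(a[1] + mids * (b[1] - a[1]), a[2] + mids * (b[2] - a[2]))
  all(point_in_polygon(poly, pts))
}

# Indices of reflex vertices (interior angle > pi) of a CCW simple polygon.
reflex_vertices <- function(poly, tol = .tol) {
  n <- nrow(poly)
  prv <- c(n, seq_len(n - 1))
  nxt <- c(2:n, 1)
  cr <- (poly[, 1] - poly[prv, 1]) * (poly[nxt, 2] - poly[, 2]) -
    (poly[, 2] - poly[prv, 2]) * (poly[nxt, 1] - poly[, 1])
  which(cr < -tol * max(abs(poly), 1))
}
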