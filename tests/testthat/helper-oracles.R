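# Shared fixtures and independent oracles.

# Small polygons used across geometry tests (plain matrices, CCW).
square_poly <- rbind(c(0, 0), c(4, 0), c(4, 4), c(0, 4))
l_poly <- rbind(c(0, 0), c(3, 0), c(3, 1), c(1, 1), c(1, 3), c(0, 3))

# Wrap a bare polygon as a hand_template so the geodesic API accepts it.
# The 24 dummy sites are placed on a small interior grid; geometry tests that
# use these templates never rely on the site layout.
poly_template <- function(poly, interior_pt) {
  sites <- tibble::tibble(
    site_id = 1:24,
    digit = rep(c("I", "II", "III", "IV", "V", "palm"), each = 4),
    segment = "palm", distal_rank = 0L,
    x = interior_pt[1] + 0.001 * (1:24),
    y = interior_pt[2] + 0.0005 * (1:24)
  )
  structure(
    list(version = paste0("test-", nrow(poly)), side = "right", outline = poly,
         sites = sites, hand_length = 1, units_per_cm = 1),
    class = "hand_template"
  )
}

square_template <- poly_template(square_poly, c(2, 2))
l_template <- poly_template(l_poly, c(0.5, 0.5))

# Independent shortest-path oracle: 8-connected grid graph inside the
# polygon, Dijkstra via igraph. Converges to the true geodesic from above as
# spacing -> 0 (up to the ~8.2% octile-metric overshoot plus O(spacing)
# endpoint snapping). Returns a function(p, q) -> length.
grid_geodesic_oracle <- function(poly, spacing) {
  xs <- seq(min(poly[, 1]), max(poly[, 1]), by = spacing)
  ys <- seq(min(poly[, 2]), max(poly[, 2]), by = spacing)
  grid <- as.matrix(expand.grid(x = xs, y = ys))
  inside <- tactloc:::point_in_polygon(poly, grid)
  idx <- matrix(NA_integer_, length(xs), length(ys))
  idx[inside] <- seq_len(sum(inside))
  nodes <- grid[inside, , drop = FALSE]
  nx <- length(xs)
  ny <- length(ys)
  edges <- NULL
  weights <- NULL
  for (d in list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(1L, -1L))) {
    i <- rep(seq_len(nx), ny)
    j <- rep(seq_len(ny), each = nx)
    i2 <- i + d[1]
    j2 <- j + d[2]
    ok <- i2 >= 1 & i2 <= nx & j2 >= 1 & j2 <= ny
    a <- idx[cbind(i[ok], j[ok])]
    b <- idx[cbind(i2[ok], j2[ok])]
    keep <- !is.na(a) & !is.na(b)
    a <- a[keep]
    b <- b[keep]
    # reject edges whose midpoint leaves the polygon (notch shortcuts)
    mid <- (nodes[a, , drop = FALSE] + nodes[b, , drop = FALSE]) / 2
    min_ok <- tactloc:::point_in_polygon(poly, mid)
    a <- a[min_ok]
    b <- b[min_ok]
    edges <- rbind(edges, cbind(a, b))
    weights <- c(weights, rep(spacing * sqrt(sum(d^2)), length(a)))
  }
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  igraph::E(g)$weight <- weights
  snap <- function(p) {
    which.min((nodes[, 1] - p[1])^2 + (nodes[, 2] - p[2])^2)
  }
  function(p, q) {
    igraph::distances(g, v = snap(p), to = snap(q))[1, 1]
  }
}

# Uniform random points strictly inside a polygon (rejection sampling).
sample_inside <- function(poly, n, margin = 0) {
  out <- matrix(NA_real_, 0, 2)
  lo <- apply(poly, 2, min)
  hi <- apply(poly, 2, max)
  while (nrow(out) < n) {
    cand <- cbind(stats::runif(4 * n, lo[1], hi[1]),
                  stats::runif(4 * n, lo[2], hi[2]))
    keep <- tactloc:::point_in_polygon(poly, cand)
    if (margin > 0) {
      bp <- tactloc:::closest_boundary_point(poly, cand)
      keep <- keep & sqrt(rowSums((bp - cand)^2)) >= margin
    }
    out <- rbind(out, cand[keep, , drop = FALSE])
  }
  out[seq_len(n), , drop = FALSE]
}

# quick valid session from a trials sketch (fills bookkeeping columns)
make_session <- function(site_id, resp_x, resp_y, side = "right",
                         missing = rep(FALSE, length(site_id)), ...) {
  new_session(
    subject_id = "test", side = side,
    trials = tibble::tibble(
      trial_index = seq_along(site_id), site_id = site_id,
      attempts = ifelse(missing, 3L, 1L),
      resp_x = resp_x, resp_y = resp_y, missing = missing
    ),
    ...
  )
}

# a session whose every response is exactly at its stimulated site
identity_session <- function(template, reps = 5, side = template$side) {
  sites <- rep(template$sites$site_id, each = reps)
  pos <- tactloc:::site_position(template, sites)
  make_session(sites, pos[, 1], pos[, 2], side = side)
}
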