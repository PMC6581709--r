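# Geodesic (shortest in-polygon path) engine.
#
# The error metrics are defined as lengths of locally length-minimizing
# curves inside the schematic hand, not straight-line distances: a response
# on the neighbouring fingertip is far away along the hand surface even when
# the two fingertips are close in the plane. In a simple polygon the shortest
# path is a polyline whose interior bends occur only at reflex vertices of
# the outline, so exact geodesics come from Dijkstra over the visibility
# graph of {endpoints} + {reflex vertices}.
#
# Per template we precompute the visibility graph over the reflex vertices
# plus the 24 site positions and its all-pairs shortest paths
# (Floyd-Warshall; ~30 nodes). A query point then only needs one visibility
# scan against those nodes. Cached per template geometry; caching does not
# change results.

.tactloc_geo_cache <- new.env(parent = emptyenv())

.template_key <- function(template) {
  o <- template$outline
  paste(template$version, template$side, template$units_per_cm,
        nrow(o), format(sum(o), digits = 17), format(sum(o * o), digits = 17),
        format(sum(template$sites$x) + sum(template$sites$y), digits = 17),
        sep = "|")
}

# Precomputed geodesic scaffold: nodes (reflex vertices then sites),
# all-pairs shortest distances D and next-hop matrix for path reconstruction.
geo_precompute <- function(template) {
  key <- .template_key(template)
  hit <- .tactloc_geo_cache[[key]]
  if (!is.null(hit)) return(hit)

  poly <- template$outline
  rv <- reflex_vertices(poly)
  nodes <- rbind(poly[rv, , drop = FALSE],
                 cbind(template$sites$x, template$sites$y))
  n_reflex <- length(rv)
  m <- nrow(nodes)
  W <- matrix(Inf, m, m)
  diag(W) <- 0
  for (i in seq_len(m - 1)) {
    for (j in (i + 1):m) {
      if (segment_in_polygon(poly, nodes[i, ], nodes[j, ])) {
        W[i, j] <- W[j, i] <- sqrt(sum((nodes[i, ] - nodes[j, ])^2))
      }
    }
  }
  # Floyd-Warshall with next-hop bookkeeping
  nxt <- matrix(NA_integer_, m, m)
  nxt[is.finite(W)] <- col(W)[is.finite(W)]
  D <- W
  for (k in seq_len(m)) {
    through <- outer(D[, k], D[k, ], `+`)
    better <- through < D
    if (any(better)) {
      D[better] <- through[better]
      nxt[better] <- matrix(nxt[, k], m, m)[better]
    }
  }
  res <- list(nodes = nodes, n_reflex = n_reflex, D = D, nxt = nxt,
              site_idx = n_reflex + seq_len(nrow(template$sites)))
  .tactloc_geo_cache[[key]] <- res
  res
}

# visibility of point p to every precomputed node (reflex + sites)
.vis_to_nodes <- function(template, geo, p) {
  vapply(seq_len(nrow(geo$nodes)), function(i) {
    segment_in_polygon(template$outline, p, geo$nodes[i, ])
  }, logical(1))
}

.check_inside <- function(template, p, name) {
  if (!point_in_polygon(template$outline, rbind(p))[1]) {
    stop(sprintf("point %s = (%.4g, %.4g) lies outside the hand outline",
                 name, p[1], p[2]))
  }
}

#' Geodesic distance within the hand outline
#'
#' Length of the shortest path from `p` to `q` that stays inside the closed
#' hand polygon. Equals the Euclidean distance whenever the straight segment
#' between the points does not leave the hand; otherwise the path bends
#' around reflex outline vertices (web notches between fingers).
#'
#' @param template a `hand_template`.
#' @param p,q points in template coordinates (length-2 numeric vectors).
#' @return distance in template units (non-negative scalar).
#' @examples
#' tpl <- default_hand_template("right")
#' s <- tpl$sites
#' geodesic_distance(tpl, c(s$x[s$site_id == 5], s$y[s$site_id == 5]),
#'                        c(s$x[s$site_id == 9], s$y[s$site_id == 9]))
#' @export
geodesic_distance <- function(template, p, q) {
  geodesic_path(template, p, q)$length
}

#' @rdname geodesic_distance
#' @return `geodesic_path()` returns a list with `waypoints` (k x 2 matrix:
#'   `p`, any intermediate reflex vertices, `q`) and `length`.
#' @export
geodesic_path <- function(template, p, q) {
  p <- as.numeric(p)
  q <- as.numeric(q)
  .check_inside(template, p, "p")
  .check_inside(template, q, "q")
  if (all(abs(p - q) < .Machine$double.eps)) {
    return(list(waypoints = rbind(p, q, deparse.level = 0), length = 0))
  }
  poly <- template$outline
  if (segment_in_polygon(poly, p, q)) {
    return(list(waypoints = rbind(p, q, deparse.level = 0),
                length = sqrt(sum((p - q)^2))))
  }
  geo <- geo_precompute(template)
  vp <- .vis_to_nodes(template, geo, p)
  vq <- .vis_to_nodes(template, geo, q)
  dp <- ifelse(vp, sqrt((geo$nodes[, 1] - p[1])^2 + (geo$nodes[, 2] - p[2])^2), Inf)
  dq <- ifelse(vq, sqrt((geo$nodes[, 1] - q[1])^2 + (geo$nodes[, 2] - q[2])^2), Inf)
  total <- outer(dp, dq, `+`) + geo$D
  best <- which(total == min(total), arr.ind = TRUE)[1, ]
  i <- best[1]; j <- best[2]
  if (!is.finite(total[i, j])) {
    stop("no in-polygon path found; template outline may be degenerate")
  }
  mid <- .reconstruct_nodes(geo, i, j)
  list(waypoints = rbind(p, geo$nodes[mid, , drop = FALSE], q,
                         deparse.level = 0),
       length = total[i, j])
}

.reconstruct_nodes <- function(geo, i, j) {
  path <- i
  while (i != j) {
    i <- geo$nxt[i, j]
    path <- c(path, i)
  }
  path
}

#' Geodesic distances from one point to all 24 stimulation sites
#'
#' One visibility scan plus table lookups against the precomputed
#' reflex-vertex graph; used by confusion-matrix discretization where every
#' response must be compared against every site.
#'
#' @param template a `hand_template`.
#' @param p a point in template coordinates.
#' @return numeric vector of 24 distances (template units), ordered by
#'   `site_id`.
#' @export
geodesic_to_sites <- function(template, p) {
  p <- as.numeric(p)
  .check_inside(template, p, "p")
  geo <- geo_precompute(template)
  poly <- template$outline
  vp <- .vis_to_nodes(template, geo, p)
  dp <- ifelse(vp, sqrt((geo$nodes[, 1] - p[1])^2 + (geo$nodes[, 2] - p[2])^2), Inf)
  # through-graph distance to each site node; direct visibility is the
  # degenerate one-hop case already covered because site nodes are in dp
  d <- vapply(geo$site_idx, function(s) min(dp + geo$D[, s]), numeric(1))
  unname(d)
}
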