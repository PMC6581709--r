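#' Schematic hand template with 24 stimulation sites
#'
#' The assessment is defined on a schematic volar (palmar) view of the hand:
#' a simple polygon outline plus 24 labeled stimulation sites. Sites 1--4 lie
#' on digit I (thumb: distal phalanx, proximal phalanx, distal and proximal
#' metacarpal), sites 5--8, 9--12, 13--16 and 17--20 on digits II--V (distal,
#' intermediate and proximal phalanx plus distal metacarpal), and sites
#' 21--24 on the palm. Template units are millimetres on a reference hand of
#' length 17 cm, measured from the tip of digit III to the wrist crease.
#' The coordinate origin is the wrist-crease midpoint, y increases distally
#' (fingertips up) and x increases toward the thumb on a right hand; the left
#' template is the mirror image about the vertical axis.
#'
#' @param side `"left"` or `"right"`.
#' @return An object of class `hand_template`: a list with elements
#'   * `version` -- template geometry version string,
#'   * `side` -- `"left"` or `"right"`,
#'   * `outline` -- n x 2 matrix, counter-clockwise simple polygon,
#'   * `sites` -- tibble with columns `site_id`, `digit`, `segment`,
#'     `distal_rank`, `x`, `y`,
#'   * `hand_length` -- template-unit length from digit III tip to wrist
#'     crease (170 on the reference hand),
#'   * `units_per_cm` -- scale factor from template units to centimetres
#'     (10 on the reference hand, so `hand_length / units_per_cm == 17`).
#' @examples
#' tpl <- default_hand_template("left")
#' nrow(tpl$sites)
#' @export
default_hand_template <- function(side = c("right", "left")) {
  side <- match.arg(side)
  tpl <- .hand_template_right()
  if (side == "left") tpl <- mirror_template(tpl)
  tpl
}

# Reference right-hand geometry, version "1.0". All constants in mm on the
# 17 cm hand. Fingers are tapered lobes separated by concave web notches;
# the thumb is an abducted lobe on the radial palm edge.
.hand_template_right <- function() {
  # thumb axis: 40 degrees from +x, base centre C, length 52, half-width 8.5
  C <- c(41, 40)
  u <- c(cos(40 * pi / 180), sin(40 * pi / 180))
  nv <- c(-u[2], u[1])
  t_tip <- C + 52 * u
  outline <- rbind(
    c(42, 0),                      # wrist, radial corner
    c(44, 22),                     # radial palm edge
    C - 8.5 * nv,                  # thumb base, proximal corner
    t_tip - 6 * nv,                # thumb tip shoulder (proximal)
    t_tip + 3 * u,                 # thumb apex
    t_tip + 6 * nv,                # thumb tip shoulder (distal)
    C + 8.5 * nv,                  # thumb-index web notch (reflex)
    c(36, 92),                     # index base, radial side
    c(33, 158), c(28.5, 163), c(24, 158),   # digit II tip
    c(19, 88),                     # II-III web notch
    c(14, 165), c(9.5, 170), c(5, 165),     # digit III tip
    c(0, 88),                      # III-IV web notch
    c(-5, 160), c(-9.5, 165), c(-14, 160),  # digit IV tip
    c(-19, 88),                    # IV-V web notch
    c(-24, 143), c(-28.5, 148), c(-33, 143),# digit V tip
    c(-36, 92),                    # little-finger base, ulnar side
    c(-44, 40),                    # ulnar palm edge
    c(-42, 10),
    c(-42, 0)                      # wrist, ulnar corner
  )
  colnames(outline) <- NULL
  finger_segments <- c("distal_phalanx", "intermediate_phalanx",
                       "proximal_phalanx", "distal_metacarpal")
  thumb_segments <- c("distal_phalanx", "proximal_phalanx",
                      "distal_metacarpal", "proximal_metacarpal")
  thumb_pos <- rbind(C + 44 * u, C + 26 * u, C + 8 * u, C - 10 * u)
  sites <- tibble::tibble(
    site_id = 1:24,
    digit = rep(c("I", "II", "III", "IV", "V", "palm"), each = 4),
    segment = c(thumb_segments, rep(finger_segments, 4),
                rep("palm", 4)),
    distal_rank = c(rep(0:3, 5), c(4L, 4L, 4L, 5L)),
    x = c(thumb_pos[, 1],
          28.5, 28, 28, 28,        # digit II
          9.5, 9.5, 9.5, 9.5,      # digit III
          -9.5, -9.5, -9.5, -9.5,  # digit IV
          -28.5, -28, -28, -28,    # digit V
          24, 2, -26, 0),          # palm: thenar, centre, hypothenar, proximal
    y = c(thumb_pos[, 2],
          153, 130, 103, 78,
          160, 135, 105, 80,
          155, 132, 104, 80,
          139, 120, 98, 78,
          30, 55, 38, 15)
  )
  new_hand_template(
    version = "1.0", side = "right", outline = outline, sites = sites,
    hand_length = 170, units_per_cm = 10
  )
}

#' @noRd
new_hand_template <- function(version, side, outline, sites, hand_length,
                              units_per_cm) {
  if (!poly_is_ccw(outline)) outline <- outline[rev(seq_len(nrow(outline))), ]
  tpl <- structure(
    list(version = version, side = side, outline = outline, sites = sites,
         hand_length = hand_length, units_per_cm = units_per_cm),
    class = "hand_template"
  )
  validate_hand_template(tpl)
  tpl
}

#' Validate a hand template
#'
#' Checks all structural invariants: a simple counter-clockwise outline with
#' at least 3 vertices, exactly 24 sites with the canonical digit/segment
#' layout, all site positions strictly inside the outline, and a positive
#' hand length.
#'
#' @param template a `hand_template`.
#' @return `template`, invisibly; errors on any violation.
#' @export
validate_hand_template <- function(template) {
  stopifnot(inherits(template, "hand_template"))
  out <- template$outline
  if (!is.matrix(out) || nrow(out) < 3) stop("outline must have >= 3 vertices")
  if (!poly_is_simple(out)) stop("outline polygon is self-intersecting")
  if (!poly_is_ccw(out)) stop("outline must be counter-clockwise")
  s <- template$sites
  if (nrow(s) != 24 || !identical(sort(s$site_id), 1:24)) {
    stop("template must define exactly the 24 sites with ids 1..24")
  }
  expected_digit <- rep(c("I", "II", "III", "IV", "V", "palm"), each = 4)
  if (!identical(s$digit[order(s$site_id)], expected_digit)) {
    stop("site ids 1-4 must be digit I, 5-8 II, 9-12 III, 13-16 IV, ",
         "17-20 V, 21-24 palm")
  }
  if (!all(point_in_polygon(out, cbind(s$x, s$y)))) {
    stop("all site positions must lie inside the outline")
  }
  if (!is.numeric(template$hand_length) || template$hand_length <= 0) {
    stop("hand_length must be positive")
  }
  if (template$units_per_cm <= 0) stop("units_per_cm must be positive")
  invisible(template)
}

#' Mirror a hand template about the vertical axis
#'
#' Converts a right template into its left counterpart and vice versa by
#' negating x coordinates (outline orientation is restored to
#' counter-clockwise).
#'
#' @param template a `hand_template`.
#' @return the mirrored `hand_template`.
#' @export
mirror_template <- function(template) {
  out <- template$outline
  out[, 1] <- -out[, 1]
  sites <- template$sites
  sites$x <- -sites$x
  new_hand_template(
    version = template$version,
    side = if (template$side == "right") "left" else "right",
    outline = out, sites = sites,
    hand_length = template$hand_length,
    units_per_cm = template$units_per_cm
  )
}

#' Rescale a template to a subject's measured hand length
#'
#' Distances are computed in template units and converted to centimetres via
#' `units_per_cm`. For a subject whose hand (digit III tip to wrist crease)
#' measures `hand_length_cm`, the same template drawing maps to a different
#' physical scale; this adjusts `units_per_cm` so converted distances are the
#' subject's physical centimetres. Normalizing results back to the 17 cm
#' reference hand is a separate multiplicative step in the metrics layer.
#'
#' @param template a `hand_template`.
#' @param hand_length_cm measured hand length in cm, positive.
#' @return the rescaled `hand_template`.
#' @export
scale_to_hand <- function(template, hand_length_cm) {
  if (!is.numeric(hand_length_cm) || length(hand_length_cm) != 1 ||
      !is.finite(hand_length_cm) || hand_length_cm <= 0) {
    stop("hand_length_cm must be a single positive number")
  }
  template$units_per_cm <- template$hand_length / hand_length_cm
  template
}

#' Test whether points lie on the hand
#'
#' Boundary points count as inside (the outline is a closed set).
#'
#' @param template a `hand_template`.
#' @param pts a length-2 numeric vector or an m x 2 matrix of points in
#'   template coordinates.
#' @return logical vector, one entry per point.
#' @export
hand_contains <- function(template, pts) {
  point_in_polygon(template$outline, rbind(pts))
}

#' Clamp points into the hand outline
#'
#' Points already inside (or on) the outline are returned unchanged; outside
#' points are replaced by the Euclidean-nearest point on the boundary. The
#' operation is idempotent. Touchscreen responses occasionally fall just off
#' the drawn hand; metrics clamp them before computing geodesic errors.
#'
#' @inheritParams hand_contains
#' @return an m x 2 matrix of clamped points.
#' @export
clamp_to_hand <- function(template, pts) {
  pts <- rbind(pts)
  inside <- point_in_polygon(template$outline, pts)
  if (any(!inside)) {
    pts[!inside, ] <- closest_boundary_point(template$outline,
                                             pts[!inside, , drop = FALSE])
  }
  pts
}

#' Hand length of a template in centimetres
#' @param template a `hand_template`.
#' @return hand length in cm (17 for the unscaled reference template).
#' @export
hand_length_cm <- function(template) {
  template$hand_length / template$units_per_cm
}

#' @export
print.hand_template <- function(x, ...) {
  cat(sprintf(
    "<hand_template v%s, %s hand: %d outline vertices, %d sites, hand length %.1f cm>\n",
    x$version, x$side, nrow(x$outline), nrow(x$sites), hand_length_cm(x)
  ))
  invisible(x)
}

#' Read / write a hand template as JSON
#'
#' The on-disk format is a JSON document with fields `version`, `side`,
#' `units_per_cm`, `hand_length`, `outline` (array of `[x, y]` pairs) and
#' `sites` (array of objects with `site_id`, `digit`, `segment`, `position`,
#' `distal_rank`). All template invariants are validated on read.
#'
#' @param path file path.
#' @return `read_hand_template()` returns a validated `hand_template`.
#' @export
read_hand_template <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  sites <- tibble::as_tibble(doc$sites)
  pos <- do.call(rbind, if (is.list(doc$sites$position)) doc$sites$position
                 else asplit(doc$sites$position, 1))
  sites$position <- NULL
  sites$x <- pos[, 1]
  sites$y <- pos[, 2]
  sites <- sites[order(sites$site_id),
                 c("site_id", "digit", "segment", "distal_rank", "x", "y")]
  sites$site_id <- as.integer(sites$site_id)
  sites$distal_rank <- as.integer(sites$distal_rank)
  new_hand_template(
    version = doc$version, side = doc$side,
    outline = matrix(unlist(doc$outline), ncol = 2, byrow = !is.matrix(doc$outline)),
    sites = sites,
    hand_length = doc$hand_length, units_per_cm = doc$units_per_cm
  )
}

#' @rdname read_hand_template
#' @param template a `hand_template` to serialize.
#' @export
write_hand_template <- function(template, path) {
  s <- template$sites
  doc <- list(
    version = template$version,
    side = template$side,
    units_per_cm = template$units_per_cm,
    hand_length = template$hand_length,
    outline = unname(asplit(template$outline, 1)),
    sites = lapply(seq_len(nrow(s)), function(i) {
      list(site_id = s$site_id[i], digit = s$digit[i], segment = s$segment[i],
           position = c(s$x[i], s$y[i]), distal_rank = s$distal_rank[i])
    })
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

# site position as a length-2 vector
site_position <- function(template, site_id) {
  i <- match(site_id, template$sites$site_id)
  if (any(is.na(i))) stop("unknown site_id: ", paste(site_id[is.na(i)], collapse = ", "))
  cbind(template$sites$x[i], template$sites$y[i])
}

# fingertip sites: distal phalanges of digits I-V
fingertip_sites <- function() c(1L, 5L, 9L, 13L, 17L)
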