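# Graphics: distortion maps and confusion-matrix heatmaps.
#
# The distortion map draws the hand outline with a thick black circle at each
# stimulation site, an arrow from the site to the centre of its responses
# (arrow length ~ offset), and a semitransparent circle around the arrow head
# whose radius equals the spread. Sites are coloured yellow (distal) to blue
# (proximal). Arrows are straight segments even though the offset itself is
# geodesic, so an arrow's drawn length is a lower bound on the offset value.

.distal_palette <- function(ranks) {
  pal <- grDevices::colorRampPalette(c("#FFD700", "#2166AC"))(max(ranks) + 1)
  pal[ranks + 1]
}

# circle polygon helper for spread circles (ggplot has no native circle geom
# in data units)
.circle_df <- function(cx, cy, r, id, n = 72) {
  th <- seq(0, 2 * pi, length.out = n + 1)
  tibble::tibble(
    x = rep(cx, each = n + 1) + rep(r, each = n + 1) * cos(th),
    y = rep(cy, each = n + 1) + rep(r, each = n + 1) * sin(th),
    id = rep(id, each = n + 1)
  )
}

#' Distortion map of an assessment summary
#'
#' @param summary an `assessment_summary` (see [summarize_session()]).
#' @param template the `hand_template` the session was scored on; defaults to
#'   the summary's side.
#' @param show_spread_circles draw semitransparent circles of radius equal to
#'   the spread around each arrow endpoint (default `TRUE`).
#' @param curved_arrows draw arrows along the geodesic path instead of as
#'   straight segments (off by default, matching the conventional rendering).
#' @return a `ggplot` object.
#' @export
plot_distortion_map <- function(summary, template = NULL,
                                show_spread_circles = TRUE,
                                curved_arrows = FALSE) {
  if (is.null(template)) template <- default_hand_template(summary$side)
  upc <- template$units_per_cm
  # summary lengths may be normalized to the 17 cm hand; undo for drawing in
  # template units so the map overlays the template geometry
  denorm <- if (summary$normalized) summary$hand_length_cm / 17 else 1
  ps <- summary$per_site
  ps <- ps[!is.na(ps$offset_cm), ]
  ps$col <- .distal_palette(template$sites$distal_rank[
    match(ps$site_id, template$sites$site_id)])
  ps$site_x <- template$sites$x[match(ps$site_id, template$sites$site_id)]
  ps$site_y <- template$sites$y[match(ps$site_id, template$sites$site_id)]
  outline <- tibble::as_tibble(as.data.frame(template$outline))
  names(outline) <- c("x", "y")
  g <- ggplot2::ggplot() +
    ggplot2::geom_polygon(data = outline, ggplot2::aes(x = .data$x, y = .data$y),
                          fill = "grey97", colour = "grey30", linewidth = 0.6) +
    ggplot2::coord_fixed() +
    ggplot2::theme_void()
  if (show_spread_circles && nrow(ps)) {
    circles <- .circle_df(ps$center_x, ps$center_y,
                          ps$spread_cm * denorm * upc, ps$site_id)
    circles$col <- ps$col[match(circles$id, ps$site_id)]
    g <- g + ggplot2::geom_polygon(
      data = circles,
      ggplot2::aes(x = .data$x, y = .data$y, group = .data$id,
                   fill = .data$col),
      alpha = 0.25, colour = NA
    ) + ggplot2::scale_fill_identity()
  }
  if (nrow(ps)) {
    if (curved_arrows) {
      segs <- purrr::map_dfr(seq_len(nrow(ps)), function(i) {
        wp <- geodesic_path(template, c(ps$site_x[i], ps$site_y[i]),
                            c(ps$center_x[i], ps$center_y[i]))$waypoints
        tibble::tibble(x = wp[-nrow(wp), 1], y = wp[-nrow(wp), 2],
                       xend = wp[-1, 1], yend = wp[-1, 2],
                       col = ps$col[i],
                       last = seq_len(nrow(wp) - 1) == nrow(wp) - 1)
      })
    } else {
      segs <- tibble::tibble(x = ps$site_x, y = ps$site_y,
                             xend = ps$center_x, yend = ps$center_y,
                             col = ps$col, last = TRUE)
    }
    moved <- (segs$x - segs$xend)^2 + (segs$y - segs$yend)^2 > 1e-12
    g <- g +
      ggplot2::geom_segment(
        data = segs[moved & segs$last, ],
        ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend,
                     yend = .data$yend, colour = .data$col),
        arrow = ggplot2::arrow(length = ggplot2::unit(2, "mm"),
                               type = "closed"),
        linewidth = 0.5
      ) +
      ggplot2::geom_segment(
        data = segs[moved & !segs$last, ],
        ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend,
                     yend = .data$yend, colour = .data$col),
        linewidth = 0.5
      )
  }
  g + ggplot2::geom_point(
    data = ps, ggplot2::aes(x = .data$site_x, y = .data$site_y),
    shape = 21, size = 2.6, stroke = 1.1, colour = "black", fill = NA
  ) +
    ggplot2::scale_colour_identity()
}

#' @method autoplot assessment_summary
#' @export
autoplot.assessment_summary <- function(object, ...) {
  plot_distortion_map(object, ...)
}

#' Confusion-matrix heatmap
#'
#' 24 x 24 heatmap of row percentages (stimulated site on the y axis, top to
#' bottom; discretized perceived site on the x axis), with grid lines after
#' sites 4, 8, 12, 16 and 20 delimiting the five digits and the palm block.
#'
#' @param cm a [confusion_matrix()].
#' @param annotate_row_n append the number of responses per row to the y
#'   axis labels.
#' @return a `ggplot` object.
#' @export
plot_confusion_heatmap <- function(cm, annotate_row_n = FALSE) {
  df <- tidy.confusion_matrix(cm)
  ylab <- if (annotate_row_n) {
    sprintf("%d (n=%d)", 1:24, cm$row_n)
  } else {
    as.character(1:24)
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$perceived, y = .data$stimulated,
                                   fill = .data$percent)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "grey10",
                                 limits = c(0, 100), na.value = "white",
                                 name = "%") +
    ggplot2::scale_y_reverse(breaks = 1:24, labels = ylab, expand = c(0, 0)) +
    ggplot2::scale_x_continuous(breaks = 1:24, expand = c(0, 0),
                                position = "top") +
    ggplot2::geom_hline(yintercept = c(4, 8, 12, 16, 20) + 0.5,
                        colour = "grey40", linewidth = 0.4) +
    ggplot2::geom_vline(xintercept = c(4, 8, 12, 16, 20) + 0.5,
                        colour = "grey40", linewidth = 0.4) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "perceived location", y = "stimulated location") +
    ggplot2::theme_minimal() +
    ggplot2::theme(panel.grid = ggplot2::element_blank(),
                   axis.text = ggplot2::element_text(size = 6))
}

#' @method autoplot confusion_matrix
#' @export
autoplot.confusion_matrix <- function(object, ...) {
  plot_confusion_heatmap(object, ...)
}

#' Render a plot to an SVG or PNG file
#'
#' Thin wrapper around the base graphics devices so figures can be written
#' without knitting; the format follows the file extension. SVG output
#' requires cairo support in the R build (PNG is always available).
#'
#' @param plot a `ggplot` object.
#' @param path output path ending in `.svg` or `.png`.
#' @param width,height device size in inches.
#' @param dpi resolution for PNG.
#' @return `path`, invisibly.
#' @export
render_plot <- function(plot, path, width = 6, height = 7, dpi = 150) {
  if (grepl("\\.svg$", path, ignore.case = TRUE)) {
    grDevices::svg(path, width = width, height = height)
  } else if (grepl("\\.png$", path, ignore.case = TRUE)) {
    grDevices::png(path, width = width * dpi, height = height * dpi, res = dpi)
  } else {
    stop("unsupported image format (use .svg or .png): ", path)
  }
  on.exit(grDevices::dev.off())
  print(plot)
  invisible(path)
}
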