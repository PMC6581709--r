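#' Response center
#'
#' The per-site "center of the reported coordinates" is the arithmetic
#' centroid of the responses. Because the centroid of points on two different
#' fingers can fall in the web notch outside the hand, a centroid outside the
#' outline is clamped to the nearest boundary point so downstream geodesic
#' computations stay defined. A geodesic (Fréchet) mean is available as an
#' alternative but is not the default.
#'
#' @param points m x 2 matrix of response points (template coordinates),
#'   m >= 1, all inside the outline.
#' @param template a `hand_template`.
#' @param method `"centroid"` (default) or `"geodesic_mean"` (point among a
#'   candidate grid of the responses minimizing summed geodesic distance;
#'   deterministic, ties to the first candidate).
#' @return length-2 numeric vector inside the hand.
#' @export
response_center <- function(points, template,
                            method = c("centroid", "geodesic_mean")) {
  method <- match.arg(method)
  points <- rbind(points)
  if (nrow(points) == 0) stop("response_center: no responses (undefined metric)")
  if (method == "centroid") {
    ctr <- colMeans(points)
    return(as.numeric(clamp_to_hand(template, ctr)))
  }
  # geodesic mean over candidates: the clamped centroid plus the responses
  cand <- rbind(as.numeric(clamp_to_hand(template, colMeans(points))), points)
  cost <- vapply(seq_len(nrow(cand)), function(i) {
    sum(vapply(seq_len(nrow(points)), function(j) {
      geodesic_distance(template, cand[i, ], points[j, ])
    }, numeric(1)))
  }, numeric(1))
  as.numeric(cand[which.min(cost), ])
}

# cm conversion helper; normalization to the 17 cm reference hand is a
# separate factor applied by the caller
.units_to_cm <- function(x, template) x / template$units_per_cm

#' Per-site localization error metrics
#'
#' Three outcome measures per stimulation site, all based on geodesic
#' (within-hand shortest-path) lengths:
#' * **offset** -- geodesic error of the response center relative to the
#'   stimulation site (accuracy of the average percept),
#' * **spread** -- mean geodesic distance of the responses from their center
#'   (precision),
#' * **distance** -- mean geodesic error of the individual responses relative
#'   to the stimulation site (accuracy per trial).
#'
#' @param responses m x 2 matrix of reported points, m >= 1, inside the hand.
#' @param site_id stimulation site id (1--24).
#' @param template a `hand_template`.
#' @param center optional pre-computed response center.
#' @return length in cm (template scale; apply the 17-cm normalization
#'   factor separately if normalized reporting is wanted).
#' @export
location_offset <- function(responses, site_id, template, center = NULL) {
  if (is.null(center)) center <- response_center(responses, template)
  d <- geodesic_distance(template, site_position(template, site_id), center)
  .units_to_cm(d, template)
}

#' @rdname location_offset
#' @export
location_spread <- function(responses, site_id, template, center = NULL) {
  responses <- rbind(responses)
  if (is.null(center)) center <- response_center(responses, template)
  d <- vapply(seq_len(nrow(responses)), function(i) {
    geodesic_distance(template, responses[i, ], center)
  }, numeric(1))
  .units_to_cm(mean(d), template)
}

#' @rdname location_offset
#' @export
location_distance <- function(responses, site_id, template) {
  responses <- rbind(responses)
  pos <- as.numeric(site_position(template, site_id))
  d <- vapply(seq_len(nrow(responses)), function(i) {
    geodesic_distance(template, responses[i, ], pos)
  }, numeric(1))
  .units_to_cm(mean(d), template)
}

#' Confusion matrix of discretized perceived locations
#'
#' Every non-missing response is discretized to the nearest stimulation site
#' (geodesic distance by default, consistent with the error metrics; ties go
#' to the lowest site id). Rows are the stimulated sites, columns the
#' discretized perceived sites, entries row percentages over the non-missing
#' responses of that row. Missing responses are counted per row and excluded
#' from percentages; rows without responses are all-`NA`.
#'
#' @param session a `tactile_session`; responses outside the outline are
#'   clamped onto it first.
#' @param template a `hand_template`; defaults to the session's side.
#' @param method `"geodesic"` (default) or `"euclidean"` nearest-site rule.
#' @return an object of class `confusion_matrix`: list with `percent`
#'   (24 x 24 matrix), `counts`, `row_n` (responses per row), `row_missing`.
#' @export
confusion_matrix <- function(session, template = NULL,
                             method = c("geodesic", "euclidean")) {
  method <- match.arg(method)
  if (is.null(template)) template <- default_hand_template(session$side)
  t <- session$trials
  counts <- matrix(0L, 24, 24, dimnames = list(stimulated = 1:24,
                                               perceived = 1:24))
  row_missing <- stats::setNames(integer(24), 1:24)
  sites_xy <- site_position(template, 1:24)
  resp <- t[!t$missing, ]
  if (nrow(resp)) {
    pts <- clamp_to_hand(template, cbind(resp$resp_x, resp$resp_y))
    for (i in seq_len(nrow(resp))) {
      d <- if (method == "geodesic") {
        geodesic_to_sites(template, pts[i, ])
      } else {
        sqrt((sites_xy[, 1] - pts[i, 1])^2 + (sites_xy[, 2] - pts[i, 2])^2)
      }
      nearest <- which.min(d) # which.min takes the first (lowest id) on ties
      counts[resp$site_id[i], nearest] <- counts[resp$site_id[i], nearest] + 1L
    }
  }
  for (s in t$site_id[t$missing]) row_missing[s] <- row_missing[s] + 1L
  row_n <- rowSums(counts)
  percent <- counts / row_n * 100
  percent[row_n == 0, ] <- NA_real_
  structure(list(percent = percent, counts = counts, row_n = row_n,
                 row_missing = row_missing, method = method),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("<confusion_matrix: %d responses, %d missing, %s nearest-site rule>\n",
              sum(x$row_n), sum(x$row_missing), x$method))
  cat(sprintf("  diagonal mean (CLR): %.1f%%\n",
              correct_localization_rate(x)$mean))
  invisible(x)
}

#' @method tidy confusion_matrix
#' @export
tidy.confusion_matrix <- function(x, ...) {
  tibble::tibble(
    stimulated = rep(1:24, times = 24),
    perceived = rep(1:24, each = 24),
    percent = as.vector(x$percent),
    count = as.vector(x$counts)
  )
}

#' Correct localization rate
#'
#' Mean (and SD across sites) of the confusion-matrix diagonal: the
#' percentage of responses discretized back to the stimulated site. The
#' fingertip subset uses the distal phalanges of the five digits, sites
#' 1, 5, 9, 13 and 17. Sites without responses are excluded.
#'
#' @param cm a [confusion_matrix()].
#' @param subset site ids to average over (default all 24); must be non-empty.
#' @return list with `mean`, `sd`, `per_site` (named diagonal values), `n_sites`.
#' @export
correct_localization_rate <- function(cm, subset = 1:24) {
  subset <- as.integer(subset)
  if (!length(subset) || !all(subset %in% 1:24)) {
    stop("subset must be a non-empty set of site ids in 1..24")
  }
  diagv <- diag(cm$percent)[subset]
  ok <- !is.na(diagv)
  list(mean = mean(diagv[ok]),
       sd = stats::sd(diagv[ok]),
       per_site = stats::setNames(diagv, subset),
       n_sites = sum(ok))
}

#' Summarize a session into per-site outcomes and hand-level means
#'
#' Computes offset, spread, distance and the correct-localization-rate
#' diagonal per stimulation site, plus means and SDs across the sites with at
#' least one response. With `normalize = TRUE` (the reporting convention) all
#' lengths are additionally multiplied by `17 / hand_length_cm` so hands of
#' different size are comparable on the 17 cm reference hand. SDs are sample
#' SDs across sites.
#'
#' @param session a `tactile_session`.
#' @param template a `hand_template`; defaults to the session's side.
#' @param normalize normalize lengths to the 17 cm reference hand
#'   (default `TRUE`).
#' @param center_method passed to [response_center()].
#' @param discretize_method passed to [confusion_matrix()].
#' @return an `assessment_summary`: list with `per_site` tibble (`site_id`,
#'   `digit`, `segment`, `n_responses`, `n_missing`, `center_x`, `center_y`,
#'   `offset_cm`, `spread_cm`, `distance_cm`, `clr_pct`), the
#'   `confusion_matrix`, scalar means/SDs, `n_missing`, and flags.
#' @export
summarize_session <- function(session, template = NULL, normalize = TRUE,
                              center_method = "centroid",
                              discretize_method = "geodesic") {
  if (is.null(template)) template <- default_hand_template(session$side)
  norm_factor <- if (normalize) 17 / session$hand_length_cm else 1
  t <- session$trials
  cm <- confusion_matrix(session, template, method = discretize_method)
  per_site <- purrr::map_dfr(1:24, function(s) {
    rows <- t[t$site_id == s & !t$missing, ]
    n_miss <- sum(t$site_id == s & t$missing)
    base <- tibble::tibble(
      site_id = s,
      digit = template$sites$digit[template$sites$site_id == s],
      segment = template$sites$segment[template$sites$site_id == s],
      n_responses = nrow(rows), n_missing = n_miss
    )
    if (nrow(rows) == 0) {
      return(dplyr::mutate(base, center_x = NA_real_, center_y = NA_real_,
                           offset_cm = NA_real_, spread_cm = NA_real_,
                           distance_cm = NA_real_, clr_pct = NA_real_))
    }
    pts <- clamp_to_hand(template, cbind(rows$resp_x, rows$resp_y))
    ctr <- response_center(pts, template, method = center_method)
    dplyr::mutate(
      base,
      center_x = ctr[1], center_y = ctr[2],
      offset_cm = location_offset(pts, s, template, center = ctr) * norm_factor,
      spread_cm = location_spread(pts, s, template, center = ctr) * norm_factor,
      distance_cm = location_distance(pts, s, template) * norm_factor,
      clr_pct = cm$percent[s, s]
    )
  })
  agg <- function(x) {
    x <- x[!is.na(x)]
    c(mean = mean(x), sd = stats::sd(x))
  }
  structure(
    list(per_site = per_site, confusion = cm,
         mean_offset_cm = agg(per_site$offset_cm),
         mean_spread_cm = agg(per_site$spread_cm),
         mean_distance_cm = agg(per_site$distance_cm),
         mean_clr_pct = agg(per_site$clr_pct),
         n_missing = sum(t$missing),
         n_trials = nrow(t),
         normalized = normalize,
         subject_id = session$subject_id, side = session$side,
         hand_length_cm = session$hand_length_cm,
         template_version = template$version),
    class = "assessment_summary"
  )
}

#' @export
print.assessment_summary <- function(x, ...) {
  cat(sprintf("<assessment_summary %s, %s hand: %d trials, %d missing%s>\n",
              x$subject_id, x$side, x$n_trials, x$n_missing,
              if (x$normalized) ", normalized to 17 cm hand" else ""))
  cat(sprintf("  mean offset   %4.1f ± %.1f cm\n",
              x$mean_offset_cm["mean"], x$mean_offset_cm["sd"]))
  cat(sprintf("  mean spread   %4.1f ± %.1f cm\n",
              x$mean_spread_cm["mean"], x$mean_spread_cm["sd"]))
  cat(sprintf("  mean distance %4.1f ± %.1f cm\n",
              x$mean_distance_cm["mean"], x$mean_distance_cm["sd"]))
  cat(sprintf("  mean CLR      %4.1f ± %.1f %%\n",
              x$mean_clr_pct["mean"], x$mean_clr_pct["sd"]))
  invisible(x)
}

#' @method tidy assessment_summary
#' @export
tidy.assessment_summary <- function(x, ...) x$per_site

#' @method glance assessment_summary
#' @export
glance.assessment_summary <- function(x, ...) {
  tibble::tibble(
    subject_id = x$subject_id, side = x$side,
    n_trials = x$n_trials, n_missing = x$n_missing,
    mean_offset_cm = unname(x$mean_offset_cm["mean"]),
    sd_offset_cm = unname(x$mean_offset_cm["sd"]),
    mean_spread_cm = unname(x$mean_spread_cm["mean"]),
    sd_spread_cm = unname(x$mean_spread_cm["sd"]),
    mean_distance_cm = unname(x$mean_distance_cm["mean"]),
    sd_distance_cm = unname(x$mean_distance_cm["sd"]),
    mean_clr_pct = unname(x$mean_clr_pct["mean"]),
    sd_clr_pct = unname(x$mean_clr_pct["sd"]),
    normalized = x$normalized
  )
}

#' Aggregate per-site metric values the way the report table does
#'
#' Takes per-site values (e.g. 24 offsets in cm) and returns their arithmetic
#' mean and sample SD, plus the same rounded to one decimal, the convention
#' used for printed report rows. `NA` sites are dropped.
#'
#' @param values numeric vector of per-site metric values.
#' @return tibble with columns `mean`, `sd`, `mean_1dp`, `sd_1dp`, `n`.
#' @export
aggregate_site_values <- function(values) {
  v <- values[!is.na(values)]
  tibble::tibble(mean = mean(v), sd = stats::sd(v),
                 mean_1dp = round(mean(v), 1), sd_1dp = round(stats::sd(v), 1),
                 n = length(v))
}

#' Export a summary / confusion matrix to files
#'
#' `write_summary()` writes the per-site table with appended mean/SD rows as
#' CSV, or the full summary as JSON, by extension. `write_confusion()` writes
#' the 24 x 24 percentage matrix with a `row_n` column as CSV.
#'
#' @param summary an `assessment_summary`.
#' @param path output path (`.csv` or `.json`).
#' @return the path, invisibly.
#' @export
write_summary <- function(summary, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    out <- list(
      subject_id = summary$subject_id, side = summary$side,
      normalized = summary$normalized, n_trials = summary$n_trials,
      n_missing = summary$n_missing,
      per_site = summary$per_site,
      mean_offset_cm = as.list(summary$mean_offset_cm),
      mean_spread_cm = as.list(summary$mean_spread_cm),
      mean_distance_cm = as.list(summary$mean_distance_cm),
      mean_clr_pct = as.list(summary$mean_clr_pct)
    )
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, na = "null")
  } else {
    tab <- summary$per_site
    means <- tibble::tibble(
      site_id = NA_integer_, digit = c("mean", "sd"), segment = "",
      n_responses = NA_integer_, n_missing = NA_integer_,
      center_x = NA_real_, center_y = NA_real_,
      offset_cm = c(summary$mean_offset_cm),
      spread_cm = c(summary$mean_spread_cm),
      distance_cm = c(summary$mean_distance_cm),
      clr_pct = c(summary$mean_clr_pct)
    )
    readr::write_csv(dplyr::bind_rows(tab, means), path, na = "")
  }
  invisible(path)
}

#' @rdname write_summary
#' @param cm a `confusion_matrix`.
#' @export
write_confusion <- function(cm, path) {
  df <- as.data.frame(cm$percent)
  names(df) <- paste0("perceived_", 1:24)
  df <- cbind(stimulated = 1:24, df, row_n = cm$row_n,
              row_missing = cm$row_missing)
  readr::write_csv(tibble::as_tibble(df), path, na = "")
  invisible(path)
}
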