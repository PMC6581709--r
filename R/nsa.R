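#' Score the NSA localization subscale
#'
#' The clinical localization test (Nottingham Sensory Assessment subscale)
#' probes six hand locations three times each; a repetition is correct when
#' the indicated location is within 2 cm of the stimulus. Each location is
#' rated 0 (absent: incorrect on all three repetitions), 1 (impaired: correct
#' on some repetitions) or 2 (normal: correct on all three); the hand total
#' ranges 0--12.
#'
#' @param correct a 6 x 3 logical matrix (rows = locations, columns =
#'   repetitions) of per-repetition correctness, with optional rownames, or a
#'   data frame with a `location` column and three logical repetition
#'   columns.
#' @return an `nsa_score`: list with `per_location` (tibble: `location`,
#'   `n_correct`, `score`) and `total`.
#' @examples
#' m <- matrix(TRUE, 6, 3)
#' m[2, ] <- FALSE                # absent at one location
#' m[3, 1] <- FALSE               # impaired at another
#' nsa_localization_score(m)$total
#' @export
nsa_localization_score <- function(correct) {
  if (is.data.frame(correct)) {
    loc <- if ("location" %in% names(correct)) correct$location else NULL
    correct <- as.matrix(correct[vapply(correct, is.logical, logical(1))])
    rownames(correct) <- loc
  }
  if (!is.matrix(correct) || !identical(dim(correct), c(6L, 3L)) ||
      !is.logical(correct) || anyNA(correct)) {
    stop("correct must be a complete 6 x 3 logical matrix ",
         "(6 locations x 3 repetitions)")
  }
  n_correct <- unname(rowSums(correct))
  score <- ifelse(n_correct == 3, 2L, ifelse(n_correct >= 1, 1L, 0L))
  loc <- rownames(correct) %||% nsa_locations()$location
  structure(
    list(per_location = tibble::tibble(location = loc,
                                       n_correct = as.integer(n_correct),
                                       score = score),
         total = sum(score)),
    class = "nsa_score"
  )
}

#' @export
print.nsa_score <- function(x, ...) {
  cat("<nsa_score>\n")
  for (i in seq_len(nrow(x$per_location))) {
    cat(sprintf("  %-26s %d/3 correct -> %d\n", x$per_location$location[i],
                x$per_location$n_correct[i], x$per_location$score[i]))
  }
  cat(sprintf("  Total %d / 12\n", x$total))
  invisible(x)
}

#' @method tidy nsa_score
#' @export
tidy.nsa_score <- function(x, ...) x$per_location

#' Reconstruct an NSA score object from per-location ratings
#'
#' For report tables that publish only the six 0/1/2 ratings per hand. A
#' rating of 1 ("correct for some of the three repetitions") is represented
#' as one correct repetition; the total is unaffected by that choice.
#'
#' @param scores integer vector of six per-location ratings in 0..2, ordered
#'   as [nsa_locations()].
#' @return an `nsa_score`.
#' @export
nsa_score_from_ratings <- function(scores) {
  scores <- as.integer(scores)
  if (length(scores) != 6 || anyNA(scores) || any(scores < 0 | scores > 2)) {
    stop("scores must be six integers in 0..2")
  }
  correct <- t(vapply(scores, function(s) {
    c(s >= 1, s >= 2, s >= 2)
  }, logical(3)))
  rownames(correct) <- nsa_locations()$location
  nsa_localization_score(correct)
}

#' Cross-walk: score the NSA subscale from an automated session
#'
#' Maps the six clinical locations onto the template, takes the first three
#' responses recorded at each mapped site, marks a repetition correct when
#' its geodesic error is at most `tolerance_cm` (the clinical 2 cm allowance),
#' and applies the 0/1/2 rule. Missing trials count as incorrect repetitions.
#'
#' @param session a `tactile_session`.
#' @param template a `hand_template`; defaults to the session's side.
#' @param tolerance_cm allowed localization error, cm (default 2).
#' @return an `nsa_score`.
#' @export
nsa_from_session <- function(session, template = NULL, tolerance_cm = 2) {
  if (is.null(template)) template <- default_hand_template(session$side)
  locs <- nsa_locations(template)
  t <- session$trials
  short <- character(0)
  correct <- matrix(FALSE, 6, 3, dimnames = list(locs$location, NULL))
  for (i in seq_len(6)) {
    rows <- t[t$site_id == locs$site_id[i], ]
    if (nrow(rows) < 3) {
      short <- c(short, locs$location[i])
      next
    }
    rows <- rows[1:3, ]
    for (r in 1:3) {
      if (rows$missing[r]) next
      p <- clamp_to_hand(template, c(rows$resp_x[r], rows$resp_y[r]))
      err_cm <- geodesic_distance(template, c(locs$x[i], locs$y[i]),
                                  as.numeric(p)) / template$units_per_cm
      correct[i, r] <- err_cm <= tolerance_cm + 1e-12
    }
  }
  if (length(short)) {
    stop("fewer than 3 trials recorded at NSA location(s): ",
         paste(short, collapse = ", "))
  }
  nsa_localization_score(correct)
}
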