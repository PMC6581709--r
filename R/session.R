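#' Assessment sessions
#'
#' A session holds one automated assessment of one hand: subject metadata and
#' an ordered table of trials. Each trial records the stimulated site, how
#' many attempts were needed (a stimulus not perceived or missed is repeated,
#' up to three attempts), and the reported touch location in template
#' coordinates -- or a missing response when all attempts lapsed. Under the
#' default protocol each of the 24 sites is stimulated five times, 120 trials
#' in total.
#'
#' @param subject_id character scalar.
#' @param side `"left"` or `"right"`.
#' @param trials a data frame with columns `trial_index`, `site_id`,
#'   `attempts`, `resp_x`, `resp_y`, `missing` and optionally
#'   `response_time`; `resp_x`/`resp_y` are `NA` for missing trials.
#' @param hand_length_cm measured hand length (digit III tip to wrist
#'   crease), cm. Default 17, the reference hand.
#' @param laterality optional `"contralesional"` or `"ipsilesional"` label.
#' @param template_ref template version string the coordinates refer to.
#' @param stimulus_params metadata list; defaults record the 1.5 s, 150 Hz
#'   vibrotactile stimulus of the assessment protocol.
#' @param seed optional integer recorded for provenance.
#' @param ground_truth optional list of simulator ground-truth parameters.
#' @return an object of class `tactile_session`.
#' @export
new_session <- function(subject_id, side, trials, hand_length_cm = 17,
                        laterality = NULL, template_ref = "1.0",
                        stimulus_params = list(duration_s = 1.5,
                                               frequency_hz = 150),
                        seed = NULL, ground_truth = NULL) {
  trials <- tibble::as_tibble(trials)
  req <- c("trial_index", "site_id", "attempts", "resp_x", "resp_y", "missing")
  miss <- setdiff(req, names(trials))
  if (length(miss)) stop("trials lacks columns: ", paste(miss, collapse = ", "))
  if (!"response_time" %in% names(trials)) trials$response_time <- NA_real_
  trials$response_time <- as.numeric(trials$response_time)
  trials$resp_x <- as.numeric(trials$resp_x)
  trials$resp_y <- as.numeric(trials$resp_y)
  trials$trial_index <- as.integer(trials$trial_index)
  trials$site_id <- as.integer(trials$site_id)
  trials$attempts <- as.integer(trials$attempts)
  trials$missing <- as.logical(trials$missing)
  s <- structure(
    list(subject_id = subject_id, side = match.arg(side, c("left", "right")),
         laterality = laterality, hand_length_cm = hand_length_cm,
         template_ref = template_ref, stimulus_params = stimulus_params,
         trials = trials[, c(req, "response_time")],
         seed = seed, ground_truth = ground_truth),
    class = "tactile_session"
  )
  err <- session_errors(s)
  if (length(err)) stop("invalid session:\n", paste("-", err, collapse = "\n"))
  s
}

# hard invariant violations (errors); soft findings live in validate_session()
session_errors <- function(session) {
  t <- session$trials
  err <- character(0)
  if (nrow(t) == 0) err <- c(err, "session has no trials")
  if (!identical(t$trial_index, seq_len(nrow(t)))) {
    err <- c(err, "trial_index must be contiguous and increasing from 1")
  }
  bad_site <- !t$site_id %in% 1:24
  if (any(bad_site)) {
    err <- c(err, sprintf("unknown site_id %s at trial %s",
                          t$site_id[bad_site], t$trial_index[bad_site]))
  }
  if (any(t$attempts < 1 | t$attempts > 3, na.rm = TRUE)) {
    err <- c(err, "attempts must be in 1..3")
  }
  incons <- t$missing != (is.na(t$resp_x) | is.na(t$resp_y))
  if (any(incons)) {
    err <- c(err, sprintf("trial %d: missing flag inconsistent with response",
                          t$trial_index[incons]))
  }
  if (any(t$missing & t$attempts != 3L)) {
    err <- c(err, "missing responses require attempts == 3 (all attempts lapsed)")
  }
  if (!is.numeric(session$hand_length_cm) || session$hand_length_cm <= 0) {
    err <- c(err, "hand_length_cm must be positive")
  }
  err
}

#' Validate a session against a template
#'
#' Returns findings as data, not errors: structural violations with severity
#' `"error"`, plus warnings for partial sessions (site tested fewer than the
#' protocol's five repetitions), missing responses, and responses falling
#' outside the hand outline. A fully regular simulated session yields zero
#' findings.
#'
#' @param session a `tactile_session`.
#' @param template a `hand_template`; defaults to the session's side.
#' @param repetitions expected repetitions per site (default 5).
#' @return tibble with columns `severity`, `trial_index`, `message`.
#' @export
validate_session <- function(session, template = NULL, repetitions = 5) {
  if (is.null(template)) template <- default_hand_template(session$side)
  t <- session$trials
  f <- tibble::tibble(severity = character(), trial_index = integer(),
                      message = character())
  add <- function(f, severity, trial, msg) {
    dplyr::bind_rows(f, tibble::tibble(severity = severity,
                                       trial_index = trial, message = msg))
  }
  for (e in session_errors(session)) f <- add(f, "error", NA_integer_, e)
  counts <- table(factor(t$site_id, levels = 1:24))
  short <- which(counts < repetitions)
  for (s in short) {
    f <- add(f, "warning", NA_integer_,
             sprintf("site %d tested %d times (expected %d)",
                     s, counts[s], repetitions))
  }
  n_missing <- sum(t$missing)
  if (n_missing > 0) {
    f <- add(f, "warning", NA_integer_,
             sprintf("%d missing response%s", n_missing,
                     if (n_missing == 1) "" else "s"))
  }
  resp <- t[!t$missing, ]
  if (nrow(resp)) {
    out <- !hand_contains(template, cbind(resp$resp_x, resp$resp_y))
    for (i in which(out)) {
      f <- add(f, "warning", resp$trial_index[i],
               sprintf("trial %d response outside the hand outline",
                       resp$trial_index[i]))
    }
  }
  f
}

#' @export
print.tactile_session <- function(x, ...) {
  cat(sprintf(
    "<tactile_session %s, %s hand%s: %d trials, %d sites, %d missing>\n",
    x$subject_id, x$side,
    if (!is.null(x$laterality)) paste0(" (", x$laterality, ")") else "",
    nrow(x$trials), length(unique(x$trials$site_id)), sum(x$trials$missing)
  ))
  invisible(x)
}

#' @method as_tibble tactile_session
#' @export
as_tibble.tactile_session <- function(x, ...) x$trials

#' Read / write assessment sessions
#'
#' Two interchangeable formats, chosen by file extension: a canonical JSON
#' document (full metadata, `$schema`-tagged, version 1) and a flat CSV trial
#' table (`trial_index, site_id, attempts, resp_x, resp_y, missing,
#' response_time`) for spreadsheet use; CSV carries metadata in `#`-prefixed
#' header comment lines. Missing responses are empty response cells plus
#' `missing = 1`. Round trips are lossless; all session invariants are
#' validated on read.
#'
#' @param path file path ending in `.json` or `.csv`.
#' @return `read_session()` returns a `tactile_session`.
#' @export
read_session <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    .read_session_json(path)
  } else if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    .read_session_csv(path)
  } else {
    stop("unsupported session format (use .json or .csv): ", path)
  }
}

#' @rdname read_session
#' @param session a `tactile_session`.
#' @export
write_session <- function(session, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    .write_session_json(session, path)
  } else if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    .write_session_csv(session, path)
  } else {
    stop("unsupported session format (use .json or .csv): ", path)
  }
  invisible(path)
}

.session_schema <- "tactloc/session/v1"

.write_session_json <- function(session, path) {
  t <- session$trials
  doc <- list(
    `$schema` = .session_schema,
    subject_id = session$subject_id,
    side = session$side,
    laterality = session$laterality,
    hand_length_cm = session$hand_length_cm,
    template_ref = session$template_ref,
    stimulus_params = session$stimulus_params,
    seed = session$seed,
    ground_truth = session$ground_truth,
    trials = t
  )
  doc <- doc[!vapply(doc, is.null, logical(1))]
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
}

.read_session_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(doc$`$schema`) || !identical(doc$`$schema`, .session_schema)) {
    stop(path, ": not a session document (missing/unknown $schema)")
  }
  tryCatch(
    new_session(
      subject_id = doc$subject_id, side = doc$side,
      trials = tibble::as_tibble(doc$trials),
      hand_length_cm = doc$hand_length_cm,
      laterality = doc$laterality, template_ref = doc$template_ref,
      stimulus_params = doc$stimulus_params, seed = doc$seed,
      ground_truth = doc$ground_truth
    ),
    error = function(e) stop(path, ": ", conditionMessage(e), call. = FALSE)
  )
}

.write_session_csv <- function(session, path) {
  meta <- c(
    sprintf("# schema: %s", .session_schema),
    sprintf("# subject_id: %s", session$subject_id),
    sprintf("# side: %s", session$side),
    if (!is.null(session$laterality)) sprintf("# laterality: %s", session$laterality),
    sprintf("# hand_length_cm: %.17g", session$hand_length_cm),
    sprintf("# template_ref: %s", session$template_ref),
    if (!is.null(session$seed)) sprintf("# seed: %d", session$seed),
    "# units: template coordinates (mm on the 17 cm reference hand)"
  )
  t <- session$trials
  t$missing <- as.integer(t$missing)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(meta, con)
  utils::write.csv(as.data.frame(t), con, row.names = FALSE, quote = FALSE,
                   na = "")
  invisible(path)
}

.read_session_csv <- function(path) {
  lines <- readLines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  get_meta <- function(key) {
    m <- grep(sprintf("^# %s:", key), meta_lines, value = TRUE)
    if (!length(m)) return(NULL)
    sub(sprintf("^# %s:\\s*", key), "", m[1])
  }
  t <- utils::read.csv(text = lines[!grepl("^#", lines)],
                       stringsAsFactors = FALSE)
  t <- tibble::as_tibble(t)
  t$missing <- as.logical(as.integer(t$missing))
  lat <- get_meta("laterality")
  seed <- get_meta("seed")
  tryCatch(
    new_session(
      subject_id = get_meta("subject_id") %||% "unknown",
      side = get_meta("side") %||% "right",
      trials = t,
      hand_length_cm = as.numeric(get_meta("hand_length_cm") %||% "17"),
      laterality = lat,
      template_ref = get_meta("template_ref") %||% "1.0",
      seed = if (!is.null(seed)) as.integer(seed)
    ),
    error = function(e) stop(path, ": ", conditionMessage(e), call. = FALSE)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
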