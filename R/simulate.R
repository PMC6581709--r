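#' Parametric somatotopic distortion fields
#'
#' A distortion field is the simulator's ground truth: a deterministic
#' mapping from each true stimulation site to the centre of its perceived
#' location, plus isotropic Gaussian response noise and a per-attempt lapse
#' probability. Field kinds:
#' * `identity` -- perception centred on the true site,
#' * `distoproximal_shift` -- every finger site displaced `shift_cm` toward
#'   the palm along its digit's axis (the archetypal distal-to-proximal
#'   mislocalization after somatosensory stroke); palm sites are not
#'   displaced,
#' * `palm_compression` -- perceived locations contracted toward an attractor
#'   point (default the centroid of the palm sites):
#'   `perceived = attractor + compression * (true - attractor)`, modelling a
#'   hand representation shrunken onto the palm,
#' * `custom` -- explicit per-site displacement vectors in cm.
#'
#' @param kind one of `"identity"`, `"distoproximal_shift"`,
#'   `"palm_compression"`, `"custom"`.
#' @param shift_cm proximal shift magnitude in cm (`distoproximal_shift`).
#' @param compression contraction factor in `[0, 1]`; 0 collapses everything
#'   onto the attractor, 1 leaves positions unchanged (`palm_compression`).
#' @param attractor optional attractor point in template coordinates
#'   (`palm_compression`); default: centroid of the four palm sites.
#' @param displacement 24 x 2 matrix of per-site displacement vectors in cm
#'   (`custom`).
#' @param noise_sd_cm isotropic Gaussian response noise SD, cm, >= 0.
#' @param lapse_prob probability that a single stimulus attempt is not
#'   perceived, in `[0, 1]`; a trial is missing when all attempts lapse.
#' @return a `distortion_field` list.
#' @export
distortion_field <- function(kind = c("identity", "distoproximal_shift",
                                      "palm_compression", "custom"),
                             shift_cm = 0, compression = 1, attractor = NULL,
                             displacement = NULL, noise_sd_cm = 0,
                             lapse_prob = 0) {
  kind <- match.arg(kind)
  stopifnot(noise_sd_cm >= 0, lapse_prob >= 0, lapse_prob <= 1)
  if (kind == "distoproximal_shift" && shift_cm < 0) {
    stop("shift_cm must be >= 0")
  }
  if (kind == "palm_compression" &&
      (compression < 0 || compression > 1)) {
    stop("compression must be in [0, 1]")
  }
  if (kind == "custom") {
    displacement <- rbind(displacement)
    if (is.null(displacement) || !identical(dim(displacement), c(24L, 2L))) {
      stop("custom fields need a 24 x 2 displacement matrix (cm)")
    }
  }
  structure(
    list(kind = kind, shift_cm = shift_cm, compression = compression,
         attractor = attractor, displacement = displacement,
         noise_sd_cm = noise_sd_cm, lapse_prob = lapse_prob),
    class = "distortion_field"
  )
}

#' Virtual subjects
#'
#' A virtual subject is a distortion field plus hand metadata; simulating a
#' session for one replaces the glove hardware and a human responder while
#' keeping the ground truth known.
#'
#' @param field a [distortion_field()].
#' @param hand_length_cm subject hand length, cm (default 17, the reference).
#' @param side `"left"` or `"right"`.
#' @param subject_id identifier recorded in simulated sessions.
#' @return a `virtual_subject` list.
#' @export
virtual_subject <- function(field = distortion_field(), hand_length_cm = 17,
                            side = "right", subject_id = "virtual") {
  stopifnot(hand_length_cm > 0)
  structure(list(field = field, hand_length_cm = hand_length_cm,
                 side = match.arg(side, c("left", "right")),
                 subject_id = subject_id),
            class = "virtual_subject")
}

#' Archetypal virtual subjects
#'
#' Three documented parameter sets spanning the clinically observed range:
#' * `healthy` -- identity field, 0.4 cm response noise, no lapses;
#' * `patient1_like` -- 1.5 cm distoproximal shift of the finger sites with
#'   0.8 cm noise: perception systematically displaced from the distal toward
#'   more proximal phalanges, as after a thalamic sensory stroke;
#' * `patient2_like` -- palm compression (factor 0.25 toward the palm
#'   centroid) with 1.8 cm noise and a 0.25 per-attempt lapse probability:
#'   perception of the whole hand collapsed onto the palmar area, as after a
#'   large cortical SI lesion.
#'
#' @param name archetype name.
#' @param side hand side for the virtual subject.
#' @return a `virtual_subject`.
#' @export
archetype <- function(name = c("healthy", "patient1_like", "patient2_like"),
                      side = "left") {
  name <- match.arg(name)
  field <- switch(
    name,
    healthy = distortion_field("identity", noise_sd_cm = 0.4),
    patient1_like = distortion_field("distoproximal_shift", shift_cm = 1.5,
                                     noise_sd_cm = 0.8),
    patient2_like = distortion_field("palm_compression", compression = 0.25,
                                     noise_sd_cm = 1.8, lapse_prob = 0.25)
  )
  virtual_subject(field, hand_length_cm = 17, side = side, subject_id = name)
}

# Unit vector pointing proximally (distal -> proximal) along a digit's axis,
# fitted through the digit's site chain. Palm sites have no axis (NULL).
digit_axis_proximal <- function(template, site_id) {
  s <- template$sites
  digit <- s$digit[s$site_id == site_id]
  if (digit == "palm") return(NULL)
  chain <- s[s$digit == digit, ]
  chain <- chain[order(chain$distal_rank), ]
  # direction from the most distal to the most proximal site of the digit
  v <- c(chain$x[nrow(chain)] - chain$x[1], chain$y[nrow(chain)] - chain$y[1])
  v / sqrt(sum(v^2))
}

# displaced (pre-noise) perceived centre for a site, template units
displaced_site <- function(field, template, site_id) {
  pos <- as.numeric(site_position(template, site_id))
  upc <- template$units_per_cm
  switch(
    field$kind,
    identity = pos,
    distoproximal_shift = {
      ax <- digit_axis_proximal(template, site_id)
      if (is.null(ax)) pos else pos + ax * field$shift_cm * upc
    },
    palm_compression = {
      attractor <- field$attractor %||% {
        palm <- template$sites[template$sites$digit == "palm", ]
        c(mean(palm$x), mean(palm$y))
      }
      attractor + field$compression * (pos - attractor)
    },
    custom = pos + field$displacement[site_id, ] * upc
  )
}

#' Simulate the percept for one stimulation
#'
#' Applies the subject's distortion field to the site, adds isotropic
#' Gaussian noise, clamps the result into the hand outline, and applies the
#' lapse/re-attempt rule: each attempt independently lapses with probability
#' `lapse_prob`; after `max_attempts` lapses the trial is missing. Randomness
#' is counter-based on `(seed, trial_index)`, so any trial can be reproduced
#' in isolation; the caller's RNG state is untouched.
#'
#' @param subject a [virtual_subject()].
#' @param template a `hand_template`.
#' @param site_id stimulated site.
#' @param seed integer session seed.
#' @param trial_index trial counter within the session.
#' @param max_attempts attempts allowed before the trial is missing.
#' @return list with `response` (length-2 point or `NULL` if missing),
#'   `attempts`, `missing`.
#' @export
perceive <- function(subject, template, site_id, seed = 1L, trial_index = 1L,
                     max_attempts = 3L) {
  field <- subject$field
  rng_lapse <- .counter_rng(seed, stream = 1L)
  rng_noise <- .counter_rng(seed, stream = 2L)
  u <- rng_lapse$runif(max_attempts, counter = trial_index)
  lapsed <- u < field$lapse_prob
  if (all(lapsed)) {
    return(list(response = NULL, attempts = max_attempts, missing = TRUE))
  }
  attempts <- which(!lapsed)[1]
  centre <- displaced_site(field, template, site_id)
  noise <- rng_noise$rnorm(2, counter = trial_index) *
    field$noise_sd_cm * template$units_per_cm
  resp <- as.numeric(clamp_to_hand(template, centre + noise))
  list(response = resp, attempts = as.integer(attempts), missing = FALSE)
}

#' Simulate a full assessment session
#'
#' Generates the stimulation sequence from the protocol configuration and
#' runs [perceive()] per trial, returning a fully valid session with the
#' ground-truth field parameters embedded in its metadata. All simulated
#' responses lie inside the hand outline.
#'
#' @param subject a [virtual_subject()].
#' @param template a `hand_template`; defaults to the subject's side.
#' @param config a [protocol_config()]; its seed drives both the sequence
#'   and the per-trial randomness.
#' @return a `tactile_session`.
#' @examples
#' s <- simulate_session(archetype("healthy"), config = protocol_config(seed = 3))
#' nrow(s$trials) # 120
#' @export
simulate_session <- function(subject, template = NULL,
                             config = protocol_config()) {
  if (is.null(template)) template <- default_hand_template(subject$side)
  seq_sites <- generate_sequence(config)
  rows <- purrr::map_dfr(seq_along(seq_sites), function(i) {
    p <- perceive(subject, template, seq_sites[i], seed = config$seed,
                  trial_index = i, max_attempts = config$max_attempts)
    tibble::tibble(
      trial_index = i, site_id = seq_sites[i], attempts = p$attempts,
      resp_x = if (p$missing) NA_real_ else p$response[1],
      resp_y = if (p$missing) NA_real_ else p$response[2],
      missing = p$missing
    )
  })
  f <- subject$field
  new_session(
    subject_id = subject$subject_id, side = subject$side, trials = rows,
    hand_length_cm = subject$hand_length_cm,
    template_ref = template$version, seed = config$seed,
    ground_truth = list(
      kind = f$kind, shift_cm = f$shift_cm, compression = f$compression,
      noise_sd_cm = f$noise_sd_cm, lapse_prob = f$lapse_prob
    )
  )
}
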