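#' Assessment protocol configuration
#'
#' The automated protocol stimulates each of the 24 sites five times in
#' pseudo-random order (120 trials), allowing up to three attempts per trial
#' before the trial is recorded as missing. "Pseudo-random" is implemented as
#' a seeded uniform shuffle with an optional no-immediate-repeat constraint
#' (on by default: two identical vibrotactile stimuli back to back would be
#' confusable), enforced by backtracking reshuffles.
#'
#' @param repetitions_per_site repetitions of every site, >= 1 (default 5).
#' @param sites site ids to test (default all 24).
#' @param max_attempts attempts allowed per trial before it counts as
#'   missing (default 3).
#' @param no_immediate_repeat forbid the same site on consecutive trials.
#' @param seed integer seed making the sequence reproducible.
#' @return a `protocol_config` list.
#' @export
protocol_config <- function(repetitions_per_site = 5, sites = 1:24,
                            max_attempts = 3, no_immediate_repeat = TRUE,
                            seed = 1L) {
  sites <- as.integer(sites)
  if (length(sites) < 1 || anyDuplicated(sites)) {
    stop("sites must be a non-empty set of unique site ids")
  }
  if (repetitions_per_site < 1) stop("repetitions_per_site must be >= 1")
  if (max_attempts < 1) stop("max_attempts must be >= 1")
  structure(
    list(repetitions_per_site = as.integer(repetitions_per_site),
         sites = sites, max_attempts = as.integer(max_attempts),
         no_immediate_repeat = isTRUE(no_immediate_repeat),
         seed = as.integer(seed)),
    class = "protocol_config"
  )
}

#' Generate a pseudo-random stimulation sequence
#'
#' Returns the ordered site ids for one session: every configured site
#' exactly `repetitions_per_site` times, uniformly shuffled under the seed,
#' with no two consecutive identical sites when `no_immediate_repeat` is set.
#' Deterministic given the seed.
#'
#' @param config a [protocol_config()].
#' @return integer vector of length `length(sites) * repetitions_per_site`.
#' @examples
#' length(generate_sequence(protocol_config(seed = 7))) # 120
#' @export
generate_sequence <- function(config = protocol_config()) {
  pool <- rep(config$sites, times = config$repetitions_per_site)
  if (config$no_immediate_repeat &&
      length(config$sites) == 1 && config$repetitions_per_site > 1) {
    stop("infeasible constraint: a single site repeated ",
         config$repetitions_per_site,
         " times cannot avoid immediate repeats")
  }
  rng <- .counter_rng(config$seed, stream = 0L)
  for (try in seq_len(10000L)) {
    seq <- pool[rng$sample_perm(length(pool), counter = try)]
    if (!config$no_immediate_repeat || !any(seq[-1] == seq[-length(seq)])) {
      return(seq)
    }
  }
  stop("could not satisfy the no-immediate-repeat constraint after 10000 shuffles")
}

#' The six clinical test locations (NSA localization subscale)
#'
#' The clinical localization test uses six hand locations: the volar distal
#' phalanges of digits I, III and V, the distal volar aspect of the 2nd and
#' 5th metacarpal, and the centre of the thenar eminence. On the template
#' these map to stimulation sites 1, 9, 17, 8 and 20 plus the thenar palm
#' site.
#'
#' @param template a `hand_template`.
#' @return tibble with columns `location`, `site_id` (the coinciding
#'   stimulation site), `x`, `y`.
#' @export
nsa_locations <- function(template = default_hand_template("right")) {
  ids <- c(1L, 8L, 9L, 17L, 20L, 21L)
  pos <- site_position(template, ids)
  tibble::tibble(
    location = c("digit_I_distal_phalanx", "digit_II_metacarpal",
                 "digit_III_distal_phalanx", "digit_V_distal_phalanx",
                 "digit_V_metacarpal", "thenar_eminence"),
    site_id = ids,
    x = pos[, 1],
    y = pos[, 2]
  )
}

# Counter-based seeded randomness: every draw re-seeds a local RNG from
# (seed, stream, counter), so results do not depend on evaluation order or
# on the caller's RNG state, and the global RNG is left untouched.
.counter_rng <- function(seed, stream = 0L) {
  base <- (as.numeric(seed) * 48271 + as.numeric(stream) * 9973) %% 2147483647
  with_counter <- function(counter, expr) {
    sub_seed <- as.integer((base + as.numeric(counter) * 2654435) %% 2147483647)
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      get(".Random.seed", globalenv())
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(sub_seed)
    expr
  }
  list(
    sample_perm = function(n, counter) with_counter(counter, sample.int(n)),
    runif = function(n, counter) with_counter(counter, stats::runif(n)),
    rnorm = function(n, counter) with_counter(counter, stats::rnorm(n))
  )
}
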