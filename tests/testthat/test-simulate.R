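tpl_r <- default_hand_template("right")

test_that("identity field with zero noise reproduces site positions exactly", {
  subj <- virtual_subject(distortion_field("identity"), side = "right")
  for (sid in c(1L, 9L, 24L)) {
    p <- perceive(subj, tpl_r, sid, seed = 3, trial_index = sid)
    expect_false(p$missing)
    expect_equal(p$attempts, 1L)
    expect_equal(p$response, as.numeric(tactloc:::site_position(tpl_r, sid)))
  }
})

test_that("distoproximal shift displaces finger sites along the digit axis", {
  shift_cm <- 1
  subj <- virtual_subject(
    distortion_field("distoproximal_shift", shift_cm = shift_cm),
    side = "right")
  # mid-finger site on the (straight) middle finger: displacement is purely
  # proximal along the digit axis and has exactly the programmed length
  p <- perceive(subj, tpl_r, 10L, seed = 1, trial_index = 1)
  pos <- as.numeric(tactloc:::site_position(tpl_r, 10L))
  d <- p$response - pos
  expect_equal(sqrt(sum(d^2)), shift_cm * tpl_r$units_per_cm, tolerance = 1e-9)
  expect_lt(d[2], 0) # proximal = toward the wrist
  ax <- tactloc:::digit_axis_proximal(tpl_r, 10L)
  expect_equal(as.numeric(d / sqrt(sum(d^2))), as.numeric(ax), tolerance = 1e-9)
  # palm sites are not displaced
  p21 <- perceive(subj, tpl_r, 21L, seed = 1, trial_index = 2)
  expect_equal(p21$response, as.numeric(tactloc:::site_position(tpl_r, 21L)))
})

test_that("palm compression contracts percepts toward the attractor", {
  # compression = 0 collapses every site onto the attractor
  att <- c(0, 34)
  subj0 <- virtual_subject(distortion_field("palm_compression",
                                            compression = 0, attractor = att),
                           side = "right")
  for (sid in c(1L, 9L, 17L)) {
    expect_equal(perceive(subj0, tpl_r, sid, seed = 2, trial_index = sid)$response,
                 att)
  }
  # intermediate compression interpolates linearly
  subj5 <- virtual_subject(distortion_field("palm_compression",
                                            compression = 0.5, attractor = att),
                           side = "right")
  pos <- as.numeric(tactloc:::site_position(tpl_r, 9L))
  expect_equal(perceive(subj5, tpl_r, 9L, seed = 2, trial_index = 1)$response,
               att + 0.5 * (pos - att))
})

test_that("lapse probability boundaries behave as specified", {
  never <- virtual_subject(distortion_field("identity", lapse_prob = 0))
  ses <- simulate_session(never, config = protocol_config(seed = 4))
  expect_equal(sum(ses$trials$missing), 0)
  expect_true(all(ses$trials$attempts == 1L))
  always <- virtual_subject(distortion_field("identity", lapse_prob = 1))
  ses1 <- simulate_session(always, config = protocol_config(seed = 4))
  expect_true(all(ses1$trials$missing))
  expect_true(all(ses1$trials$attempts == 3L))
})

test_that("missing fraction across many trials matches lapse_prob cubed", {
  p <- 0.4
  subj <- virtual_subject(distortion_field("identity", lapse_prob = p))
  n <- 10000
  missing <- vapply(seq_len(n), function(i) {
    perceive(subj, tpl_r, 22L, seed = 13, trial_index = i)$missing
  }, logical(1))
  expected <- p^3
  # binomial 99% CI around the theoretical missing rate
  half <- qnorm(0.995) * sqrt(expected * (1 - expected) / n)
  expect_gte(mean(missing), expected - half)
  expect_lte(mean(missing), expected + half)
  # attempts distribution: geometric truncated at 3
  att <- vapply(which(!missing)[1:2000], function(i) {
    perceive(subj, tpl_r, 22L, seed = 13, trial_index = i)$attempts
  }, integer(1))
  expect_equal(mean(att == 1), (1 - p) / (1 - p^3), tolerance = 0.05)
})

test_that("simulated sessions are valid, seed-deterministic and inside the hand", {
  subj <- archetype("patient2_like")
  s1 <- simulate_session(subj, config = protocol_config(seed = 31))
  s2 <- simulate_session(subj, config = protocol_config(seed = 31))
  s3 <- simulate_session(subj, config = protocol_config(seed = 32))
  expect_identical(s1$trials, s2$trials)
  expect_false(identical(s1$trials, s3$trials))
  expect_identical(nrow(s1$trials), 120L)
  expect_identical(nrow(validate_session(s1)[validate_session(s1)$severity == "error", ]), 0L)
  resp <- s1$trials[!s1$trials$missing, ]
  expect_true(all(hand_contains(default_hand_template("left"),
                                cbind(resp$resp_x, resp$resp_y))))
  expect_identical(s1$ground_truth$kind, "palm_compression")
})

test_that("programmed shifts are recovered by the offset metric", {
  # zero noise: recovery is exact at straight-segment finger sites
  for (delta in c(0.5, 1, 2)) {
    subj <- virtual_subject(
      distortion_field("distoproximal_shift", shift_cm = delta),
      side = "right")
    ses <- simulate_session(subj, config = protocol_config(seed = 7))
    sm <- summarize_session(ses)
    mid_finger <- c(10L, 11L, 14L, 15L) # interior sites of digits III and IV
    for (sid in mid_finger) {
      expect_equal(sm$per_site$offset_cm[sm$per_site$site_id == sid], delta,
                   tolerance = 1e-6)
    }
  }
  # with noise: recovery within 3 sigma / sqrt(reps)
  sigma <- 0.4
  delta <- 1
  subj <- virtual_subject(
    distortion_field("distoproximal_shift", shift_cm = delta,
                     noise_sd_cm = sigma), side = "right")
  ses <- simulate_session(subj, config = protocol_config(seed = 19))
  sm <- summarize_session(ses)
  tol <- 3 * sigma / sqrt(5)
  for (sid in c(10L, 11L, 14L, 15L)) {
    expect_lt(abs(sm$per_site$offset_cm[sm$per_site$site_id == sid] - delta),
              tol)
  }
})

test_that("archetypes produce their characteristic confusion structure", {
  # patient1-like, noise stripped: fingertip percepts discretize to a more
  # proximal site on the same digit
  f <- distortion_field("distoproximal_shift", shift_cm = 1.5)
  subj <- virtual_subject(f, side = "right")
  for (tip in c(5L, 9L, 13L, 17L)) {
    p <- perceive(subj, tpl_r, tip, seed = 1, trial_index = tip)
    d <- geodesic_to_sites(tpl_r, p$response)
    nearest <- which.min(d)
    digit_of <- function(s) tpl_r$sites$digit[tpl_r$sites$site_id == s]
    expect_identical(digit_of(nearest), digit_of(tip))
    expect_gt(nearest, tip) # more proximal site of the same digit chain
  }
  # patient2-like, noise stripped: finger-site percepts leave the fingers
  f2 <- distortion_field("palm_compression", compression = 0.25)
  subj2 <- virtual_subject(f2, side = "right")
  finger_sites <- 1:20
  proximal_or_palm <- function(s) {
    seg <- tpl_r$sites$segment[tpl_r$sites$site_id == s]
    seg %in% c("palm", "distal_metacarpal", "proximal_metacarpal")
  }
  for (sid in c(1L, 5L, 9L, 13L, 17L, 6L, 10L)) {
    p <- perceive(subj2, tpl_r, sid, seed = 1, trial_index = sid)
    nearest <- which.min(geodesic_to_sites(tpl_r, p$response))
    expect_true(proximal_or_palm(nearest))
  }
  # healthy archetype scores near-perfectly
  ses <- simulate_session(archetype("healthy"), config = protocol_config(seed = 5))
  sm <- summarize_session(ses)
  expect_lt(unname(sm$mean_offset_cm["mean"]), 0.6)
  expect_gt(unname(sm$mean_clr_pct["mean"]), 80)
})

test_that("perceive leaves the caller's RNG state untouched", {
  set.seed(123)
  before <- .Random.seed
  invisible(perceive(archetype("patient2_like"), default_hand_template("left"),
                     3L, seed = 9, trial_index = 2))
  expect_identical(.Random.seed, before)
})
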