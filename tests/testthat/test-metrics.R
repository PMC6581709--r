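tpl_r <- default_hand_template("right")

test_that("response center is the centroid, clamped into the hand when needed", {
  expect_equal(response_center(rbind(c(1, 2)), square_template), c(1, 2))
  expect_equal(response_center(rbind(c(1, 0), c(1, 2)), square_template), c(1, 1))
  # responses on two adjacent fingertips: centroid falls in the web gap and
  # must be clamped onto the outline
  p5 <- as.numeric(tactloc:::site_position(tpl_r, 5))
  p9 <- as.numeric(tactloc:::site_position(tpl_r, 9))
  mid <- (p5 + p9) / 2
  expect_false(hand_contains(tpl_r, mid))
  ctr <- response_center(rbind(p5, p9), tpl_r)
  expect_true(hand_contains(tpl_r, ctr))
  expect_error(response_center(matrix(0, 0, 2), square_template), "no responses")
})

test_that("offset, spread and distance follow their definitions in a convex region", {
  # all responses at the site -> all three metrics are zero
  site10 <- as.numeric(tactloc:::site_position(tpl_r, 10))
  resp <- rbind(site10, site10, site10)
  expect_equal(location_offset(resp, 10L, tpl_r), 0)
  expect_equal(location_spread(resp, 10L, tpl_r), 0)
  expect_equal(location_distance(resp, 10L, tpl_r), 0)
  # square template has units_per_cm = 1: responses symmetric about c give
  # offset = Euclidean(site, c); two points 2 apart give spread 1
  sq <- square_template
  s1 <- c(sq$sites$x[1], sq$sites$y[1])
  resp <- rbind(s1 + c(0.5, 1.1), s1 + c(0.9, 0.9), s1 + c(0.1, 1.3))
  ctr <- colMeans(resp)
  expect_equal(location_offset(resp, 1L, sq), sqrt(sum((ctr - s1)^2)))
  two <- rbind(c(1, 1), c(1, 3))
  expect_equal(location_spread(two, 1L, sq), 1)
  # distance = mean of the individual errors (here 0.5 and 1.5)
  resp13 <- rbind(s1 + c(0, 0.5), s1 - c(0, 1.5))
  expect_equal(location_distance(resp13, 1L, sq), 1)
  # single response -> zero spread
  expect_equal(location_spread(rbind(c(2, 2)), 1L, sq), 0)
})

test_that("spread of isotropic Gaussian responses approaches sigma * sqrt(pi/2)", {
  set.seed(202)
  sigma <- 0.2
  n <- 5000
  resp <- cbind(rnorm(n, 2, sigma), rnorm(n, 2, sigma))
  stopifnot(all(tactloc:::point_in_polygon(square_poly, resp)))
  sp <- location_spread(resp, 1L, square_template)
  expect_equal(sp, sigma * sqrt(pi / 2), tolerance = 0.02)
})

test_that("distance dominates offset for responses within one convex sub-region", {
  # Jensen: mean distance to the site >= distance of the mean to the site
  set.seed(31)
  for (rep in 1:20) {
    resp <- sample_inside(square_poly, 6)
    off <- location_offset(resp, 1L, square_template)
    dst <- location_distance(resp, 1L, square_template)
    expect_gte(dst, off - 1e-9)
  }
})

test_that("metrics are invariant under rigid motions of template plus responses", {
  th <- 30 * pi / 180
  R <- rbind(c(cos(th), -sin(th)), c(sin(th), cos(th)))
  shift <- c(12, -7)
  rot_tpl <- tpl_r
  rot_tpl$outline <- t(R %*% t(tpl_r$outline)) + rep(shift, each = nrow(tpl_r$outline))
  xy <- t(R %*% t(cbind(tpl_r$sites$x, tpl_r$sites$y))) +
    rep(shift, each = 24)
  rot_tpl$sites$x <- xy[, 1]
  rot_tpl$sites$y <- xy[, 2]
  rot_tpl$version <- "rot"
  set.seed(8)
  for (sid in c(9L, 21L)) {
    pos <- as.numeric(tactloc:::site_position(tpl_r, sid))
    resp <- rep(pos, each = 5) + matrix(rnorm(10, 0, 3), 5, 2)
    stopifnot(all(hand_contains(tpl_r, resp)))
    resp_rot <- t(R %*% t(resp)) + rep(shift, each = 5)
    expect_equal(location_offset(resp_rot, sid, rot_tpl),
                 location_offset(resp, sid, tpl_r), tolerance = 1e-9)
    expect_equal(location_spread(resp_rot, sid, rot_tpl),
                 location_spread(resp, sid, tpl_r), tolerance = 1e-9)
    expect_equal(location_distance(resp_rot, sid, rot_tpl),
                 location_distance(resp, sid, tpl_r), tolerance = 1e-9)
  }
})

test_that("confusion matrix discretizes to the nearest site with valid row percentages", {
  # identity responses -> 100% diagonal
  ses <- identity_session(tpl_r, reps = 2)
  cm <- confusion_matrix(ses, tpl_r)
  expect_equal(diag(cm$percent), rep(100, 24), ignore_attr = TRUE)
  expect_equal(rowSums(cm$percent), rep(100, 24), ignore_attr = TRUE)
  expect_equal(cm$row_n, rep(2, 24), ignore_attr = TRUE)
  # a response placed exactly at another site's coordinates lands there
  p22 <- as.numeric(tactloc:::site_position(tpl_r, 22))
  one <- make_session(3L, p22[1], p22[2])
  cm1 <- confusion_matrix(one, tpl_r)
  expect_equal(cm1$percent[3, 22], 100)
  expect_equal(sum(cm1$counts), 1)
  # random interior responses: assignment equals exhaustive argmin over sites
  set.seed(77)
  pts <- sample_inside(tpl_r$outline, 8, margin = 1)
  ses2 <- make_session(rep(1L, 8), pts[, 1], pts[, 2])
  cm2 <- confusion_matrix(ses2, tpl_r)
  for (i in 1:8) {
    d <- vapply(1:24, function(s) {
      geodesic_distance(tpl_r, pts[i, ],
                        as.numeric(tactloc:::site_position(tpl_r, s)))
    }, numeric(1))
    expect_gt(cm2$counts[1, which.min(d)], 0)
  }
  expect_equal(sum(cm2$counts[1, ]), 8)
  # rows sum to 100 whenever they have responses (structural invariant)
  expect_equal(unname(rowSums(cm2$percent)[1]), 100)
  expect_true(all(is.na(cm2$percent[2:24, ])))
})

test_that("missing responses are excluded from confusion percentages but counted", {
  pos <- as.numeric(tactloc:::site_position(tpl_r, 4))
  ses <- make_session(
    site_id = c(4L, 4L, 4L),
    resp_x = c(pos[1], NA, pos[1]), resp_y = c(pos[2], NA, pos[2]),
    missing = c(FALSE, TRUE, FALSE)
  )
  cm <- confusion_matrix(ses, tpl_r)
  expect_equal(cm$row_n[["4"]], 2)
  expect_equal(cm$row_missing[["4"]], 1)
  expect_equal(cm$percent[4, 4], 100)
})

test_that("correct localization rate averages the requested diagonal subset", {
  ses <- identity_session(tpl_r, reps = 1)
  cm <- confusion_matrix(ses, tpl_r)
  clr <- correct_localization_rate(cm)
  expect_equal(clr$mean, 100)
  expect_equal(clr$sd, 0)
  # half the rows perfectly wrong -> mean 50
  cm2 <- cm
  cm2$percent[1:12, ] <- 0
  cm2$percent[cbind(1:12, c(2:13))] <- 100
  expect_equal(correct_localization_rate(cm2)$mean, 50)
  # fingertip subset = distal phalanges of the five digits
  tips <- correct_localization_rate(cm2, subset = c(1, 5, 9, 13, 17))
  expect_equal(tips$n_sites, 5)
  expect_equal(unname(tips$per_site),
               unname(diag(cm2$percent)[c(1, 5, 9, 13, 17)]))
  expect_error(correct_localization_rate(cm, subset = integer(0)), "non-empty")
})

test_that("summarize_session is order-invariant and normalizes by hand length", {
  subj <- archetype("patient1_like")
  ses <- simulate_session(subj, config = protocol_config(seed = 9))
  sm <- summarize_session(ses)
  # permuting trials changes nothing
  perm <- withr::with_seed(1, sample(nrow(ses$trials)))
  t2 <- ses$trials[perm, ]
  t2$trial_index <- seq_len(nrow(t2))
  ses2 <- new_session(ses$subject_id, ses$side, t2,
                      hand_length_cm = ses$hand_length_cm)
  sm2 <- summarize_session(ses2)
  expect_equal(sm2$per_site$offset_cm, sm$per_site$offset_cm)
  expect_equal(sm2$mean_clr_pct, sm$mean_clr_pct)
  # normalization multiplies every length by 17 / hand_length
  ses_big <- new_session(ses$subject_id, ses$side, ses$trials,
                         hand_length_cm = 20)
  raw <- summarize_session(ses_big, normalize = FALSE)
  nrm <- summarize_session(ses_big, normalize = TRUE)
  expect_equal(nrm$per_site$offset_cm, raw$per_site$offset_cm * 17 / 20)
  expect_equal(nrm$per_site$spread_cm, raw$per_site$spread_cm * 17 / 20)
  # tidiers
  expect_identical(tidy(sm), sm$per_site)
  g <- glance(sm)
  expect_equal(g$n_trials, 120)
  expect_equal(g$mean_offset_cm, unname(sm$mean_offset_cm["mean"]))
})

test_that("a zero-noise identity simulation scores perfectly", {
  subj <- virtual_subject(distortion_field("identity"), side = "right")
  ses <- simulate_session(subj, config = protocol_config(seed = 2))
  sm <- summarize_session(ses)
  expect_equal(sm$per_site$offset_cm, rep(0, 24))
  expect_equal(sm$per_site$spread_cm, rep(0, 24))
  expect_equal(sm$per_site$distance_cm, rep(0, 24))
  expect_equal(unname(sm$mean_clr_pct["mean"]), 100)
  expect_equal(sm$n_missing, 0)
})

test_that("aggregate_site_values reports mean and SD with 1-decimal reporting", {
  agg <- aggregate_site_values(c(1.0, 2.0, 3.0, NA))
  expect_equal(agg$mean, 2)
  expect_equal(agg$sd, 1)
  expect_equal(agg$n, 3)
  expect_equal(aggregate_site_values(c(0.123, 0.129))$mean_1dp, 0.1)
})

test_that("summary and confusion exports write readable tables", {
  ses <- identity_session(tpl_r, reps = 1)
  sm <- summarize_session(ses)
  csv <- withr::local_tempfile(fileext = ".csv")
  write_summary(sm, csv)
  tab <- readr::read_csv(csv, show_col_types = FALSE)
  expect_equal(nrow(tab), 26) # 24 sites + mean + sd rows
  expect_equal(tab$offset_cm[25], unname(sm$mean_offset_cm["mean"]))
  js <- withr::local_tempfile(fileext = ".json")
  write_summary(sm, js)
  doc <- jsonlite::read_json(js, simplifyVector = TRUE)
  expect_equal(doc$mean_clr_pct$mean, 100)
  cmf <- withr::local_tempfile(fileext = ".csv")
  write_confusion(sm$confusion, cmf)
  cm_tab <- readr::read_csv(cmf, show_col_types = FALSE)
  expect_equal(dim(cm_tab), c(24L, 27L))
  expect_equal(cm_tab$perceived_1[1], 100)
})
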