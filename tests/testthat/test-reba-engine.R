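test_that("body-part subscores reproduce the worksheet band examples", {
  ## (inputs) -> expected, per body part
  expect_identical(score_neck(10, 0, 0), 1L)
  expect_identical(score_neck(25, 0, 0), 2L)
  expect_identical(score_neck(-5, 15, 0), 3L)
  expect_identical(score_neck(25, 15, 15), 3L)     # twist adjustment capped

  expect_identical(score_trunk(0, 0, 0), 1L)
  expect_identical(score_trunk(10, 0, 0), 2L)
  expect_identical(score_trunk(-10, 0, 0), 2L)
  expect_identical(score_trunk(-30, 0, 0), 3L)
  expect_identical(score_trunk(70, 0, 0), 4L)
  expect_identical(score_trunk(30, 12, 0), 4L)
  expect_identical(score_trunk(70, 12, 12), 5L)    # capped at 5

  expect_identical(score_legs(0, 0, TRUE, TRUE), 1L)
  expect_identical(score_legs(65, 0, TRUE, FALSE), 4L)
  expect_identical(score_legs(40, 40, TRUE, TRUE), 2L)
  expect_identical(score_legs(0, 0, FALSE, FALSE), 2L)  # flight: unstable base
  expect_identical(score_legs(80, 80, FALSE, TRUE), 4L)

  expect_identical(score_load(c(0, 6, 11)), c(0L, 1L, 2L))

  expect_identical(score_upper_arm(0, 0, 0), 1L)
  expect_identical(score_upper_arm(-30, 0, 0), 2L)
  expect_identical(score_upper_arm(30, 0, 0), 2L)
  expect_identical(score_upper_arm(100, 0, 0), 4L)
  expect_identical(score_upper_arm(50, 0, 15), 4L)
  expect_identical(score_upper_arm(0, 70, 0), 3L)  # abducted elevation counts

  expect_identical(score_forearm(c(80, 10, 120)), c(1L, 2L, 2L))

  expect_identical(score_wrist(0, 0, 0), 1L)
  expect_identical(score_wrist(20, 0, 0), 2L)
  expect_identical(score_wrist(20, 20, 50), 3L)
  expect_identical(score_wrist(0, 20, 0), 2L)

  expect_error(score_neck(NaN, 0, 0), "non-finite")
  expect_error(score_load(Inf), "non-finite")
})

test_that("every angular breakpoint flips its subscore exactly at the printed value", {
  eps <- 0.01
  flip <- function(f, at, below, above) {
    expect_identical(f(at - eps), below)
    expect_identical(f(at + eps), above)
  }
  flip(function(x) score_neck(x, 0, 0), 0, 2L, 1L)
  flip(function(x) score_neck(x, 0, 0), 20, 1L, 2L)
  flip(function(x) score_neck(10, x, 0), 10, 1L, 2L)
  flip(function(x) score_neck(10, 0, x), 10, 1L, 2L)
  flip(function(x) score_trunk(x, 0, 0), 2, 1L, 2L)   # neutral tolerance edge
  flip(function(x) score_trunk(x, 0, 0), 20, 2L, 3L)
  flip(function(x) score_trunk(x, 0, 0), 60, 3L, 4L)
  flip(function(x) score_trunk(x, 0, 0), -20, 3L, 2L)
  flip(function(x) score_trunk(10, x, 0), 10, 2L, 3L)
  flip(function(x) score_legs(x, 0, TRUE, TRUE), 30, 1L, 2L)
  flip(function(x) score_legs(x, 0, TRUE, TRUE), 60, 2L, 3L)
  flip(function(x) score_load(x), 5, 0L, 1L)
  flip(function(x) score_load(x), 10, 1L, 2L)
  flip(function(x) score_upper_arm(x, 0, 0), 20, 1L, 2L)
  flip(function(x) score_upper_arm(x, 0, 0), -20, 2L, 1L)
  flip(function(x) score_upper_arm(x, 0, 0), 45, 2L, 3L)
  flip(function(x) score_upper_arm(x, 0, 0), 90, 3L, 4L)
  flip(function(x) score_upper_arm(30, 0, x), 10, 2L, 3L)
  flip(function(x) score_forearm(x), 60, 2L, 1L)
  flip(function(x) score_forearm(x), 100, 1L, 2L)
  flip(function(x) score_wrist(x, 0, 0), 15, 1L, 2L)
  flip(function(x) score_wrist(x, 0, 0), -15, 2L, 1L)
  flip(function(x) score_wrist(0, x, 0), 10, 1L, 2L)
  flip(function(x) score_wrist(0, 0, x), 45, 1L, 2L)
})

test_that("table transcriptions span their ranges, hit spot cells and are monotone", {
  tabs <- reba_tables()
  expect_setequal(unique(as.vector(tabs$a)), 1:9)
  expect_setequal(unique(as.vector(tabs$b)), 1:9)
  expect_setequal(unique(as.vector(tabs$c)), 1:12)
  expect_identical(lookup_table_a(1, 1, 1), 1L)
  expect_identical(lookup_table_a(3, 5, 4), 9L)
  expect_true(lookup_table_a(2, 3, 2) <= lookup_table_a(2, 4, 2))
  expect_identical(lookup_table_b(1, 1, 1), 1L)
  expect_identical(lookup_table_b(6, 2, 3), 9L)
  expect_identical(lookup_table_c(1, 1), 1L)
  expect_identical(lookup_table_c(11, 9), 12L)
  mono <- function(arr) {
    for (d in seq_along(dim(arr))) {
      expect_true(all(apply(arr, setdiff(seq_along(dim(arr)), d),
                            function(v) all(diff(v) >= 0))))
    }
  }
  mono(tabs$a); mono(tabs$b); mono(tabs$c)
  expect_error(lookup_table_a(0, 1, 1), "out of range")
  expect_error(lookup_table_c(13, 1), "out of range")
})

test_that("composition equals brute-force nested lookup over all subscore combinations", {
  grid <- expand.grid(neck = 1:3, trunk = 1:5, legs = 1:4, load = 0:2,
                      ua = 1:6, fa = 1:2, wr = 1:3, act = 0:2)
  got <- compose_reba(grid$neck, grid$trunk, grid$legs, grid$load,
                      grid$ua, grid$fa, grid$wr, activity = grid$act)
  want <- mapply(oracle_final,
                 grid$neck, grid$trunk, grid$legs, grid$load,
                 grid$ua, grid$fa, grid$wr, grid$ua, grid$fa, grid$wr,
                 grid$act)
  expect_identical(got$final, as.integer(want))
  ## and with asymmetric arms the worse side carries
  set.seed(42)
  k <- sample(nrow(grid), 500)
  got2 <- compose_reba(grid$neck[k], grid$trunk[k], grid$legs[k], grid$load[k],
                       grid$ua[k], grid$fa[k], grid$wr[k],
                       rev(grid$ua[k]), rev(grid$fa[k]), rev(grid$wr[k]),
                       activity = grid$act[k])
  want2 <- mapply(oracle_final,
                  grid$neck[k], grid$trunk[k], grid$legs[k], grid$load[k],
                  grid$ua[k], grid$fa[k], grid$wr[k],
                  rev(grid$ua[k]), rev(grid$fa[k]), rev(grid$wr[k]),
                  grid$act[k])
  expect_identical(got2$final, as.integer(want2))
})

test_that("raising any single subscore never lowers the final score", {
  set.seed(11)
  base <- data.frame(neck = sample(1:3, 200, TRUE),
                     trunk = sample(1:5, 200, TRUE),
                     legs = sample(1:4, 200, TRUE),
                     load = sample(0:2, 200, TRUE),
                     ua = sample(1:6, 200, TRUE),
                     fa = sample(1:2, 200, TRUE),
                     wr = sample(1:3, 200, TRUE),
                     act = sample(0:2, 200, TRUE))
  f0 <- compose_reba(base$neck, base$trunk, base$legs, base$load,
                     base$ua, base$fa, base$wr, activity = base$act)$final
  caps <- c(neck = 3, trunk = 5, legs = 4, load = 2, ua = 6, fa = 2, wr = 3,
            act = 2)
  for (col in names(caps)) {
    up <- base
    up[[col]] <- pmin(up[[col]] + 1L, caps[[col]])
    f1 <- compose_reba(up$neck, up$trunk, up$legs, up$load,
                       up$ua, up$fa, up$wr, activity = up$act)$final
    expect_true(all(f1 >= f0), label = paste("monotone in", col))
  }
})

test_that("an all-neutral static standing recording scores the floor of 1 everywhere", {
  rec <- make_recording(n = 240 * 12, fs = 240)
  rs <- compute_reba_series(rec)
  expect_true(all(rs$scores$final == 1L))
  expect_true(all(rs$scores$table_c == 1L))
  ## the raw static flag itself is on (held posture), but not applied at
  ## the neutral floor
  expect_identical(score_activity(rec, rec$n_frames), 1L)
})

test_that("a deep plie posture lands in at least the medium risk band", {
  rec <- make_recording(
    n = 120, fs = 240,
    angles = list(jL5S1 = c(25, 0, 0), jLeftKnee = c(70, 0, 0),
                  jRightKnee = c(70, 0, 0)))
  rs <- compute_reba_series(rec)
  expect_true(all(rs$scores$final >= 4L))
})

test_that("landing accelerations of 11 g contribute a load score of 2", {
  n <- 120
  rec <- make_recording(n = n, fs = 240)
  accel <- rep(0, n); accel[60] <- 11 * 9.81
  load <- load_from_accel(accel, 240)
  rs <- compute_reba_series(rec, load = load)
  expect_identical(rs$scores$load_score[60], 2L)
  expect_identical(rs$scores$score_a[60], rs$scores$table_a[60] + 2L)
  expect_identical(rs$scores$load_score[10], 0L)
})

test_that("activity flags follow the windowed static/spectral criteria", {
  fs <- 60
  ## constant posture: static hold only
  rec <- make_recording(n = fs * 10, fs = fs)
  expect_identical(score_activity(rec, fs * 10), 1L)
  ## 8 Hz tone on every joint group: dynamic, not static
  t <- seq_len(fs * 10) / fs
  rec8 <- make_waveform_recording(30 * sin(2 * pi * 8 * t), fs)
  expect_identical(score_activity(rec8, fs * 10), 1L)
  fl <- rebamotion:::activity_flags_at(rebamotion:::activity_signals(rec8),
                                       fs, fs * 10, reba_config())
  expect_true(fl[["dynamic"]])
  expect_false(fl[["static"]])
  ## large-range noise band-limited below 2 Hz: neither flag
  set.seed(3)
  freqs <- runif(8, 0.2, 1.8)
  phases <- runif(8, 0, 2 * pi)
  w <- rowSums(sapply(seq_along(freqs),
                      function(k) sin(2 * pi * freqs[k] * t + phases[k])))
  w <- 40 * (w - min(w)) / diff(range(w))   # range exactly 40 deg
  recn <- make_waveform_recording(w, fs)
  expect_identical(score_activity(recn, fs * 10), 0L)
  expect_error(score_activity(rec, 10 * fs + 1L), "out of range")
})

test_that("the frame-wise series agrees with the scalar scorers on random postures", {
  set.seed(21)
  n <- 50
  rnd <- function(lo, hi) runif(n, lo, hi)
  angles <- list(
    jC1Head = cbind(rnd(-30, 40), rnd(-20, 20), rnd(-20, 20)),
    jL5S1 = cbind(rnd(-10, 30), rnd(-10, 10), rnd(-10, 10)),
    jLeftKnee = cbind(rnd(0, 90), 0, 0),
    jRightKnee = cbind(rnd(0, 90), 0, 0),
    jLeftShoulder = cbind(rnd(-40, 120), rnd(0, 60), 0),
    jLeftElbow = cbind(rnd(0, 130), 0, 0),
    jLeftWrist = cbind(rnd(-30, 30), rnd(-20, 20), rnd(-60, 60)))
  rec <- make_recording(n = n, fs = 240, angles = angles)
  rs <- compute_reba_series(rec)
  ja <- rec$joint_angles
  expect_identical(rs$scores$neck,
                   score_neck(ja$jC1Head[, 1], ja$jC1Head[, 3], ja$jC1Head[, 2]))
  trunk_f <- ja$jL5S1[, 1] + ja$jL4L3[, 1] + ja$jL1T12[, 1] + ja$jT1C7[, 1]
  trunk_r <- ja$jL5S1[, 3] + ja$jL4L3[, 3] + ja$jL1T12[, 3] + ja$jT1C7[, 3]
  trunk_l <- ja$jL5S1[, 2] + ja$jL4L3[, 2] + ja$jL1T12[, 2] + ja$jT1C7[, 2]
  expect_identical(rs$scores$trunk, score_trunk(trunk_f, trunk_r, trunk_l))
  expect_identical(rs$scores$legs,
                   score_legs(ja$jLeftKnee[, 1], ja$jRightKnee[, 1],
                              rec$foot_contact[, 1], rec$foot_contact[, 2]))
  expect_identical(rs$scores$upper_arm_left,
                   score_upper_arm(ja$jLeftShoulder[, 1], ja$jLeftShoulder[, 2],
                                   ja$jLeftT4Shoulder[, 1]))
  expect_identical(rs$scores$forearm_left, score_forearm(ja$jLeftElbow[, 1]))
  expect_identical(rs$scores$wrist_left,
                   score_wrist(ja$jLeftWrist[, 1], ja$jLeftWrist[, 3],
                               ja$jLeftWrist[, 2]))
  expect_true(all(rs$scores$final >= 1L & rs$scores$final <= 14L))
})
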