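#' Scoring configuration: every angular threshold of the adapted REBA scheme
#'
#' Returns the full set of tunable thresholds used by the frame-wise REBA
#' engine, with the published worksheet values as defaults. Any element can
#' be overridden by passing a named nested list, e.g.
#' `reba_config(trunk = list(neutral_tol_deg = 1))`.
#'
#' @param ... Named overrides merged into the defaults with
#'   [utils::modifyList()].
#' @return Nested list of thresholds (degrees unless stated otherwise).
#' @details The trunk "upright" band is a `neutral_tol_deg` tolerance around
#'   zero (an exact-zero band never fires on real signals). The load
#'   thresholds are vertical pelvic acceleration in units of g. The activity
#'   block holds the static-range / spectral criteria of the adapted
#'   activity score (see [score_activity()]).
#' @export
reba_config <- function(...) {
  cfg <- list(
    neck      = list(flex_lo = 0, flex_hi = 20, twist_deg = 10),
    trunk     = list(neutral_tol_deg = 2, flex_band1 = 20, flex_band2 = 60,
                     twist_deg = 10),
    legs      = list(knee_band1 = 30, knee_band2 = 60),
    load      = list(accel_g_1 = 5, accel_g_2 = 10),
    upper_arm = list(neutral = 20, flex_band2 = 45, flex_band3 = 90,
                     raise_deg = 10),
    forearm   = list(flex_lo = 60, flex_hi = 100),
    wrist     = list(neutral = 15, twist_deg = 10, deviation_deg = 45),
    activity  = list(window_s = 10, static_range_deg = 7.5, mpf_hz = 5,
                     rms_min_deg = 5, stride_s = 0.25)
  )
  ov <- list(...)
  if (length(ov)) cfg <- utils::modifyList(cfg, ov)
  cfg
}

check_finite <- function(..., .what = "angle") {
  for (x in list(...)) {
    if (!is.numeric(x) || anyNA(x) || any(!is.finite(x))) {
      stop("non-finite ", .what, " input", call. = FALSE)
    }
  }
  invisible(NULL)
}

## ---- per-body-part subscores (all vectorised over frames) -----------------

#' Neck subscore
#'
#' Base 1 for forward tilt in 0-20 deg, 2 for >20 deg or extension (<0 deg);
#' +1 (capped at one increment, since the worksheet neck range is 1-3 and
#' cannot absorb two) when the head is rotated or laterally tilted beyond
#' +-10 deg.
#'
#' @param flexion_deg,rotation_deg,lateral_deg Neck angles in degrees
#'   (flexion positive forward).
#' @param config A [reba_config()].
#' @return Integer vector in 1-3.
#' @export
#' @examples
#' score_neck(10, 0, 0)   # 1
#' score_neck(25, 0, 0)   # 2
#' score_neck(-5, 15, 0)  # 3
score_neck <- function(flexion_deg, rotation_deg = 0, lateral_deg = 0,
                       config = reba_config()) {
  check_finite(flexion_deg, rotation_deg, lateral_deg)
  th <- config$neck
  base <- ifelse(flexion_deg >= th$flex_lo & flexion_deg <= th$flex_hi, 1L, 2L)
  adj <- (abs(rotation_deg) > th$twist_deg | abs(lateral_deg) > th$twist_deg)
  pmin(base + as.integer(adj), 3L)
}

#' Trunk subscore
#'
#' The trunk angle is the summed flexion of the four spine joints (jL5S1,
#' jL4L3, jL1T12, jT1C7). Bands: upright (within `neutral_tol_deg` of zero)
#' 1; flexion or extension up to 20 deg 2; flexion 20-60 deg or extension
#' beyond 20 deg 3; flexion beyond 60 deg 4; +1 (capped) for rotation or
#' side bending beyond +-10 deg.
#'
#' @inheritParams score_neck
#' @param total_flexion_deg Summed spinal flexion (degrees).
#' @return Integer vector in 1-5.
#' @export
#' @examples
#' score_trunk(0, 0, 0)   # 1
#' score_trunk(70, 0, 0)  # 4
#' score_trunk(30, 12, 0) # 4
score_trunk <- function(total_flexion_deg, rotation_deg = 0, lateral_deg = 0,
                        config = reba_config()) {
  check_finite(total_flexion_deg, rotation_deg, lateral_deg)
  th <- config$trunk
  f <- total_flexion_deg
  base <- ifelse(abs(f) < th$neutral_tol_deg, 1L,
          ifelse(abs(f) <= th$flex_band1, 2L,
          ifelse(f > th$flex_band2, 4L, 3L)))
  adj <- (abs(rotation_deg) > th$twist_deg | abs(lateral_deg) > th$twist_deg)
  pmin(base + as.integer(adj), 5L)
}

#' Leg subscore
#'
#' Base 1 when both feet are in ground contact, 2 otherwise (one leg raised;
#' full flight is treated the same way, as maximally unstable support). Knee
#' flexion adds +1 per side in (30, 60] deg and +2 beyond 60 deg; the worse
#' side counts.
#'
#' @param knee_flex_left_deg,knee_flex_right_deg Knee flexion (degrees).
#' @param contact_left,contact_right Logical ground-contact flags.
#' @inheritParams score_neck
#' @return Integer vector in 1-4.
#' @export
#' @examples
#' score_legs(0, 0, TRUE, TRUE)    # 1
#' score_legs(65, 0, TRUE, FALSE)  # 4
#' score_legs(40, 40, TRUE, TRUE)  # 2
score_legs <- function(knee_flex_left_deg, knee_flex_right_deg,
                       contact_left, contact_right,
                       config = reba_config()) {
  check_finite(knee_flex_left_deg, knee_flex_right_deg)
  th <- config$legs
  base <- ifelse(contact_left & contact_right, 1L, 2L)
  adj <- function(k) as.integer(k > th$knee_band1) + as.integer(k > th$knee_band2)
  pmin(base + pmax(adj(knee_flex_left_deg), adj(knee_flex_right_deg)), 4L)
}

#' Load (force) subscore from vertical pelvic acceleration
#'
#' No external weight is carried when dancing, so the worksheet's static
#' load bands are replaced by the take-off/landing accelerations: +1 beyond
#' 5 g and +2 beyond 10 g of vertical pelvic acceleration.
#'
#' @param pelvic_accel_g Vertical pelvic acceleration magnitude in units of
#'   g.
#' @inheritParams score_neck
#' @return Integer vector in 0-2.
#' @export
#' @examples
#' score_load(c(0, 6, 11))  # 0 1 2
score_load <- function(pelvic_accel_g, config = reba_config()) {
  check_finite(pelvic_accel_g, .what = "acceleration")
  th <- config$load
  as.integer(pelvic_accel_g > th$accel_g_1) +
    as.integer(pelvic_accel_g > th$accel_g_2)
}

#' Upper-arm subscore
#'
#' Worksheet bands on shoulder elevation: -20..20 deg 1; extension beyond
#' -20 deg or flexion 20-45 deg 2; 45-90 deg 3; beyond 90 deg 4. Abduction
#' is mapped through the same bands (elevation in any plane is the scored
#' construct) and the worse of the two planes counts. +1 when the shoulder
#' girdle is raised (T4-shoulder flexion beyond 10 deg); no support credit
#' is given.
#'
#' @param flexion_deg,abduction_deg Shoulder angles (degrees).
#' @param shoulder_raise_deg T4-shoulder (girdle elevation) angle (degrees).
#' @inheritParams score_neck
#' @return Integer vector in 1-6.
#' @export
#' @examples
#' score_upper_arm(0, 0, 0)    # 1
#' score_upper_arm(100, 0, 0)  # 4
#' score_upper_arm(50, 0, 15)  # 4
score_upper_arm <- function(flexion_deg, abduction_deg = 0,
                            shoulder_raise_deg = 0,
                            config = reba_config()) {
  check_finite(flexion_deg, abduction_deg, shoulder_raise_deg)
  th <- config$upper_arm
  band <- function(f) {
    ifelse(f >= -th$neutral & f <= th$neutral, 1L,
    ifelse(f < -th$neutral, 2L,
    ifelse(f <= th$flex_band2, 2L,
    ifelse(f <= th$flex_band3, 3L, 4L))))
  }
  base <- pmax(band(flexion_deg), band(abs(abduction_deg)))
  pmin(base + as.integer(shoulder_raise_deg > th$raise_deg), 6L)
}

#' Forearm subscore
#'
#' 1 for elbow flexion in the 60-100 deg working range, 2 outside it.
#'
#' @param flexion_deg Elbow flexion (degrees).
#' @inheritParams score_neck
#' @return Integer vector in 1-2.
#' @export
score_forearm <- function(flexion_deg, config = reba_config()) {
  check_finite(flexion_deg)
  th <- config$forearm
  ifelse(flexion_deg >= th$flex_lo & flexion_deg <= th$flex_hi, 1L, 2L)
}

#' Wrist subscore
#'
#' Base 1 within +-15 deg flexion/extension, 2 beyond; +1 (capped, as the
#' Table B wrist dimension is 1-3) when rotated beyond +-10 deg or deviated
#' beyond +-45 deg.
#'
#' @param flexion_deg,rotation_deg,deviation_deg Wrist angles (degrees).
#' @inheritParams score_neck
#' @return Integer vector in 1-3.
#' @export
#' @examples
#' score_wrist(0, 0, 0)     # 1
#' score_wrist(20, 0, 0)    # 2
#' score_wrist(20, 20, 50)  # 3
score_wrist <- function(flexion_deg, rotation_deg = 0, deviation_deg = 0,
                        config = reba_config()) {
  check_finite(flexion_deg, rotation_deg, deviation_deg)
  th <- config$wrist
  base <- ifelse(abs(flexion_deg) <= th$neutral, 1L, 2L)
  adj <- (abs(rotation_deg) > th$twist_deg |
            abs(deviation_deg) > th$deviation_deg)
  pmin(base + as.integer(adj), 3L)
}

## ---- activity score -------------------------------------------------------

## Power-weighted mean frequency (Hz) of the linearly detrended signal, and
## its detrended RMS. DC is excluded.
mean_power_frequency <- function(x, fs) {
  n <- length(x)
  if (n < 4L) return(list(mpf = 0, rms = 0))
  t <- seq_len(n)
  x <- stats::residuals(stats::lm.fit(cbind(1, t), x))
  rms <- sqrt(mean(x^2))
  p <- Mod(stats::fft(x))^2
  k <- 2:(n %/% 2 + 1)                     # positive frequencies, no DC
  freq <- (k - 1) * fs / n
  pw <- p[k]
  tot <- sum(pw)
  mpf <- if (tot <= .Machine$double.eps * n) 0 else sum(freq * pw) / tot
  list(mpf = mpf, rms = rms)
}

## Signals examined by the activity criteria: per-group flexion channels.
activity_signals <- function(rec) {
  trunk_sum <- rec$joint_angles$jL5S1[, "flexion"] +
    rec$joint_angles$jL4L3[, "flexion"] +
    rec$joint_angles$jL1T12[, "flexion"] +
    rec$joint_angles$jT1C7[, "flexion"]
  c(list(trunk = trunk_sum),
    lapply(rec$joint_angles[c("jC1Head", "jLeftKnee", "jRightKnee",
                              "jLeftShoulder", "jRightShoulder",
                              "jLeftElbow", "jRightElbow",
                              "jLeftWrist", "jRightWrist")],
           function(m) m[, "flexion"]))
}

activity_flags_at <- function(signals, fs, frame_index, config) {
  th <- config$activity
  n <- length(signals[[1]])
  if (frame_index < 1L || frame_index > n) {
    stop("frame_index ", frame_index, " out of range 1..", n, call. = FALSE)
  }
  w <- max(2L, round(th$window_s * fs))
  idx <- max(1L, frame_index - w + 1L):frame_index
  rng <- vapply(signals, function(s) diff(range(s[idx])), 0)
  static <- any(rng <= th$static_range_deg)
  total <- Reduce(`+`, signals)
  sp <- mean_power_frequency(total[idx], fs)
  dynamic <- (sp$mpf > th$mpf_hz) && (sp$rms > th$rms_min_deg)
  c(static = static, dynamic = dynamic)
}

#' Activity subscore at one frame
#'
#' The worksheet's activity adjustments are evaluated over the trailing
#' `window_s` seconds (truncated at the start of the recording): +1 when at
#' least one scored joint group's flexion range over the window is no more
#' than 7.5 deg (a static hold), and +1 when the power-weighted mean
#' frequency of the detrended, summed joint-flexion signal exceeds 5 Hz
#' (rapid, repeated posture change). The spectral flag additionally
#' requires a minimal movement amplitude (detrended RMS above
#' `rms_min_deg`) so that sensor noise on a still posture cannot register
#' as dynamic activity.
#'
#' @param recording A [motion_recording()].
#' @param frame_index Frame at which to evaluate (1-based).
#' @param window_s Trailing window length in seconds.
#' @param config A [reba_config()].
#' @return Integer 0-2 (static flag + dynamic flag).
#' @export
score_activity <- function(recording, frame_index, window_s = 10,
                           config = reba_config()) {
  validate_motion_recording(recording)
  config$activity$window_s <- window_s
  fl <- activity_flags_at(activity_signals(recording),
                          recording$sample_rate_hz, frame_index, config)
  as.integer(fl["static"]) + as.integer(fl["dynamic"])
}

## Trailing-window running max/min in O(n) (block prefix/suffix scan).
run_extreme <- function(x, w, maximum = TRUE) {
  n <- length(x)
  cumf <- if (maximum) cummax else cummin
  if (w >= n) return(cumf(x))
  fill <- if (maximum) -Inf else Inf
  m <- ceiling(n / w) * w
  blk <- matrix(c(x, rep(fill, m - n)), nrow = w)
  left <- as.vector(apply(blk, 2L, cumf))
  right <- blk[w:1, , drop = FALSE]
  right <- apply(right, 2L, cumf)[w:1, , drop = FALSE]
  right <- as.vector(right)
  res <- numeric(n)
  res[1:(w - 1L)] <- left[1:(w - 1L)]
  i <- w:n
  res[i] <- if (maximum) pmax(right[i - w + 1L], left[i])
            else pmin(right[i - w + 1L], left[i])
  res
}

## Per-frame activity flags for a whole recording. The static flag is exact
## per frame (running range); the spectral flag is evaluated every
## `stride_s` seconds and held constant in between.
activity_flags_series <- function(rec, config) {
  th <- config$activity
  fs <- rec$sample_rate_hz
  n <- rec$n_frames
  w <- max(2L, round(th$window_s * fs))
  signals <- activity_signals(rec)
  static <- rep(FALSE, n)
  for (s in signals) {
    rng <- run_extreme(s, w, TRUE) - run_extreme(s, w, FALSE)
    static <- static | (rng <= th$static_range_deg)
    if (all(static)) break
  }
  total <- Reduce(`+`, signals)
  stride <- max(1L, round(th$stride_s * fs))
  eval_at <- unique(c(seq(1L, n, by = stride), n))
  dyn_at <- vapply(eval_at, function(i) {
    idx <- max(1L, i - w + 1L):i
    sp <- mean_power_frequency(total[idx], fs)
    (sp$mpf > th$mpf_hz) && (sp$rms > th$rms_min_deg)
  }, TRUE)
  dynamic <- dyn_at[findInterval(seq_len(n), eval_at)]
  cbind(static = static, dynamic = dynamic)
}

## ---- composition ----------------------------------------------------------

#' Compose a final REBA score from its subscores
#'
#' Runs the worksheet table path: Table A on (neck, trunk, legs); Score A =
#' Table A + load; Table B per arm with the worse side carried forward as
#' Score B (the coupling score is fixed at 0: nothing is held when
#' dancing); Table C on (Score A, Score B); final = Table C + activity.
#'
#' @param neck,trunk,legs,load_score Body subscores (see the `score_*`
#'   functions).
#' @param upper_arm_left,forearm_left,wrist_left Left arm-chain subscores.
#' @param upper_arm_right,forearm_right,wrist_right Right arm-chain
#'   subscores.
#' @param activity Activity subscore, 0-2.
#' @return A data.frame with columns `table_a`, `score_a`, `table_b_left`,
#'   `table_b_right`, `score_b`, `table_c`, `final`. Vectorised.
#' @export
compose_reba <- function(neck, trunk, legs, load_score,
                         upper_arm_left, forearm_left, wrist_left,
                         upper_arm_right = upper_arm_left,
                         forearm_right = forearm_left,
                         wrist_right = wrist_left,
                         activity = 0L) {
  load_score <- check_index(load_score, 0, 2, "load_score")
  activity <- check_index(activity, 0, 2, "activity")
  table_a <- lookup_table_a(neck, trunk, legs)
  score_a <- table_a + load_score
  table_b_left <- lookup_table_b(upper_arm_left, forearm_left, wrist_left)
  table_b_right <- lookup_table_b(upper_arm_right, forearm_right, wrist_right)
  score_b <- pmax(table_b_left, table_b_right)   # + coupling, fixed at 0
  table_c <- lookup_table_c(score_a, score_b)
  data.frame(table_a = table_a, score_a = score_a,
             table_b_left = table_b_left, table_b_right = table_b_right,
             score_b = score_b, table_c = table_c,
             final = table_c + activity)
}

#' Frame-wise REBA scoring of a motion recording
#'
#' Applies the adapted REBA scheme to every frame: neck from jC1Head; trunk
#' from the summed spine joints; legs from knee flexion and foot contacts;
#' the load score from the magnitude of the vertical pelvic acceleration (in
#' g); both arm chains (shoulder, T4-shoulder girdle, elbow, wrist) with the
#' worse side carried into Table B; and the windowed activity adjustments.
#'
#' The static activity increment is only applied on frames whose postural
#' score (Table C) exceeds 1: a neutral stance held still is not a static
#' working posture, so an all-neutral standing recording scores the scale
#' floor of 1 on every frame.
#'
#' @param recording A [motion_recording()].
#' @param load Optional [load_from_accel()] result aligned frame-wise with
#'   the recording; computed from the recording's pelvis trajectory via
#'   [pelvis_load()] when omitted.
#' @param config A [reba_config()].
#' @return A `reba_series`: list with a per-frame `scores` data.frame
#'   (subscores, table values, `final`) and the recording metadata.
#' @export
compute_reba_series <- function(recording, load = NULL,
                                config = reba_config()) {
  validate_motion_recording(recording)
  if (is.null(load)) {
    load <- pelvis_load(recording, gravity = 9.81)
  }
  if (length(load$accel_g) != recording$n_frames) {
    stop("load series length (", length(load$accel_g),
         ") does not match recording frames (", recording$n_frames, ")",
         call. = FALSE)
  }
  ja <- recording$joint_angles
  neck <- score_neck(ja$jC1Head[, "flexion"], ja$jC1Head[, "rotation"],
                     ja$jC1Head[, "abduction"], config)
  trunk_f <- ja$jL5S1[, "flexion"] + ja$jL4L3[, "flexion"] +
    ja$jL1T12[, "flexion"] + ja$jT1C7[, "flexion"]
  trunk_r <- ja$jL5S1[, "rotation"] + ja$jL4L3[, "rotation"] +
    ja$jL1T12[, "rotation"] + ja$jT1C7[, "rotation"]
  trunk_l <- ja$jL5S1[, "abduction"] + ja$jL4L3[, "abduction"] +
    ja$jL1T12[, "abduction"] + ja$jT1C7[, "abduction"]
  trunk <- score_trunk(trunk_f, trunk_r, trunk_l, config)
  legs <- score_legs(ja$jLeftKnee[, "flexion"], ja$jRightKnee[, "flexion"],
                     recording$foot_contact[, "left"],
                     recording$foot_contact[, "right"], config)
  load_score <- score_load(abs(load$accel_g), config)
  arm <- function(side) {
    sh <- ja[[paste0("j", side, "Shoulder")]]
    t4 <- ja[[paste0("j", side, "T4Shoulder")]]
    el <- ja[[paste0("j", side, "Elbow")]]
    wr <- ja[[paste0("j", side, "Wrist")]]
    list(
      upper_arm = score_upper_arm(sh[, "flexion"], sh[, "abduction"],
                                  t4[, "flexion"], config),
      forearm = score_forearm(el[, "flexion"], config),
      wrist = score_wrist(wr[, "flexion"], wr[, "rotation"],
                          wr[, "abduction"], config))
  }
  left <- arm("Left")
  right <- arm("Right")
  flags <- activity_flags_series(recording, config)
  comp <- compose_reba(neck, trunk, legs, load_score,
                       left$upper_arm, left$forearm, left$wrist,
                       right$upper_arm, right$forearm, right$wrist,
                       activity = 0L)
  ## static increment suppressed on neutral-posture frames (table_c == 1)
  activity <- as.integer(flags[, "dynamic"]) +
    as.integer(flags[, "static"] & comp$table_c > 1L)
  scores <- data.frame(
    frame = seq_len(recording$n_frames),
    neck = neck, trunk = trunk, legs = legs,
    table_a = comp$table_a, load_score = load_score, score_a = comp$score_a,
    upper_arm_left = left$upper_arm, forearm_left = left$forearm,
    wrist_left = left$wrist,
    upper_arm_right = right$upper_arm, forearm_right = right$forearm,
    wrist_right = right$wrist,
    table_b_left = comp$table_b_left, table_b_right = comp$table_b_right,
    score_b = comp$score_b, table_c = comp$table_c,
    static_flag = flags[, "static"], dynamic_flag = flags[, "dynamic"],
    activity = activity,
    final = comp$table_c + activity)
  structure(
    list(scores = scores,
         n_frames = recording$n_frames,
         sample_rate_hz = recording$sample_rate_hz,
         subject_id = recording$subject_id,
         gender = recording$gender,
         sequence_label = recording$sequence_label,
         phase = recording$phase),
    class = "reba_series")
}

#' @export
print.reba_series <- function(x, ...) {
  cat("<reba_series> ", x$sequence_label, " (phase ", x$phase, ", ",
      x$subject_id, "): ", x$n_frames, " frames\n", sep = "")
  cat(sprintf("  final score: mean %.2f, range %d-%d\n",
              mean(x$scores$final), min(x$scores$final), max(x$scores$final)))
  invisible(x)
}

#' @export
summary.reba_series <- function(object, ...) {
  print(object)
  tab <- table(factor(object$scores$final, levels = 1:14))
  rel <- as.numeric(tab) / object$n_frames
  df <- data.frame(score = 1:14, rel_freq = round(rel, 4))
  print(df[df$rel_freq > 0, ], row.names = FALSE)
  invisible(df)
}
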