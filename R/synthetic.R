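#' Specify a synthetic movement sequence
#'
#' A `sequence_spec` scripts one movement sequence for the synthetic motion
#' generator: a base posture, optional timed posture targets with smooth
#' transitions, optional joint oscillations, an optional jump program
#' (ballistic pelvis arcs with push-off/landing transients), an optional
#' single-support episode and an optional continuous spin. The generator
#' turns the spec into a [motion_recording()] plus its frame-wise ground
#' truth.
#'
#' @param label Sequence label (matched against training-plan rows).
#' @param phase Training phase 1-3.
#' @param duration_s Sequence duration in seconds.
#' @param posture Named list `joint -> c(flexion, abduction, rotation)`
#'   (degrees); unnamed joints stay neutral (0, 0, 0).
#' @param keyframes Optional list of timed posture targets, each
#'   `list(at = <s>, transition_s = <s>, angles = list(joint = c(f, a, r)))`;
#'   the target is reached through a raised-cosine ramp starting at `at`.
#' @param oscillation Optional list of oscillations, each
#'   `list(joint, dof, amplitude_deg, freq_hz, center_deg = 0)`. A single
#'   oscillation may be given unnested.
#' @param jumps Optional jump program
#'   `list(n, flight_time_s, landing_peak_g = 2)`: `n` evenly spaced jump
#'   cycles, each with an exact parabolic flight arc of `flight_time_s`
#'   seconds and raised-cosine push-off/landing acceleration transients
#'   peaking at `landing_peak_g` g.
#' @param single_support Optional fraction of the sequence (centred) spent
#'   with the right foot raised.
#' @param spin Optional `list(joint = "jC1Head", rate_dps = 360)` continuous
#'   (unwrapped) rotation ramp.
#' @param static_hold_fraction Fraction of the sequence tail during which
#'   oscillations are gated off (a held balance).
#' @param offset Named list `joint -> c(f, a, r)` added to every set-point
#'   (used for gender and subject posture offsets).
#' @param seed Optional integer seed used by [generate_sequence()].
#' @return A `sequence_spec`.
#' @export
sequence_spec <- function(label, phase = 1L, duration_s = 10,
                          posture = list(), keyframes = list(),
                          oscillation = list(), jumps = NULL,
                          single_support = 0, spin = NULL,
                          static_hold_fraction = 0, offset = list(),
                          seed = NULL) {
  if (duration_s <= 0) stop("duration_s must be > 0", call. = FALSE)
  if (static_hold_fraction < 0 || static_hold_fraction > 1) {
    stop("static_hold_fraction must be in [0, 1]", call. = FALSE)
  }
  if (length(oscillation) && !is.null(oscillation$joint)) {
    oscillation <- list(oscillation)
  }
  for (o in oscillation) {
    if ((o$amplitude_deg %||% 0) < 0) {
      stop("oscillation amplitudes must be >= 0", call. = FALSE)
    }
  }
  if (!is.null(jumps)) {
    jumps$landing_peak_g <- jumps$landing_peak_g %||% 2
    if (jumps$n < 1 || jumps$flight_time_s <= 0) {
      stop("jump program needs n >= 1 and flight_time_s > 0", call. = FALSE)
    }
    cycle <- duration_s / jumps$n
    if (jumps$flight_time_s >= cycle) {
      stop("inconsistent jump program: flight time ", jumps$flight_time_s,
           " s does not fit the ", round(cycle, 3), " s jump cycle",
           call. = FALSE)
    }
  }
  structure(
    list(label = label, phase = as.integer(phase), duration_s = duration_s,
         posture = posture, keyframes = keyframes, oscillation = oscillation,
         jumps = jumps, single_support = single_support, spin = spin,
         static_hold_fraction = static_hold_fraction, offset = offset,
         seed = seed),
    class = "sequence_spec")
}

## Closed-form pelvis trajectory for a jump program: rest - raised-cosine
## push-off - exact parabola - raised-cosine landing - rest, one cycle per
## jump, centred within its cycle. Returns z (m) and the in-flight mask.
jump_trajectory <- function(t, duration_s, jumps, z0 = 0.95, gravity = 9.81) {
  n_j <- jumps$n
  tf <- jumps$flight_time_s
  v0 <- gravity * tf / 2
  a_pk <- jumps$landing_peak_g * gravity
  tc <- 2 * v0 / a_pk
  cycle <- duration_s / n_j
  if (tf + 2 * tc >= cycle) {
    stop("inconsistent jump program: flight ", tf, " s + transients ",
         round(2 * tc, 3), " s exceed the ", round(cycle, 3), " s cycle",
         call. = FALSE)
  }
  lead <- (cycle - tf - 2 * tc) / 2
  tau_c <- t %% cycle                    # time within cycle
  z <- rep(z0, length(t))
  flight <- rep(FALSE, length(t))
  hann_z <- function(tau) {              # double integral of the hann pulse
    (a_pk / 2) * (tau^2 / 2 + (cos(2 * pi * tau / tc) - 1) * tc^2 / (4 * pi^2))
  }
  z_to <- z0 + v0 * tc / 2               # take-off height
  push <- tau_c >= lead & tau_c < lead + tc
  z[push] <- z0 + hann_z(tau_c[push] - lead)
  fl <- tau_c >= lead + tc & tau_c <= lead + tc + tf
  tau <- tau_c[fl] - (lead + tc)
  z[fl] <- z_to + v0 * tau - gravity * tau^2 / 2
  flight[tau_c > lead + tc & tau_c < lead + tc + tf] <- TRUE
  land <- tau_c > lead + tc + tf & tau_c < lead + 2 * tc + tf
  tau <- tau_c[land] - (lead + tc + tf)
  z[land] <- z_to - v0 * tau + hann_z(tau)
  list(z = z, flight = flight)
}

raised_cosine_gate <- function(t, t_off, roll_s = 0.5) {
  g <- rep(1, length(t))
  ramp <- t >= t_off & t < t_off + roll_s
  g[ramp] <- (1 + cos(pi * (t[ramp] - t_off) / roll_s)) / 2
  g[t >= t_off + roll_s] <- 0
  g
}

#' Generate a synthetic motion recording from a sequence spec
#'
#' Builds noiseless per-frame set-points from the spec (posture, keyframe
#' ramps, oscillations, spin), a pelvis trajectory (constant standing
#' height, or ballistic jump arcs when a jump program is given) and foot
#' contacts (false exactly during flight; right foot raised during a
#' single-support episode). Ground truth is the frame-wise REBA and load
#' evaluation of the noiseless signals; the returned recording adds
#' independent Gaussian angle noise.
#'
#' @param spec A [sequence_spec()].
#' @param sample_rate_hz Sampling rate (Hz).
#' @param noise_sd_deg Angle noise standard deviation (degrees); well below
#'   the +-2 deg accuracy of suit-based inertial capture.
#' @param gender,subject_id Metadata for the recording.
#' @param z0_m Standing pelvis height (m).
#' @param gravity Gravitational acceleration (m/s^2).
#' @param seed Integer seed; defaults to the spec's `seed`.
#' @return `list(recording, truth)` where `truth` is
#'   `list(reba, load, flight)`: the noiseless [compute_reba_series()]
#'   result, the noiseless `load_series` and the intended flight mask.
#' @export
generate_sequence <- function(spec, sample_rate_hz = 240, noise_sd_deg = 0.5,
                              gender = c("female", "male"),
                              subject_id = "synthetic", z0_m = 0.95,
                              gravity = 9.81, seed = spec$seed) {
  stopifnot(inherits(spec, "sequence_spec"))
  gender <- match.arg(gender)
  if (!is.null(seed)) set.seed(as.integer(seed))
  n <- max(3L, round(spec$duration_s * sample_rate_hz))
  t <- (seq_len(n) - 1L) / sample_rate_hz

  ## noiseless set-points
  ang <- lapply(REQUIRED_JOINTS, function(j) {
    base <- spec$posture[[j]] %||% c(0, 0, 0)
    off <- spec$offset[[j]] %||% c(0, 0, 0)
    m <- matrix(rep(base + off, each = n), ncol = 3L,
                dimnames = list(NULL, ANGLE_DOFS))
    m
  })
  names(ang) <- REQUIRED_JOINTS
  for (kf in spec$keyframes) {
    tr <- kf$transition_s %||% 0.5
    for (j in names(kf$angles)) {
      target <- kf$angles[[j]] + (spec$offset[[j]] %||% c(0, 0, 0))
      for (d in 1:3) {
        cur <- ang[[j]][, d]
        prev <- cur[max(1L, sum(t < kf$at))]
        ramp <- t >= kf$at & t < kf$at + tr
        after <- t >= kf$at + tr
        cur[ramp] <- prev + (target[d] - prev) *
          (1 - cos(pi * (t[ramp] - kf$at) / tr)) / 2
        cur[after] <- target[d]
        ang[[j]][, d] <- cur
      }
    }
  }
  gate <- if (spec$static_hold_fraction > 0) {
    raised_cosine_gate(t, (1 - spec$static_hold_fraction) * spec$duration_s)
  } else rep(1, n)
  for (o in spec$oscillation) {
    d <- o$dof %||% "flexion"
    wave <- (o$center_deg %||% 0) +
      o$amplitude_deg * sin(2 * pi * o$freq_hz * t) * gate
    ang[[o$joint]][, d] <- ang[[o$joint]][, d] + wave
  }
  if (!is.null(spec$spin)) {
    j <- spec$spin$joint %||% "jC1Head"
    ang[[j]][, "rotation"] <- ang[[j]][, "rotation"] + spec$spin$rate_dps * t
  }

  ## pelvis + contacts
  if (!is.null(spec$jumps)) {
    traj <- jump_trajectory(t, spec$duration_s, spec$jumps, z0 = z0_m,
                            gravity = gravity)
    z <- traj$z
    flight <- traj$flight
  } else {
    z <- rep(z0_m, n)
    flight <- rep(FALSE, n)
  }
  contact <- cbind(left = !flight, right = !flight)
  if (spec$single_support > 0) {
    half <- spec$single_support * spec$duration_s / 2
    mid <- spec$duration_s / 2
    contact[t >= mid - half & t < mid + half, "right"] <- FALSE
  }

  make_rec <- function(a) motion_recording(
    joint_angles = a, pelvis_z_m = z, foot_contact = contact,
    sample_rate_hz = sample_rate_hz, subject_id = subject_id,
    gender = gender, sequence_label = spec$label, phase = spec$phase)

  clean <- make_rec(ang)
  truth_load <- pelvis_load(clean, gravity = gravity)
  truth_reba <- compute_reba_series(clean, load = truth_load)
  noisy <- if (noise_sd_deg > 0) {
    make_rec(lapply(ang, function(m) m + matrix(
      stats::rnorm(length(m), sd = noise_sd_deg), nrow = n)))
  } else clean
  list(recording = noisy,
       truth = list(reba = truth_reba, load = truth_load, flight = flight))
}

## ---- default posture programs --------------------------------------------

## Stylised kinematic sketches of the named classical elements -- set-points
## and oscillation rates chosen to exercise the scoring bands, not
## biomechanically validated choreography. Arms default to a rounded low
## carriage (shoulders ~30 deg elevation, elbows ~45 deg).
ballet_arms <- function(shoulder_flex = 30, elbow_flex = 45) {
  list(
    jLeftShoulder = c(shoulder_flex, 15, 0),
    jRightShoulder = c(shoulder_flex, 15, 0),
    jLeftElbow = c(elbow_flex, 0, 0),
    jRightElbow = c(elbow_flex, 0, 0),
    jLeftWrist = c(5, 0, 0),
    jRightWrist = c(5, 0, 0))
}

trunk_posture <- function(total_flex = 0, total_lat = 0) {
  ## distribute a summed spinal angle over the four scored joints
  w <- c(jL5S1 = 0.4, jL4L3 = 0.3, jL1T12 = 0.2, jT1C7 = 0.1)
  lapply(w, function(wi) c(total_flex * wi, total_lat * wi, 0))
}

#' Default posture program for a plan row label
#'
#' Returns the generator [sequence_spec()] for one of the default
#' training-plan labels (see [default_training_plan()]); unknown labels get
#' a generic program for their phase.
#'
#' @param label Plan row label.
#' @param phase Training phase (used for unknown labels).
#' @param duration_s Sequence duration in seconds.
#' @return A [sequence_spec()].
#' @export
default_sequence_spec <- function(label, phase = 1L, duration_s = 10) {
  arms <- ballet_arms()
  ## head carried with a slight forward gaze so the neck set-point sits
  ## inside the neutral band rather than on its exact edge
  head <- list(jC1Head = c(8, 0, 0))
  base <- function(trunk_flex = 10, ...) {
    c(trunk_posture(trunk_flex), arms, head, list(...))
  }
  ## phase-3 jump rows aim at ~20% of the sequence in flight; short
  ## (compressed) sequences get proportionally shorter flight arcs so the
  ## program still fits
  jumps_for <- function(flight_s, peak_g, frac = 0.20) {
    fl <- min(flight_s, frac * duration_s)
    list(n = max(1L, round(frac * duration_s / fl)),
         flight_time_s = fl, landing_peak_g = peak_g)
  }
  spec <- switch(
    label,
    plie_right = ,
    plie_left = sequence_spec(
      label, 1L, duration_s, posture = base(15),
      oscillation = list(
        list(joint = "jLeftKnee", dof = "flexion", amplitude_deg = 40,
             freq_hz = 0.2, center_deg = 40),
        list(joint = "jRightKnee", dof = "flexion", amplitude_deg = 40,
             freq_hz = 0.2, center_deg = 40)),
      static_hold_fraction = 0.1),
    ronds_de_jambe_right = ,
    ronds_de_jambe_left = sequence_spec(
      label, 1L, duration_s, posture = base(10),
      oscillation = list(
        list(joint = "jL5S1", dof = "rotation", amplitude_deg = 12,
             freq_hz = 0.3),
        list(joint = "jLeftShoulder", dof = "flexion", amplitude_deg = 30,
             freq_hz = 0.25, center_deg = 20)),
      static_hold_fraction = 0.15),
    battement_frappe = sequence_spec(
      label, 1L, duration_s, posture = base(8),
      oscillation = list(
        list(joint = "jRightKnee", dof = "flexion", amplitude_deg = 30,
             freq_hz = 2, center_deg = 35))),
    adagio_fondu_developpe = sequence_spec(
      label, 1L, duration_s, posture = base(12),
      oscillation = list(
        list(joint = "jLeftKnee", dof = "flexion", amplitude_deg = 35,
             freq_hz = 0.15, center_deg = 40)),
      single_support = 0.4, static_hold_fraction = 0.1),
    grand_battement = sequence_spec(
      label, 1L, duration_s, posture = base(10),
      oscillation = list(
        list(joint = "jL5S1", dof = "flexion", amplitude_deg = 8,
             freq_hz = 0.8, center_deg = 0),
        list(joint = "jRightKnee", dof = "flexion", amplitude_deg = 20,
             freq_hz = 0.8, center_deg = 15)),
      single_support = 0.3),
    port_de_bras_adagio = sequence_spec(
      label, 2L, duration_s,
      posture = c(trunk_posture(10), ballet_arms(70, 40), head),
      keyframes = list(
        list(at = duration_s * 0.25, transition_s = 2,
             angles = trunk_posture(55)),
        list(at = duration_s * 0.55, transition_s = 2,
             angles = trunk_posture(10))),
      oscillation = list(
        list(joint = "jLeftShoulder", dof = "abduction", amplitude_deg = 25,
             freq_hz = 0.2, center_deg = 20)),
      static_hold_fraction = 0.1),
    pirouettes_right = ,
    pirouettes_left = sequence_spec(
      label, 2L, duration_s, posture = base(8),
      oscillation = list(
        list(joint = "jLeftKnee", dof = "flexion", amplitude_deg = 30,
             freq_hz = 0.5, center_deg = 45)),
      spin = list(joint = "jC1Head", rate_dps = 360),
      single_support = 0.5),
    warmup_jumps = ,
    warmup_pointe = sequence_spec(
      label, 3L, duration_s, posture = base(8),
      jumps = jumps_for(0.25, 1.8),
      oscillation = list(
        list(joint = "jLeftKnee", dof = "flexion", amplitude_deg = 25,
             freq_hz = 1.5, center_deg = 25),
        list(joint = "jRightKnee", dof = "flexion", amplitude_deg = 25,
             freq_hz = 1.5, center_deg = 25))),
    jetes_glissades = ,
    batterie = sequence_spec(
      label, 3L, duration_s, posture = base(10),
      jumps = jumps_for(0.30, 2.2),
      oscillation = list(
        list(joint = "jLeftKnee", dof = "flexion", amplitude_deg = 30,
             freq_hz = 1.2, center_deg = 30),
        list(joint = "jRightKnee", dof = "flexion", amplitude_deg = 30,
             freq_hz = 1.2, center_deg = 30))),
    grand_allegro_right = ,
    grand_allegro_left = ,
    grand_allegro_manege = sequence_spec(
      label, 3L, duration_s, posture = base(12),
      jumps = jumps_for(0.40, 2.6),
      oscillation = list(
        list(joint = "jLeftKnee", dof = "flexion", amplitude_deg = 35,
             freq_hz = 0.9, center_deg = 35),
        list(joint = "jRightKnee", dof = "flexion", amplitude_deg = 35,
             freq_hz = 0.9, center_deg = 35))),
    manege_demi_pointe_right = ,
    manege_demi_pointe_left = ,
    manege_pointe_right = sequence_spec(
      label, 3L, duration_s, posture = base(8),
      spin = list(joint = "jC1Head", rate_dps = 540),
      single_support = 0.4,
      oscillation = list(
        list(joint = "jRightKnee", dof = "flexion", amplitude_deg = 25,
             freq_hz = 1.5, center_deg = 30))),
    ## generic fallback per phase
    sequence_spec(label, phase, duration_s, posture = base(10),
                  jumps = if (phase == 3L) jumps_for(0.30, 2.2) else NULL,
                  oscillation = list(
                    list(joint = "jLeftKnee", dof = "flexion",
                         amplitude_deg = 25,
                         freq_hz = if (phase == 3L) 1.2 else 0.3,
                         center_deg = 30)))
  )
  spec$phase <- as.integer(phase)
  spec
}

#' Apply a posture offset to a set of sequence specs
#'
#' Adds a fixed angular offset to the named joint/DoF of every spec in the
#' set, so that two groups generated from offset and non-offset spec sets
#' differ by a known amount with a known effect direction.
#'
#' @param specs List of [sequence_spec()] objects.
#' @param effect `list(joint, dof, delta_deg)`; `dof` is one of
#'   `"flexion"`, `"abduction"`, `"rotation"`.
#' @return The spec set with offsets applied.
#' @seealso [delta_from_offset()] for the closed-form Cliff's delta implied
#'   by a given offset under Gaussian subject variation.
#' @export
inject_gender_effect <- function(specs, effect) {
  if (is.null(effect) || (effect$delta_deg %||% 0) == 0) return(specs)
  d <- match(effect$dof %||% "flexion", ANGLE_DOFS)
  if (is.na(d)) stop("unknown dof in effect config", call. = FALSE)
  lapply(specs, function(sp) {
    off <- sp$offset[[effect$joint]] %||% c(0, 0, 0)
    off[d] <- off[d] + effect$delta_deg
    sp$offset[[effect$joint]] <- off
    sp
  })
}

#' Cliff's delta implied by a location offset between two Gaussian groups
#'
#' For subject-level summaries distributed `N(mu, sd)` and `N(mu + offset,
#' sd)`, `delta = 2 * pnorm(offset / (sd * sqrt(2))) - 1`. Used by the
#' generator to script effects with a known true effect size.
#'
#' @param offset Location difference between the groups.
#' @param sd Common within-group standard deviation.
#' @return Cliff's delta in `(-1, 1)`.
#' @export
delta_from_offset <- function(offset, sd) {
  2 * stats::pnorm(offset / (sd * sqrt(2))) - 1
}

#' @rdname delta_from_offset
#' @param delta Target Cliff's delta.
#' @return `offset_for_delta`: the location offset achieving `delta`.
#' @export
offset_for_delta <- function(delta, sd) {
  stats::qnorm((delta + 1) / 2) * sd * sqrt(2)
}

#' Generate one subject's full training session
#'
#' Emits one recording per plan row applicable to the gender, honouring the
#' row durations (optionally compressed by `time_scale` for desk-scale
#' work) and the gender-specific rows (pointe work female-only, the closing
#' manege jumps male-only). Deterministic under a fixed seed.
#'
#' @param plan A [training_plan()].
#' @param gender `"female"` or `"male"`.
#' @param seed Integer seed.
#' @param subject_id Subject identifier.
#' @param sample_rate_hz Sampling rate (Hz).
#' @param time_scale Multiplier on row durations (1 = the printed plan).
#' @param noise_sd_deg Angle noise SD (degrees).
#' @param effect Optional gender effect `list(joint, dof, delta_deg)`
#'   applied to female subjects (see [inject_gender_effect()]).
#' @param subject_offset_deg Scalar posture offset (degrees, on the jL5S1
#'   flexion set-point) representing this subject's habitual posture.
#' @return List with one `list(recording, truth)` per plan row.
#' @export
generate_session <- function(plan, gender = c("female", "male"), seed = 1L,
                             subject_id = "S01", sample_rate_hz = 240,
                             time_scale = 1, noise_sd_deg = 0.5,
                             effect = NULL, subject_offset_deg = 0) {
  gender <- match.arg(gender)
  rows <- plan_for_gender(plan, gender)
  specs <- lapply(seq_len(nrow(rows)), function(i) {
    default_sequence_spec(rows$label[i], rows$phase[i],
                          rows$duration_s[i] * time_scale)
  })
  if (!is.null(effect) && gender == "female") {
    specs <- inject_gender_effect(specs, effect)
  }
  if (subject_offset_deg != 0) {
    specs <- inject_gender_effect(
      specs, list(joint = "jL5S1", dof = "flexion",
                  delta_deg = subject_offset_deg))
  }
  lapply(seq_along(specs), function(i) {
    generate_sequence(specs[[i]], sample_rate_hz = sample_rate_hz,
                      noise_sd_deg = noise_sd_deg, gender = gender,
                      subject_id = subject_id,
                      seed = as.integer(seed) + 1000L * i)
  })
}

#' Generate a whole two-gender study
#'
#' One session per subject (default 16 female, 12 male, as in a typical
#' two-company ensemble study), with per-subject posture offsets drawn from
#' `N(0, subject_sd_deg)` and an optional scripted gender effect.
#'
#' @inheritParams generate_session
#' @param n_female,n_male Number of subjects per gender.
#' @param subject_sd_deg SD of the per-subject trunk posture offset
#'   (degrees).
#' @return List with elements `recordings` (flat list of
#'   [motion_recording()]s) and `truths` (matching ground-truth list).
#' @export
generate_study <- function(plan, n_female = 16L, n_male = 12L, seed = 1L,
                           sample_rate_hz = 240, time_scale = 1,
                           noise_sd_deg = 0.5, effect = NULL,
                           subject_sd_deg = 2) {
  set.seed(as.integer(seed))
  subjects <- data.frame(
    id = sprintf("%s%02d", rep(c("F", "M"), c(n_female, n_male)),
                 c(seq_len(n_female), seq_len(n_male))),
    gender = rep(c("female", "male"), c(n_female, n_male)),
    offset = stats::rnorm(n_female + n_male, sd = subject_sd_deg),
    seed = sample.int(1e6, n_female + n_male))
  out <- lapply(seq_len(nrow(subjects)), function(i) {
    generate_session(plan, subjects$gender[i], seed = subjects$seed[i],
                     subject_id = subjects$id[i],
                     sample_rate_hz = sample_rate_hz,
                     time_scale = time_scale, noise_sd_deg = noise_sd_deg,
                     effect = effect,
                     subject_offset_deg = subjects$offset[i])
  })
  list(recordings = unlist(lapply(out, lapply, `[[`, "recording"),
                           recursive = FALSE),
       truths = unlist(lapply(out, lapply, `[[`, "truth"),
                       recursive = FALSE))
}

#' Draw subject-level summary scores for the two genders
#'
#' The generator's closed-form subject model: a subject's
#' duration-weighted summary score is its group mean plus a Gaussian
#' subject offset. Used for statistical calibration at study scale (the
#' full motion synthesis is exercised separately); with `delta_deg = 0` the
#' two groups are exchangeable.
#'
#' @param n_a,n_b Group sizes (convention: a = male, b = female).
#' @param delta_deg Location shift added to group b.
#' @param subject_sd SD of the subject offsets.
#' @param base Common group mean.
#' @return `list(a, b)` numeric vectors.
#' @export
simulate_subject_scores <- function(n_a, n_b, delta_deg = 0, subject_sd = 2,
                                    base = 6) {
  list(a = base + stats::rnorm(n_a, sd = subject_sd),
       b = base + delta_deg + stats::rnorm(n_b, sd = subject_sd))
}
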