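#' @keywords internal
"_PACKAGE"

## Canonical joint set required for whole-body REBA scoring. Angle triplets
## are (flexion, abduction, rotation) in degrees; flexion positive,
## extension negative; right-ward lateral bend / rotation positive.
REQUIRED_JOINTS <- c(
  "jC1Head", "jT1C7", "jL1T12", "jL4L3", "jL5S1",
  "jLeftShoulder", "jRightShoulder",
  "jLeftT4Shoulder", "jRightT4Shoulder",
  "jLeftElbow", "jRightElbow",
  "jLeftWrist", "jRightWrist",
  "jLeftKnee", "jRightKnee"
)

ANGLE_DOFS <- c("flexion", "abduction", "rotation")

## Known spelling variants in circulating REBA/Xsens materials, mapped to the
## canonical Xsens joint labels.
JOINT_ALIASES <- c(
  jLeftMWUist  = "jLeftWrist",
  jRightMWUist = "jRightWrist",
  jL1ST12      = "jL1T12"
)

#' Normalise a joint name to its canonical Xsens label
#'
#' Accepts the canonical Xsens labels (e.g. `jLeftWrist`) as well as the
#' spelling variants that appear in some published materials
#' (`jLeftMWUist`, `jRightMWUist`, `jL1ST12`) and returns the canonical
#' form.
#'
#' @param joint Character vector of joint names.
#' @return Character vector of canonical joint names.
#' @export
#' @examples
#' normalize_joint_name(c("jLeftMWUist", "jLeftKnee"))
normalize_joint_name <- function(joint) {
  stopifnot(is.character(joint))
  hit <- joint %in% names(JOINT_ALIASES)
  joint[hit] <- JOINT_ALIASES[joint[hit]]
  joint
}

#' Construct a motion recording
#'
#' A `motion_recording` holds the per-frame joint-angle triplets, vertical
#' pelvic-centre position and foot-contact flags of one recorded movement
#' sequence, together with subject and sequence metadata. It is the input
#' container for REBA scoring ([compute_reba_series()]) and load estimation
#' ([pelvis_load()]).
#'
#' @param joint_angles Named list; one entry per joint, each an
#'   `n_frames x 3` numeric matrix with columns `flexion`, `abduction`,
#'   `rotation` (degrees). Must include all of [required_joints()]. Joint
#'   names are normalised via [normalize_joint_name()].
#' @param pelvis_z_m Numeric vector, vertical pelvic-centre position in
#'   metres, one value per frame.
#' @param foot_contact Logical `n_frames x 2` matrix (columns `left`,
#'   `right`) or a list/data.frame coercible to one: `TRUE` where the foot
#'   is in ground contact.
#' @param sample_rate_hz Sampling rate in Hz (default 240, the native rate
#'   of the Xsens MVN Link suit).
#' @param subject_id,gender,sequence_label,phase Subject and sequence
#'   metadata. `gender` is `"female"` or `"male"`; `phase` is 1
#'   (barre), 2 (centre) or 3 (jumps/allegro).
#' @return An object of class `motion_recording`.
#' @seealso [read_recording()], [get_angle()], [compute_reba_series()]
#' @export
motion_recording <- function(joint_angles, pelvis_z_m, foot_contact,
                             sample_rate_hz = 240,
                             subject_id = "anonymous",
                             gender = c("female", "male"),
                             sequence_label = "unlabelled",
                             phase = 1L) {
  gender <- match.arg(gender)
  if (!is.list(joint_angles) || is.null(names(joint_angles))) {
    stop("`joint_angles` must be a named list of n x 3 matrices", call. = FALSE)
  }
  names(joint_angles) <- normalize_joint_name(names(joint_angles))
  joint_angles <- lapply(joint_angles, function(m) {
    m <- as.matrix(m)
    if (ncol(m) != 3L) {
      stop("each joint-angle channel must have 3 columns (flexion, abduction, rotation)",
           call. = FALSE)
    }
    colnames(m) <- ANGLE_DOFS
    storage.mode(m) <- "double"
    m
  })
  if (is.data.frame(foot_contact)) foot_contact <- as.matrix(foot_contact)
  if (is.list(foot_contact)) {
    foot_contact <- cbind(left = foot_contact$left, right = foot_contact$right)
  }
  foot_contact <- matrix(as.logical(foot_contact), ncol = 2L,
                         dimnames = list(NULL, c("left", "right")))
  rec <- structure(
    list(
      subject_id     = as.character(subject_id),
      gender         = gender,
      sequence_label = as.character(sequence_label),
      phase          = as.integer(phase),
      sample_rate_hz = as.numeric(sample_rate_hz),
      n_frames       = length(pelvis_z_m),
      joint_angles   = joint_angles,
      pelvis_z_m     = as.numeric(pelvis_z_m),
      foot_contact   = foot_contact
    ),
    class = "motion_recording"
  )
  validate_motion_recording(rec)
}

#' Validate a motion recording
#'
#' Checks channel-length agreement, finiteness of angles and positions,
#' positivity of the sample rate and presence of all mandatory joints.
#' Called by [motion_recording()] and by the file readers; exported so that
#' externally assembled objects can be checked.
#'
#' @param rec A `motion_recording`.
#' @return `rec`, invisibly unchanged, if valid; otherwise an error.
#' @export
validate_motion_recording <- function(rec) {
  if (!inherits(rec, "motion_recording")) {
    stop("not a motion_recording", call. = FALSE)
  }
  n <- rec$n_frames
  if (!is.numeric(rec$sample_rate_hz) || length(rec$sample_rate_hz) != 1L ||
      !is.finite(rec$sample_rate_hz) || rec$sample_rate_hz <= 0) {
    stop("sample_rate_hz must be a single positive number", call. = FALSE)
  }
  if (n < 1L) stop("recording must contain at least one frame", call. = FALSE)
  if (!(rec$phase %in% 1:3)) {
    stop("phase must be 1, 2 or 3", call. = FALSE)
  }
  missing <- setdiff(REQUIRED_JOINTS, names(rec$joint_angles))
  if (length(missing)) {
    stop("missing mandatory joint channel(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  bad_len <- names(rec$joint_angles)[vapply(rec$joint_angles, nrow, 0L) != n]
  if (length(bad_len)) {
    stop("channel length mismatch (expected ", n, " frames): ",
         paste(bad_len, collapse = ", "), call. = FALSE)
  }
  nonfinite <- names(rec$joint_angles)[
    !vapply(rec$joint_angles, function(m) all(is.finite(m)), TRUE)]
  if (length(nonfinite)) {
    stop("non-finite angle values in: ", paste(nonfinite, collapse = ", "),
         call. = FALSE)
  }
  if (length(rec$pelvis_z_m) != n || !all(is.finite(rec$pelvis_z_m))) {
    stop("pelvis_z_m must be finite and have one value per frame", call. = FALSE)
  }
  if (nrow(rec$foot_contact) != n || anyNA(rec$foot_contact)) {
    stop("foot_contact must be a complete n_frames x 2 logical matrix",
         call. = FALSE)
  }
  invisible(rec)
}

#' Mandatory joints of a scoreable recording
#'
#' @return Character vector of the canonical joint names a recording must
#'   carry for whole-body REBA scoring.
#' @export
required_joints <- function() REQUIRED_JOINTS

#' Extract one joint-angle channel
#'
#' @param rec A `motion_recording`.
#' @param joint Joint name (canonical or known variant spelling).
#' @param dof One of `"flexion"`, `"abduction"`, `"rotation"`.
#' @return A `joint_angle_series`: list with `joint`, `dof`, `values_deg`
#'   and `sample_rate_hz`.
#' @export
#' @examples
#' rec <- generate_sequence(sequence_spec("demo", duration_s = 1))$recording
#' head(get_angle(rec, "jC1Head", "flexion")$values_deg)
get_angle <- function(rec, joint, dof = c("flexion", "abduction", "rotation")) {
  validate_motion_recording(rec)
  dof <- match.arg(dof)
  joint <- normalize_joint_name(joint)
  if (!joint %in% names(rec$joint_angles)) {
    stop("unknown joint '", joint, "' (dof '", dof, "') in recording",
         call. = FALSE)
  }
  structure(
    list(joint = joint, dof = dof,
         values_deg = rec$joint_angles[[joint]][, dof],
         sample_rate_hz = rec$sample_rate_hz),
    class = "joint_angle_series"
  )
}

#' @export
print.motion_recording <- function(x, ...) {
  cat("<motion_recording> ", x$sequence_label,
      " (phase ", x$phase, ", ", x$gender, ", subject ", x$subject_id, ")\n",
      sep = "")
  cat(sprintf("  %d frames @ %g Hz (%.1f s), %d joints\n",
              x$n_frames, x$sample_rate_hz, x$n_frames / x$sample_rate_hz,
              length(x$joint_angles)))
  invisible(x)
}

#' @export
print.joint_angle_series <- function(x, ...) {
  cat(sprintf("<joint_angle_series> %s / %s: %d samples @ %g Hz, range [%.1f, %.1f] deg\n",
              x$joint, x$dof, length(x$values_deg), x$sample_rate_hz,
              min(x$values_deg), max(x$values_deg)))
  invisible(x)
}

#' @export
summary.motion_recording <- function(object, ...) {
  fl <- vapply(object$joint_angles, function(m) range(m[, "flexion"]), numeric(2))
  cat("Recording '", object$sequence_label, "': ", object$n_frames,
      " frames @ ", object$sample_rate_hz, " Hz\n", sep = "")
  cat(sprintf("  pelvis z: [%.3f, %.3f] m; ground contact (both feet): %.1f%% of frames\n",
              min(object$pelvis_z_m), max(object$pelvis_z_m),
              100 * mean(object$foot_contact[, 1] & object$foot_contact[, 2])))
  cat("  flexion ranges (deg):\n")
  for (j in names(object$joint_angles)) {
    cat(sprintf("    %-18s [%7.2f, %7.2f]\n", j, fl[1, j], fl[2, j]))
  }
  invisible(object)
}
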