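## File formats
##
## CSV dialect: an embedded metadata header of '#'-prefixed YAML lines
## (subject_id, gender, sequence_label, phase, sample_rate_hz) followed by a
## regular CSV table, one row per frame, columns "<joint>.<dof>" plus
## "pelvis_z", "contact_left", "contact_right".
##
## MVNX subset: a reduced Xsens-style XML document. Only joint angles, the
## pelvis segment position and foot contacts are read; any other element is
## ignored. Foot contacts are stored as the usual four heel/toe flags; a
## side is "in contact" when either its heel or toe flag is set.

#' Read a motion recording from disk
#'
#' @param path Path to the file.
#' @param format `"csv_dialect"` or `"mvnx_subset"`. Defaults to guessing
#'   from the file extension (`.mvnx`/`.xml` vs anything else).
#' @return A validated [motion_recording()].
#' @seealso [write_recording()]
#' @export
read_recording <- function(path, format = c("auto", "csv_dialect", "mvnx_subset")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    format <- if (grepl("\\.(mvnx|xml)$", path, ignore.case = TRUE))
      "mvnx_subset" else "csv_dialect"
  }
  switch(format,
         csv_dialect = read_recording_csv(path),
         mvnx_subset = read_recording_mvnx(path))
}

#' Write a motion recording to disk
#'
#' `read_recording(write_recording(rec, path))` reproduces `rec` field by
#' field up to floating-point formatting (angles are written with enough
#' digits for 1e-6 degree agreement); foot contacts round-trip exactly.
#'
#' @param rec A [motion_recording()].
#' @param path Output path.
#' @param format `"csv_dialect"` or `"mvnx_subset"`.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path, format = c("csv_dialect", "mvnx_subset")) {
  validate_motion_recording(rec)
  format <- match.arg(format)
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("cannot write to '", path, "': no such directory",
                             call. = FALSE)
  switch(format,
         csv_dialect = write_recording_csv(rec, path),
         mvnx_subset = write_recording_mvnx(rec, path))
  invisible(path)
}

## ---- CSV dialect ----------------------------------------------------------

recording_metadata <- function(rec) {
  list(subject_id = rec$subject_id, gender = rec$gender,
       sequence_label = rec$sequence_label, phase = rec$phase,
       sample_rate_hz = rec$sample_rate_hz)
}

write_recording_csv <- function(rec, path) {
  meta <- recording_metadata(rec)
  header <- paste0("# ", strsplit(yaml::as.yaml(meta), "\n")[[1]])
  cols <- c(
    unlist(lapply(names(rec$joint_angles), function(j) paste(j, ANGLE_DOFS, sep = "."))),
    "pelvis_z", "contact_left", "contact_right")
  mat <- cbind(
    do.call(cbind, rec$joint_angles),
    rec$pelvis_z_m,
    rec$foot_contact[, "left"] + 0L,
    rec$foot_contact[, "right"] + 0L)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  writeLines(paste(cols, collapse = ","), con)
  body <- apply(mat, 1L, function(r) paste(formatC(r, format = "g", digits = 15),
                                           collapse = ","))
  writeLines(body, con)
}

read_recording_csv <- function(path) {
  lines <- readLines(path, n = 200L)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  if (length(meta_lines)) {
    meta <- yaml::yaml.load(paste(sub("^#\\s?", "", meta_lines), collapse = "\n"))
  }
  tab <- tryCatch(
    utils::read.csv(path, comment.char = "#", check.names = FALSE),
    error = function(e) stop("malformed CSV recording '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  cols <- names(tab)
  mandatory <- c(unlist(lapply(REQUIRED_JOINTS,
                               function(j) paste(j, ANGLE_DOFS, sep = "."))),
                 "pelvis_z", "contact_left", "contact_right")
  have <- unique(c(cols, vapply(strsplit(cols, ".", fixed = TRUE), function(p) {
    if (length(p) == 2L) paste(normalize_joint_name(p[1]), p[2], sep = ".") else ""
  }, "")))
  missing <- setdiff(mandatory, have)
  if (length(missing)) {
    miss_ch <- sort(unique(sub("\\.(flexion|abduction|rotation)$", "", missing)))
    stop("recording '", path, "' is missing mandatory channel(s): ",
         paste(miss_ch, collapse = ", "), call. = FALSE)
  }
  angle_cols <- grep("\\.(flexion|abduction|rotation)$", cols, value = TRUE)
  joints <- unique(sub("\\.(flexion|abduction|rotation)$", "", angle_cols))
  ja <- lapply(joints, function(j) {
    m <- sapply(ANGLE_DOFS, function(d) {
      cn <- paste(j, d, sep = ".")
      if (!cn %in% cols) stop("recording '", path, "' has incomplete triplet for ",
                              j, " (missing ", d, ")", call. = FALSE)
      as.numeric(tab[[cn]])
    })
    matrix(m, ncol = 3L, dimnames = list(NULL, ANGLE_DOFS))
  })
  names(ja) <- joints
  motion_recording(
    joint_angles = ja,
    pelvis_z_m = as.numeric(tab$pelvis_z),
    foot_contact = cbind(left = as.logical(tab$contact_left),
                         right = as.logical(tab$contact_right)),
    sample_rate_hz = meta$sample_rate_hz %||% 240,
    subject_id = meta$subject_id %||% "anonymous",
    gender = meta$gender %||% "female",
    sequence_label = meta$sequence_label %||% "unlabelled",
    phase = meta$phase %||% 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## ---- MVNX subset ----------------------------------------------------------

num_row <- function(x) paste(formatC(x, format = "g", digits = 15), collapse = " ")

write_recording_mvnx <- function(rec, path) {
  joints <- names(rec$joint_angles)
  n <- rec$n_frames
  ang <- do.call(cbind, rec$joint_angles)          # n x (3*J), joint-major
  fc <- rec$foot_contact + 0L
  frames <- character(n)
  for (i in seq_len(n)) {
    frames[i] <- paste0(
      "    <frame index=\"", i - 1L, "\" type=\"normal\">",
      "<jointAngle>", num_row(ang[i, ]), "</jointAngle>",
      "<position>0 0 ", formatC(rec$pelvis_z_m[i], format = "g", digits = 15),
      "</position>",
      "<footContacts>", fc[i, "left"], " ", fc[i, "left"], " ",
      fc[i, "right"], " ", fc[i, "right"], "</footContacts>",
      "</frame>")
  }
  doc <- c(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
    "<mvnx version=\"4\">",
    paste0("  <subject label=\"", rec$subject_id, "\" frameRate=\"",
           formatC(rec$sample_rate_hz, format = "g", digits = 15),
           "\" gender=\"", rec$gender, "\">"),
    paste0("  <sequence label=\"", rec$sequence_label, "\" phase=\"",
           rec$phase, "\"/>"),
    "  <joints>",
    paste0("    <joint label=\"", joints, "\"/>"),
    "  </joints>",
    "  <frames>",
    frames,
    "  </frames>",
    "  </subject>",
    "</mvnx>")
  writeLines(doc, path)
}

read_recording_mvnx <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("malformed MVNX file '", path, "': ",
                                           conditionMessage(e), call. = FALSE))
  subj <- xml2::xml_find_first(doc, ".//subject")
  if (inherits(subj, "xml_missing")) {
    stop("malformed MVNX file '", path, "': no <subject> element", call. = FALSE)
  }
  joints <- normalize_joint_name(
    xml2::xml_attr(xml2::xml_find_all(subj, ".//joints/joint"), "label"))
  if (!length(joints)) {
    stop("malformed MVNX file '", path, "': no <joints> declaration", call. = FALSE)
  }
  seq_node <- xml2::xml_find_first(subj, ".//sequence")
  frames <- xml2::xml_find_all(subj, ".//frames/frame")
  if (!length(frames)) {
    stop("malformed MVNX file '", path, "': no frames", call. = FALSE)
  }
  parse_rows <- function(xpath, what) {
    txt <- xml2::xml_text(xml2::xml_find_first(frames, xpath))
    if (anyNA(txt)) {
      stop("recording '", path, "' is missing mandatory channel(s): ", what,
           call. = FALSE)
    }
    vals <- lapply(strsplit(trimws(txt), "\\s+"), as.numeric)
    len <- lengths(vals)
    if (length(unique(len)) != 1L) {
      stop("malformed MVNX file '", path, "': ragged <", what, "> rows",
           call. = FALSE)
    }
    do.call(rbind, vals)
  }
  ang <- parse_rows("./jointAngle", "jointAngle")
  pos <- parse_rows("./position", "position (pelvis)")
  fc  <- parse_rows("./footContacts", "footContacts")
  if (ncol(ang) != 3L * length(joints)) {
    stop("malformed MVNX file '", path, "': jointAngle width ", ncol(ang),
         " does not match ", length(joints), " declared joints", call. = FALSE)
  }
  if (ncol(fc) < 2L) {
    stop("malformed MVNX file '", path, "': footContacts needs >= 2 flags",
         call. = FALSE)
  }
  ja <- lapply(seq_along(joints), function(k) {
    m <- ang[, (3L * (k - 1L) + 1L):(3L * k), drop = FALSE]
    dimnames(m) <- list(NULL, ANGLE_DOFS)
    m
  })
  names(ja) <- joints
  contact <- if (ncol(fc) >= 4L) {
    cbind(left = fc[, 1] > 0 | fc[, 2] > 0, right = fc[, 3] > 0 | fc[, 4] > 0)
  } else {
    cbind(left = fc[, 1] > 0, right = fc[, 2] > 0)
  }
  missing <- setdiff(REQUIRED_JOINTS, joints)
  if (length(missing)) {
    stop("recording '", path, "' is missing mandatory channel(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  attr_or <- function(node, a, default) {
    v <- xml2::xml_attr(node, a)
    if (is.na(v)) default else v
  }
  motion_recording(
    joint_angles = ja,
    pelvis_z_m = pos[, ncol(pos)],
    foot_contact = contact,
    sample_rate_hz = as.numeric(attr_or(subj, "frameRate", "240")),
    subject_id = attr_or(subj, "label", "anonymous"),
    gender = attr_or(subj, "gender", "female"),
    sequence_label = if (!inherits(seq_node, "xml_missing"))
      attr_or(seq_node, "label", "unlabelled") else "unlabelled",
    phase = if (!inherits(seq_node, "xml_missing"))
      as.integer(attr_or(seq_node, "phase", "1")) else 1L)
}
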