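## Fixture builders: recordings assembled in code, no stored data.

## A recording with every joint at a constant posture (neutral by default).
## `angles` overrides individual joints with a c(flexion, abduction,
## rotation) triplet; per-frame matrices are also accepted.
make_recording <- function(n = 24, fs = 240, angles = list(),
                           pelvis = NULL, contact = NULL, ...) {
  ja <- lapply(stats::setNames(nm = required_joints()), function(j) {
    a <- angles[[j]]
    if (is.null(a)) a <- c(0, 0, 0)
    if (is.matrix(a)) a else matrix(rep(a, each = n), ncol = 3)
  })
  if (is.null(pelvis)) pelvis <- rep(0.95, n)
  if (is.null(contact)) contact <- cbind(left = rep(TRUE, n),
                                         right = rep(TRUE, n))
  motion_recording(ja, pelvis, contact, sample_rate_hz = fs, ...)
}

## Apply the same flexion waveform to every activity joint group, so the
## static/dynamic flags can be driven deliberately.
make_waveform_recording <- function(wave, fs) {
  n <- length(wave)
  angles <- lapply(stats::setNames(nm = required_joints()),
                   function(j) cbind(wave, 0, 0))
  make_recording(n = n, fs = fs, angles = angles)
}
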