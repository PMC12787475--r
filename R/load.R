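#' Second derivative of a position series by central differences
#'
#' `a[i] = (z[i-1] - 2 z[i] + z[i+1]) * fs^2` on interior frames, with
#' one-sided second differences at the two endpoints. Exact (to floating
#' point) for quadratic trajectories, hence for ballistic flight arcs. An
#' optional zero-phase low-pass (Butterworth via the signal package, order
#' 2) can be applied to the position before differentiating; it is off by
#' default.
#'
#' @param z_m Numeric vector, vertical position in metres (>= 3 samples).
#' @param sample_rate_hz Sampling rate in Hz.
#' @param smooth Logical; pre-smooth the position before differencing.
#' @param cutoff_hz Low-pass cutoff in Hz when `smooth = TRUE`.
#' @return Numeric vector of accelerations (m/s^2), same length as `z_m`.
#' @export
second_derivative <- function(z_m, sample_rate_hz, smooth = FALSE,
                              cutoff_hz = 12) {
  if (!is.numeric(z_m) || length(z_m) < 3L) {
    stop("position series must contain at least 3 samples", call. = FALSE)
  }
  if (anyNA(z_m) || any(!is.finite(z_m))) {
    stop("non-finite position values", call. = FALSE)
  }
  if (smooth) {
    if (!requireNamespace("signal", quietly = TRUE)) {
      stop("pre-smoothing requires the 'signal' package", call. = FALSE)
    }
    bf <- signal::butter(2, cutoff_hz / (sample_rate_hz / 2))
    z_m <- signal::filtfilt(bf, z_m)
  }
  n <- length(z_m)
  a <- numeric(n)
  i <- 2:(n - 1L)
  a[i] <- (z_m[i - 1L] - 2 * z_m[i] + z_m[i + 1L]) * sample_rate_hz^2
  a[1L] <- (z_m[1L] - 2 * z_m[2L] + z_m[3L]) * sample_rate_hz^2
  a[n] <- (z_m[n - 2L] - 2 * z_m[n - 1L] + z_m[n]) * sample_rate_hz^2
  a
}

#' Vertical load in body-weight units from pelvic acceleration
#'
#' The supported load is `max(0, 1 + a/g)` body weights, so quiet standing
#' (`a = 0`) carries 1 BW and ballistic flight (`a = -g`) carries exactly
#' 0 BW; landings with upward pelvic acceleration carry more than 1 BW.
#'
#' @param accel_mps2 Vertical pelvic acceleration in m/s^2 (gravity
#'   excluded, i.e. the second derivative of position).
#' @param sample_rate_hz Sampling rate in Hz (carried for downstream use).
#' @param gravity Gravitational acceleration, m/s^2.
#' @return A `load_series`: list with `values_bw`, `accel_g` and
#'   `sample_rate_hz`.
#' @export
#' @examples
#' load_from_accel(c(0, -9.81, 2 * 9.81))$values_bw  # 1, 0, 3
load_from_accel <- function(accel_mps2, sample_rate_hz = 240,
                            gravity = 9.81) {
  if (!is.numeric(accel_mps2) || anyNA(accel_mps2) ||
      any(!is.finite(accel_mps2))) {
    stop("non-finite acceleration values", call. = FALSE)
  }
  accel_g <- accel_mps2 / gravity
  structure(
    list(values_bw = pmax(0, 1 + accel_g),
         accel_g = accel_g,
         sample_rate_hz = sample_rate_hz),
    class = "load_series")
}

#' Load series of a recording from its pelvis trajectory
#'
#' Convenience composition of [second_derivative()] and
#' [load_from_accel()] on the recording's vertical pelvic-centre position.
#'
#' @param recording A [motion_recording()].
#' @param smooth,cutoff_hz Passed to [second_derivative()].
#' @param gravity Passed to [load_from_accel()].
#' @return A `load_series`.
#' @export
pelvis_load <- function(recording, smooth = FALSE, cutoff_hz = 12,
                        gravity = 9.81) {
  validate_motion_recording(recording)
  a <- second_derivative(recording$pelvis_z_m, recording$sample_rate_hz,
                         smooth = smooth, cutoff_hz = cutoff_hz)
  load_from_accel(a, recording$sample_rate_hz, gravity = gravity)
}

#' @export
print.load_series <- function(x, ...) {
  cat(sprintf("<load_series> %d frames @ %g Hz: mean %.2f BW, max %.2f BW, flight %.1f%%\n",
              length(x$values_bw), x$sample_rate_hz, mean(x$values_bw),
              max(x$values_bw), 100 * flight_fraction(x)))
  invisible(x)
}

#' Relative frequency distribution of load, binned in 0.5 BW graduations
#'
#' Each frame is assigned to the nearest of the bin centres 0, 0.5, ...,
#' 5.0 BW (ties go to the higher bin; values beyond the last edge are
#' clamped into the 5.0 bin), and frequencies are normalised by the frame
#' count. The mean load is taken from the binned distribution.
#'
#' @param load A `load_series` (or numeric vector of BW values).
#' @param bin_width Bin width in BW.
#' @param max_bw Largest bin centre in BW.
#' @return A `load_histogram`: list with `bin_centers_bw`, `rel_freq`,
#'   `mean_load_bw` and `total_frames`.
#' @export
load_histogram <- function(load, bin_width = 0.5, max_bw = 5) {
  values <- if (inherits(load, "load_series")) load$values_bw else load
  if (!length(values)) stop("empty load series", call. = FALSE)
  centers <- seq(0, max_bw, by = bin_width)
  idx <- pmin(floor(values / bin_width + 0.5) + 1L, length(centers))
  counts <- tabulate(idx, nbins = length(centers))
  rel <- counts / length(values)
  structure(
    list(bin_centers_bw = centers, rel_freq = rel,
         mean_load_bw = sum(centers * rel), total_frames = length(values)),
    class = "load_histogram")
}

#' Fraction of frames spent in flight
#'
#' @param load A `load_series` (or numeric vector of BW values).
#' @param threshold_bw Loads below this count as flight (ballistic, no
#'   ground reaction force).
#' @return Fraction in `[0, 1]`.
#' @export
flight_fraction <- function(load, threshold_bw = 0.25) {
  values <- if (inherits(load, "load_series")) load$values_bw else load
  if (!length(values)) stop("empty load series", call. = FALSE)
  mean(values < threshold_bw)
}

#' @export
print.load_histogram <- function(x, ...) {
  cat(sprintf("<load_histogram> %d frames, mean %.2f BW\n",
              x$total_frames, x$mean_load_bw))
  df <- data.frame(bin_bw = x$bin_centers_bw, rel_freq = round(x$rel_freq, 4))
  print(df[df$rel_freq > 0, ], row.names = FALSE)
  invisible(x)
}

#' @export
plot.load_histogram <- function(x, main = "Vertical load distribution", ...) {
  graphics::barplot(x$rel_freq, names.arg = formatC(x$bin_centers_bw, 1, format = "f"),
                    xlab = "Load [BW]", ylab = "Relative frequency",
                    col = "steelblue", main = main, ...)
  invisible(x)
}
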