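# Preprocessing: Butterworth low-pass stages, Mahony orientation
# estimation, and gravity removal producing the 36-signal "0g" dataset
# (6 sensors x {3 gravity-free acceleration + 3 angular velocity}).

#' Mahony filter gains
#'
#' @param kp proportional gain, 1/s (> 0).
#' @param ki integral gain, 1/s^2 (>= 0), with per-component anti-windup.
#' @param mode "9-axis" (accelerometer + magnetometer correction) or
#'   "6-axis" (accelerometer only). Gravity removal needs only roll/pitch,
#'   so 6-axis mode is sufficient when the local magnetic field is
#'   unusable.
#' @return object of class `mahony_gains`.
#' @export
mahony_gains <- function(kp = 1.0, ki = 0.3, mode = c("9-axis", "6-axis")) {
  mode <- match.arg(mode)
  stopifnot(kp > 0, ki >= 0)
  structure(list(kp = kp, ki = ki, mode = mode), class = "mahony_gains")
}

#' Zero-phase Butterworth low-pass filter of a stream or matrix
#'
#' Applies a forward-backward (zero-phase) Butterworth filter to every
#' channel; DC is preserved. The causal single-pass variant
#' (`zero_phase = FALSE`) is used by the real-time path.
#'
#' @param x an [imu_stream()] or a numeric matrix/vector sampled at `rate`.
#' @param cutoff cutoff frequency, Hz (must be below Nyquist).
#' @param order filter order (default 6, matching the pipeline's 2 Hz
#'   stage).
#' @param rate sample rate, Hz (taken from the stream when `x` is one).
#' @param zero_phase logical; FALSE gives causal single-pass filtering.
#' @return filtered object of the same shape/class as `x`.
#' @export
lowpass <- function(x, cutoff, order = 6, rate = NULL, zero_phase = TRUE) {
  if (inherits(x, "imu_stream")) {
    rate <- x$rate
    check_cutoff(cutoff, rate, order, length(x$t))
    out <- x
    out$acc <- lowpass_mat(x$acc, cutoff, order, rate, zero_phase)
    out$gyro <- lowpass_mat(x$gyro, cutoff, order, rate, zero_phase)
    if (!is.null(x$mag))
      out$mag <- lowpass_mat(x$mag, cutoff, order, rate, zero_phase)
    return(out)
  }
  if (is.null(rate)) stop("rate is required for matrix/vector input")
  vec <- is.null(dim(x))
  m <- if (vec) matrix(x, ncol = 1) else x
  check_cutoff(cutoff, rate, order, nrow(m))
  out <- lowpass_mat(m, cutoff, order, rate, zero_phase)
  if (vec) drop(out) else out
}

check_cutoff <- function(cutoff, rate, order, n) {
  if (cutoff >= rate / 2)
    stop(sprintf("cutoff %g Hz is at/above Nyquist (%g Hz)", cutoff, rate / 2))
  if (cutoff <= 0) stop("cutoff must be positive")
  if (n <= 3 * order)
    stop("stream too short for the requested filter order")
}

lowpass_mat <- function(m, cutoff, order, rate, zero_phase) {
  bf <- signal::butter(order, cutoff / (rate / 2), type = "low")
  # remove the channel mean before filtering to tame filtfilt edge
  # transients; add it back afterwards (DC gain is 1)
  apply(m, 2, function(col) {
    mu <- mean(col)
    y <- if (zero_phase) signal::filtfilt(bf, col - mu)
         else signal::filter(bf, col - mu)
    as.numeric(y) + mu
  })
}

#' Estimate per-sample orientation with the Mahony complementary filter
#'
#' Integrates the gyroscope and corrects drift with proportional-integral
#' feedback on the accelerometer gravity direction (and, in 9-axis mode,
#' the magnetometer field direction). The initial attitude is taken from
#' the mean accelerometer direction over the first `init_window_s` seconds
#' (roll/pitch, zero yaw) unless an explicit quaternion is supplied.
#'
#' @param stream a uniform-rate [imu_stream()].
#' @param gains a [mahony_gains()].
#' @param init length-4 quaternion or "auto".
#' @param init_window_s seconds of data used for the automatic initial tilt.
#' @param boost_s high-gain startup duration, s: for the first `boost_s`
#'   seconds the proportional gain is raised tenfold and the integrator is
#'   frozen, so the attitude locks onto the measurements quickly before the
#'   nominal gains take over.
#' @param bias_capture_s seconds of startup data whose mean gyroscope
#'   reading is treated as the constant gyro bias and subtracted (standard
#'   IMU startup calibration; the monitoring protocol begins with the
#'   subject standing still). Set 0 when the start of the stream is not
#'   known to be stationary; the integral term then absorbs bias slowly.
#' @param conv_threshold innovation threshold, rad, under which a sample
#'   counts toward convergence.
#' @param conv_window_s seconds the innovation must stay below the
#'   threshold before the track is flagged converged.
#' @return object of class `orientation_track`: list with `q` (n x 4 unit
#'   quaternions, sensor -> Earth), `innovation` (rad), `converged`
#'   (logical per sample), `rate`.
#' @export
estimate_orientation <- function(stream, gains = mahony_gains(),
                                 init = "auto", init_window_s = 0.5,
                                 boost_s = 2, bias_capture_s = 2,
                                 conv_threshold = 0.02, conv_window_s = 1) {
  stopifnot(inherits(stream, "imu_stream"), inherits(gains, "mahony_gains"))
  n <- length(stream$t)
  if (n < 2) stop("stream too short for orientation estimation")
  dt <- diff(stream$t)
  if (max(dt) - min(dt) > 1e-6) stop("stream must be uniform-rate")
  use_mag <- gains$mode == "9-axis"
  if (use_mag && is.null(stream$mag)) {
    warning("magnetometer absent; falling back to 6-axis mode")
    use_mag <- FALSE
  }
  if (identical(init, "auto")) {
    w <- max(2L, min(n, round(init_window_s * stream$rate)))
    init <- quat_from_acc(colMeans(stream$acc[seq_len(w), , drop = FALSE]))
  }
  init <- quat_normalize(as.numeric(init))
  gyro <- stream$gyro
  if (bias_capture_s > 0) {
    n0 <- max(2L, min(n, round(bias_capture_s * stream$rate)))
    gyro <- sweep(gyro, 2, colMeans(gyro[seq_len(n0), , drop = FALSE]))
  }
  mag <- if (use_mag) stream$mag else matrix(numeric(0), 0, 3)
  res <- mahony_filter_cpp(stream$acc, gyro, mag, 1 / stream$rate,
                           gains$kp, gains$ki, init, use_mag,
                           boost_n = round(boost_s * stream$rate))
  if (res$skipped > 0)
    warning(res$skipped, " zero-norm accelerometer sample(s): gyro-only propagation")
  win <- max(1L, round(conv_window_s * stream$rate))
  below <- res$innovation < conv_threshold
  run <- 0L
  converged <- logical(n)
  for (i in seq_len(n)) {
    run <- if (below[i]) run + 1L else 0L
    converged[i] <- run >= win
  }
  if (any(converged)) converged[seq(which(converged)[1], n)] <- TRUE
  structure(list(q = res$q, innovation = res$innovation,
                 converged = converged, rate = stream$rate),
            class = "orientation_track")
}

#' @export
print.orientation_track <- function(x, ...) {
  cat(sprintf("<orientation_track> %d samples @ %g Hz, converged from %s\n",
              nrow(x$q), x$rate,
              if (any(x$converged))
                sprintf("t = %.2f s", (which(x$converged)[1] - 1) / x$rate)
              else "<never>"))
  invisible(x)
}

#' Remove the gravitational component from accelerometer data
#'
#' Rotates each specific-force sample into the Earth frame using the
#' orientation track, subtracts (0, 0, g), and rotates the remainder back
#' into the sensor frame, yielding the gravity-free ("0g") acceleration.
#'
#' @param stream an [imu_stream()].
#' @param track an [estimate_orientation()] result aligned to the stream
#'   (or any n x 4 quaternion matrix).
#' @param g gravitational acceleration, m/s^2.
#' @return n x 3 matrix of 0g acceleration, m/s^2, sensor frame.
#' @export
remove_gravity <- function(stream, track, g = G_MPS2) {
  q <- if (inherits(track, "orientation_track")) track$q else as_quat_mat(track)
  acc <- if (inherits(stream, "imu_stream")) stream$acc else as_mat3(stream, "acc")
  if (nrow(q) != nrow(acc))
    stop("orientation track and stream lengths differ (",
         nrow(q), " vs ", nrow(acc), ")")
  acc_e <- quat_rotate(q, acc)
  acc_e[, 3] <- acc_e[, 3] - g
  quat_rotate_inv(q, acc_e)
}

#' Build the 36-signal gravity-free trial ("microgravity simulation")
#'
#' The full preprocessing chain of the monitoring system: a 20 Hz low-pass
#' on all nine channels of each sensor, Mahony orientation estimation, and
#' gravity removal. The result carries, per sensor, the 0g acceleration and
#' the (filtered) angular velocity - 6 channels x 6 sensors = 36 signals -
#' plus each sensor's orientation track.
#'
#' @param trial an aligned uniform-rate [imu_trial()].
#' @param gains a [mahony_gains()].
#' @param cutoff_hz,order the pre-filter stage (default 20 Hz, 6th order).
#' @param warmup_s seconds flagged as orientation warm-up; downstream
#'   segmentation ignores this span.
#' @param g gravitational acceleration, m/s^2.
#' @return object of class `zerog_trial`: `t`, `rate`, `label`, `meta`,
#'   `warmup_s`, and `sensors` - a named list with `acc0g`, `gyro`
#'   (n x 3 each) and `track` per sensor.
#' @export
simulate_microgravity <- function(trial, gains = mahony_gains(),
                                  cutoff_hz = 20, order = 6,
                                  warmup_s = 5, g = G_MPS2) {
  stopifnot(inherits(trial, "imu_trial"))
  if (!is_aligned(trial, tol = 1e-6))
    stop("trial must be aligned on a uniform grid (see resample_align)")
  sensors <- lapply(trial$streams, function(s) {
    sf <- lowpass(s, cutoff_hz, order)
    trk <- estimate_orientation(sf, gains)
    list(acc0g = remove_gravity(sf, trk, g), gyro = sf$gyro, track = trk)
  })
  structure(list(t = trial$streams[[1]]$t, rate = trial$rate,
                 label = trial$label, meta = trial$meta,
                 warmup_s = warmup_s, sensors = sensors),
            class = "zerog_trial")
}

#' @export
print.zerog_trial <- function(x, ...) {
  cat(sprintf("<zerog_trial> 36 signals (6 sensors x 6 channels), %d samples @ %g Hz, label %s\n",
              length(x$t), x$rate,
              if (all(is.na(x$label))) "<unlabeled>" else as.character(x$label)))
  invisible(x)
}

#' Earth-frame 0g acceleration of one sensor
#'
#' Convenience accessor: rotates a sensor's gravity-free acceleration into
#' the Earth frame (the vertical component drives repetition segmentation).
#'
#' @param ztrial a [simulate_microgravity()] result.
#' @param sensor sensor id.
#' @return n x 3 matrix, Earth frame (ENU), m/s^2.
#' @export
zerog_earth <- function(ztrial, sensor = "sacrum") {
  s <- ztrial$sensors[[sensor]]
  if (is.null(s)) stop("no such sensor: ", sensor)
  quat_rotate(s$track$q, s$acc0g)
}
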