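#' squatmon: IMU-based squat technique monitoring
#'
#' End-to-end processing chain for a six-sensor wearable squat monitor:
#' orientation estimation (Mahony complementary filter), gravity removal
#' ("microgravity simulation"), repetition segmentation, a 2250-item
#' time/frequency feature bank, multi-class technique-error classification
#' with macro-averaged metrics, paired-sensor agreement statistics, a
#' simulated real-time monitor, and a kinematic squat simulator used as the
#' test substrate.
#'
#' @useDynLib squatmon, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats approx ar.burg cor fft median quantile IQR mad sd var
#'   predict rnorm runif
#' @importFrom utils head tail write.csv read.csv
#' @keywords internal
"_PACKAGE"

#' Standard gravitational acceleration (m/s^2)
#' @export
G_MPS2 <- 9.80665

#' Body sites of the six sensors
#'
#' Both shanks, both thighs, sacrum and sternum, in canonical order.
#' @export
sensor_sites <- function() {
  c("shank_L", "shank_R", "thigh_L", "thigh_R", "sacrum", "sternum")
}

#' Squat execution classes
#'
#' Six technique classes with stable integer codes 0-5: CO (correct
#' execution), KOT (knees overcoming toes), VK (valgus knees), RB (rounded
#' back), RH (raised heels), SH (shallow squat).
#' @export
squat_classes <- function() {
  c("CO", "KOT", "VK", "RB", "RH", "SH")
}

#' Convert labels to the canonical squat-class factor
#'
#' @param x character vector, factor or integer codes (0-5).
#' @return factor with levels `squat_classes()`.
#' @export
squat_label <- function(x) {
  cls <- squat_classes()
  if (is.numeric(x)) {
    stopifnot(all(x %in% 0:5))
    x <- cls[x + 1L]
  }
  x <- as.character(x)
  bad <- setdiff(unique(x), cls)
  if (length(bad)) stop("unknown squat class label(s): ", paste(bad, collapse = ", "))
  factor(x, levels = cls)
}

#' Construct a single-sensor IMU stream
#'
#' A 9-axis stream: timestamps, specific force (accelerometer, m/s^2),
#' angular velocity (gyroscope, rad/s) and normalized magnetic field
#' direction (unitless), all in the sensor frame. Magnetometer columns are
#' optional; on construction the magnetometer rows are normalized to unit
#' length (only the field direction is used downstream).
#'
#' @param sensor_id one of `sensor_sites()`.
#' @param t numeric timestamps, seconds, strictly increasing, non-negative.
#' @param acc,gyro n x 3 numeric matrices.
#' @param mag n x 3 numeric matrix or NULL when the magnetometer is absent.
#' @param rate nominal sample rate, Hz.
#' @return object of class `imu_stream`.
#' @export
imu_stream <- function(sensor_id, t, acc, gyro, mag = NULL, rate) {
  sensor_id <- match.arg(sensor_id, sensor_sites())
  t <- as.numeric(t)
  acc <- as_mat3(acc, "acc")
  gyro <- as_mat3(gyro, "gyro")
  n <- length(t)
  if (nrow(acc) != n || nrow(gyro) != n)
    stop("acc/gyro length must match timestamps")
  if (n > 0) {
    if (any(!is.finite(t)) || any(t < 0))
      stop("timestamps must be finite and non-negative")
    d <- diff(t)
    if (any(d <= 0)) {
      bad <- which(d <= 0)[1] + 1L
      stop(sprintf("non-monotone timestamps in sensor '%s' at row %d",
                   sensor_id, bad))
    }
    if (any(!is.finite(acc)) || any(!is.finite(gyro)))
      stop("non-finite accelerometer/gyroscope values")
  }
  if (!is.null(mag)) {
    mag <- as_mat3(mag, "mag")
    if (nrow(mag) != n) stop("mag length must match timestamps")
    if (any(!is.finite(mag))) stop("non-finite magnetometer values")
    nrm <- sqrt(rowSums(mag^2))
    nz <- nrm > 0
    mag[nz, ] <- mag[nz, , drop = FALSE] / nrm[nz]
  }
  if (!is.numeric(rate) || length(rate) != 1 || rate <= 0)
    stop("rate must be a positive scalar (Hz)")
  structure(list(sensor_id = sensor_id, rate = as.numeric(rate),
                 t = t, acc = acc, gyro = gyro, mag = mag),
            class = "imu_stream")
}

as_mat3 <- function(x, what) {
  x <- as.matrix(x)
  if (length(x) == 0) x <- matrix(numeric(0), 0, 3)
  if (ncol(x) != 3) stop(what, " must have 3 columns")
  storage.mode(x) <- "double"
  dimnames(x) <- NULL
  x
}

#' @export
print.imu_stream <- function(x, ...) {
  cat(sprintf("<imu_stream> %s: %d samples @ %g Hz, mag %s\n",
              x$sensor_id, length(x$t), x$rate,
              if (is.null(x$mag)) "absent" else "present"))
  invisible(x)
}

#' Construct a six-sensor trial recording
#'
#' @param streams named list of six [imu_stream()] objects, one per body
#'   site.
#' @param label squat class label or NA for unlabeled trials.
#' @param meta named list of free-form metadata (subject, session, load,
#'   notes).
#' @param aligned logical; TRUE when streams share a uniform common grid.
#' @return object of class `imu_trial`.
#' @export
imu_trial <- function(streams, label = NA, meta = list()) {
  sites <- sensor_sites()
  if (is.null(names(streams))) names(streams) <- vapply(streams, `[[`, "", "sensor_id")
  if (!setequal(names(streams), sites))
    stop("trial requires exactly the six sensor sites: ",
         paste(sites, collapse = ", "))
  streams <- streams[sites]
  for (s in streams) {
    if (!inherits(s, "imu_stream")) stop("streams must be imu_stream objects")
  }
  rates <- vapply(streams, `[[`, 0, "rate")
  if (max(rates) - min(rates) > 1e-9) stop("all streams must share one rate")
  if (!all(is.na(label))) label <- squat_label(label)
  structure(list(streams = streams, rate = rates[[1]],
                 label = label, meta = meta),
            class = "imu_trial")
}

#' @export
print.imu_trial <- function(x, ...) {
  ns <- vapply(x$streams, function(s) length(s$t), 0L)
  cat(sprintf("<imu_trial> 6 sensors @ %g Hz, %s samples, label %s\n",
              x$rate,
              if (length(unique(ns)) == 1) as.character(ns[[1]])
              else paste0(min(ns), "-", max(ns)),
              if (all(is.na(x$label))) "<unlabeled>" else as.character(x$label)))
  invisible(x)
}

#' Is a trial aligned on a single uniform grid?
#'
#' @param trial an `imu_trial`.
#' @param tol spacing tolerance, seconds.
#' @return logical.
#' @export
is_aligned <- function(trial, tol = 1e-9) {
  ts <- lapply(trial$streams, `[[`, "t")
  n <- unique(vapply(ts, length, 0L))
  if (length(n) != 1 || n[1] < 2) return(length(n) == 1)
  t0 <- ts[[1]]
  if (any(vapply(ts, function(t) max(abs(t - t0)), 0) > tol)) return(FALSE)
  dt <- diff(t0)
  max(abs(dt - 1 / trial$rate)) <= tol
}

#' Construct a sensor layout description
#'
#' Maps the six sensor ids to body-site descriptions and a free-text axis
#' convention note. The axis convention is documentation, not enforced: the
#' pipeline only assumes right-handed sensor frames.
#'
#' @param notes optional named character vector overriding per-site notes.
#' @return object of class `sensor_layout`.
#' @export
sensor_layout <- function(notes = NULL) {
  sites <- sensor_sites()
  desc <- c(
    shank_L = "left shank, midpoint lateral malleolus-femoral condyle",
    shank_R = "right shank, midpoint lateral malleolus-femoral condyle",
    thigh_L = "left thigh, midpoint femoral condyle-greater trochanter",
    thigh_R = "right thigh, midpoint femoral condyle-greater trochanter",
    sacrum  = "sacrum, between the posterior superior iliac spines",
    sternum = "sternum, mid-chest"
  )
  note <- rep("right-handed sensor frame; z along segment long axis (up when standing), x anterior", 6)
  names(note) <- sites
  if (!is.null(notes)) note[names(notes)] <- notes
  structure(list(sites = sites, description = desc, axis_note = note),
            class = "sensor_layout")
}

#' @export
print.sensor_layout <- function(x, ...) {
  cat("<sensor_layout>\n")
  for (s in x$sites) cat(sprintf("  %-8s %s\n", s, x$description[[s]]))
  invisible(x)
}
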