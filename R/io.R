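# Trial CSV interchange: long format, one row per sample per sensor, header
# sensor_id,t,ax,ay,az,gx,gy,gz,mx,my,mz. Label and metadata live in a YAML
# sidecar (keys: label, subject, session, rate_hz) next to the CSV.

trial_csv_columns <- c("sensor_id", "t", "ax", "ay", "az",
                       "gx", "gy", "gz", "mx", "my", "mz")

sidecar_path <- function(path) paste0(sub("\\.csv$", "", path), ".meta.yaml")

#' Read a six-sensor trial from CSV
#'
#' Reads the long-format trial CSV (see [write_trial()]) plus its YAML
#' metadata sidecar, if present. Missing or all-NA magnetometer columns
#' yield streams flagged magnetometer-absent.
#'
#' @param path CSV file path.
#' @param layout a [sensor_layout()]; used to check sensor ids.
#' @return an [imu_trial()].
#' @export
read_trial <- function(path, layout = sensor_layout()) {
  if (!file.exists(path)) stop("trial file not found: ", path)
  dt <- data.table::fread(path, sep = ",", header = TRUE, data.table = FALSE)
  need <- setdiff(trial_csv_columns[1:8], names(dt))
  if (length(need))
    stop("malformed trial header, missing column(s): ",
         paste(need, collapse = ", "))
  has_mag <- all(c("mx", "my", "mz") %in% names(dt)) &&
    !all(is.na(dt$mx))
  meta <- list(); label <- NA; rate <- NA_real_
  sc <- sidecar_path(path)
  if (file.exists(sc)) {
    side <- yaml::read_yaml(sc)
    if (!is.null(side$label) && !is.na(side$label)) label <- side$label
    if (!is.null(side$rate_hz)) rate <- as.numeric(side$rate_hz)
    meta <- side[setdiff(names(side), c("label", "rate_hz"))]
  }
  streams <- lapply(layout$sites, function(sid) {
    rows <- dt[dt$sensor_id == sid, , drop = FALSE]
    if (!nrow(rows)) stop("trial file has no rows for sensor '", sid, "'")
    d <- diff(rows$t)
    if (any(d <= 0)) {
      bad <- which(d <= 0)[1] + 1L
      stop(sprintf("non-monotone timestamps in sensor '%s' at row %d",
                   sid, bad))
    }
    r <- if (is.finite(rate)) rate else 1 / stats::median(d)
    imu_stream(sid, rows$t,
               acc = as.matrix(rows[, c("ax", "ay", "az")]),
               gyro = as.matrix(rows[, c("gx", "gy", "gz")]),
               mag = if (has_mag) as.matrix(rows[, c("mx", "my", "mz")]) else NULL,
               rate = r)
  })
  names(streams) <- layout$sites
  imu_trial(streams, label = label, meta = meta)
}

#' Write a six-sensor trial to CSV
#'
#' Long format with per-sensor blocks in canonical site order; values are
#' written with enough digits for a faithful round trip (>= 9 significant
#' digits). Label and metadata go to a `.meta.yaml` sidecar.
#'
#' @param trial an [imu_trial()].
#' @param path destination CSV path.
#' @return the path, invisibly.
#' @export
write_trial <- function(trial, path) {
  stopifnot(inherits(trial, "imu_trial"))
  blocks <- lapply(trial$streams, function(s) {
    n <- length(s$t)
    mg <- if (is.null(s$mag)) matrix(NA_real_, n, 3) else s$mag
    data.frame(sensor_id = rep(s$sensor_id, n), t = s$t,
               ax = s$acc[, 1], ay = s$acc[, 2], az = s$acc[, 3],
               gx = s$gyro[, 1], gy = s$gyro[, 2], gz = s$gyro[, 3],
               mx = mg[, 1], my = mg[, 2], mz = mg[, 3])
  })
  out <- do.call(rbind, blocks)
  ok <- tryCatch({
    data.table::fwrite(out, path, sep = ",", na = "NA")
    TRUE
  }, error = function(e) stop("cannot write trial file: ", conditionMessage(e)))
  side <- c(list(label = if (all(is.na(trial$label))) NA
                 else as.character(trial$label),
                 rate_hz = trial$rate),
            trial$meta)
  yaml::write_yaml(side, sidecar_path(path))
  invisible(path)
}

#' Resample and align all streams onto one uniform grid
#'
#' Linearly interpolates every channel of every stream onto a common uniform
#' grid at the requested rate, spanning the time range shared by all six
#' streams. Never extrapolates.
#'
#' @param trial an [imu_trial()].
#' @param rate target rate, Hz.
#' @return an aligned [imu_trial()].
#' @export
resample_align <- function(trial, rate = trial$rate) {
  stopifnot(inherits(trial, "imu_trial"), rate > 0)
  for (s in trial$streams)
    if (length(s$t) < 2) stop("resample_align needs >= 2 samples per stream")
  t0 <- max(vapply(trial$streams, function(s) s$t[1], 0))
  t1 <- min(vapply(trial$streams, function(s) s$t[length(s$t)], 0))
  if (t1 <= t0) stop("streams have no overlapping time range; cannot align")
  grid <- seq(t0, t0 + floor((t1 - t0) * rate) / rate, by = 1 / rate)
  streams <- lapply(trial$streams, function(s) {
    interp <- function(m) {
      apply(m, 2, function(col) approx(s$t, col, xout = grid)$y)
    }
    imu_stream(s$sensor_id, grid, interp(s$acc), interp(s$gyro),
               if (is.null(s$mag)) NULL else interp(s$mag), rate)
  })
  imu_trial(streams, label = trial$label, meta = trial$meta)
}
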