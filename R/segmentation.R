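# Repetition segmentation: peak/valley detection on a driver signal (by
# default the Earth-frame vertical 0g acceleration of the sacrum, smoothed
# at 2 Hz) with repetition boundaries at the zero crossing before each
# valley and after each peak. A repetition is a valley-then-peak pair of
# vertical acceleration: descent braking, then the upward push at the
# bottom of the squat.

#' Segmentation parameters
#'
#' @param sensor sensor whose signal drives detection.
#' @param channel driver channel: "earth_z" (Earth-frame vertical 0g
#'   acceleration) or an index 1-3 into the sensor-frame 0g acceleration.
#' @param min_prominence required extremum prominence as a fraction of the
#'   driver signal's IQR.
#' @param min_separation minimum spacing between same-kind extrema, s.
#' @param zero_band tolerance around zero, m/s^2, for the boundary
#'   fallback when no sign change exists.
#' @param amp_frac sign-consistency threshold as a fraction of the driver
#'   IQR: peaks must rise above it, valleys fall below its negative
#'   (floored at `zero_band`), so near-zero wiggles at standing cannot
#'   form cycles.
#' @param smooth_hz,smooth_order extra low-pass applied to the driver
#'   before detection (default 2 Hz, 6th-order Butterworth).
#' @return object of class `segmentation_params`.
#' @export
segmentation_params <- function(sensor = "sacrum", channel = "earth_z",
                                min_prominence = 0.5, min_separation = 1.0,
                                zero_band = 0.05, amp_frac = 0.25,
                                smooth_hz = 2, smooth_order = 6) {
  stopifnot(min_prominence > 0, min_separation > 0, zero_band >= 0,
            amp_frac >= 0)
  structure(list(sensor = sensor, channel = channel,
                 min_prominence = min_prominence,
                 min_separation = min_separation, zero_band = zero_band,
                 amp_frac = amp_frac,
                 smooth_hz = smooth_hz, smooth_order = smooth_order),
            class = "segmentation_params")
}

# local extrema of a numeric vector; plateaus contribute their center
local_extrema_idx <- function(x, maxima = TRUE) {
  if (!maxima) x <- -x
  n <- length(x)
  if (n < 3) return(integer(0))
  d <- diff(x)
  s <- sign(d)
  # propagate the sign of the last nonzero slope across plateaus
  for (i in seq_along(s)) if (s[i] == 0 && i > 1) s[i] <- s[i - 1]
  idx <- which(diff(s) < 0) + 1L
  idx[idx > 1 & idx < n]
}

prominence_of <- function(x, idx, maxima = TRUE) {
  if (!maxima) x <- -x
  vapply(idx, function(i) {
    h <- x[i]
    left <- x[seq_len(i - 1)]
    right <- x[seq(i + 1, length(x))]
    lb <- which(left > h)
    lmin <- if (length(lb)) min(left[seq(max(lb) + 1L, i - 1L)]) else min(left)
    rb <- which(right > h)
    rmin <- if (length(rb)) min(right[seq_len(min(rb) - 1L)]) else min(right)
    h - max(lmin, rmin)
  }, 0)
}

#' Detect prominent peaks and valleys in a 1-D signal
#'
#' Local extrema with prominence at least `min_prominence` times the
#' signal's IQR; same-kind extrema closer than `min_separation` are thinned
#' greedily by descending prominence.
#'
#' @param x numeric driver signal.
#' @param params a [segmentation_params()].
#' @param rate sample rate, Hz.
#' @return data.frame with columns `index`, `kind` ("peak"/"valley"),
#'   `value`, `prominence`, ordered by index; possibly empty.
#' @export
detect_extrema <- function(x, params = segmentation_params(), rate) {
  stopifnot(length(x) >= 3, rate > 0)
  thr <- params$min_prominence * IQR(x)
  sep <- round(params$min_separation * rate)
  one_kind <- function(maxima) {
    idx <- local_extrema_idx(x, maxima)
    if (!length(idx)) return(NULL)
    prom <- prominence_of(x, idx, maxima)
    keep <- prom >= thr & prom > 0
    idx <- idx[keep]; prom <- prom[keep]
    if (!length(idx)) return(NULL)
    ord <- order(prom, decreasing = TRUE)
    chosen <- integer(0)
    for (i in ord) {
      if (!length(chosen) || all(abs(idx[i] - idx[chosen]) >= sep))
        chosen <- c(chosen, i)
    }
    data.frame(index = idx[chosen],
               kind = if (maxima) "peak" else "valley",
               value = x[idx[chosen]], prominence = prom[chosen])
  }
  out <- rbind(one_kind(TRUE), one_kind(FALSE))
  if (is.null(out))
    return(data.frame(index = integer(0), kind = character(0),
                      value = numeric(0), prominence = numeric(0)))
  out[order(out$index), , drop = FALSE]
}

# Boundary before a valley / after a peak: the zero crossing, evaluated
# with the zero_band tolerance - the last sample above -zero_band before
# the valley, the first sample below +zero_band after the peak. The band
# matters where the driver hovers near zero (standing spans): a strict
# sign test there is ill-conditioned, landing wherever noise or filter
# ripple last grazes zero. Fallback: midpoint to the adjacent extremum
# (or the search-window edge).
boundary_before_valley <- function(x, v, sep, zero_band, prev_extremum = NA) {
  lo <- max(1L, v - sep)
  win <- seq(lo, v)
  nn <- win[x[win] > -zero_band]
  if (length(nn)) return(max(nn))
  if (!is.na(prev_extremum)) return(floor((prev_extremum + v) / 2))
  lo
}

boundary_after_peak <- function(x, p, sep, zero_band, next_extremum = NA) {
  hi <- min(length(x), p + sep)
  win <- seq(p, hi)
  np <- win[x[win] < zero_band]
  if (length(np)) return(min(np))
  if (!is.na(next_extremum)) return(ceiling((p + next_extremum) / 2))
  hi
}

# Shared boundary rule on an already-smoothed driver. A repetition is an
# upward-push peak (positive vertical acceleration at the squat bottom)
# paired with its nearest preceding braking valley; boundaries are the
# zero crossings around the pair. Extrema whose value lies inside the
# sign-consistency band (max of zero_band and amp_frac x IQR) are
# discarded - a peak that never rises above zero cannot be flanked by the
# zero crossings the rule needs. Used both by segment_repetitions
# (estimated driver) and by the squat simulator when it derives
# ground-truth boundaries from its analytic kinematics.
driver_cycles <- function(driver, params, rate, min_index = 1L) {
  ext <- detect_extrema(driver, params, rate)
  ext <- ext[ext$index >= min_index, , drop = FALSE]
  if (!nrow(ext)) return(NULL)
  amp <- max(params$zero_band, params$amp_frac * IQR(driver))
  ext <- ext[(ext$kind == "peak" & ext$value > amp) |
               (ext$kind == "valley" & ext$value < -amp), , drop = FALSE]
  if (!nrow(ext)) return(NULL)
  sep <- round(params$min_separation * rate)
  peaks <- ext$index[ext$kind == "peak"]
  valleys <- ext$index[ext$kind == "valley"]
  if (!length(peaks) || !length(valleys)) return(NULL)
  used <- rep(FALSE, length(valleys))
  cycles <- NULL
  for (p in peaks) {
    cand <- which(valleys < p & !used)
    if (!length(cand)) next
    vi <- cand[which.max(valleys[cand])]  # nearest preceding unused valley
    used[vi] <- TRUE
    v <- valleys[vi]
    prev_e <- suppressWarnings(max(ext$index[ext$index < v]))
    next_e <- suppressWarnings(min(ext$index[ext$index > p]))
    s <- boundary_before_valley(driver, v, sep, params$zero_band,
                                if (is.finite(prev_e)) prev_e else NA)
    e <- boundary_after_peak(driver, p, sep, params$zero_band,
                             if (is.finite(next_e)) next_e else NA)
    cycles <- rbind(cycles, data.frame(start = s, end = e, valley = v, peak = p))
  }
  cycles
}

#' Segment a gravity-free trial into repetitions
#'
#' Applies peak/valley detection to the driver signal (Earth-frame vertical
#' sacrum 0g acceleration by default, smoothed at 2 Hz) and cuts one
#' segment per valley-then-peak cycle, from the zero crossing before the
#' valley to the zero crossing after the peak. Samples inside the
#' orientation warm-up are excluded; incomplete boundary cycles are
#' dropped.
#'
#' @param ztrial a [simulate_microgravity()] result.
#' @param params a [segmentation_params()].
#' @return list of `rep_segment` objects (possibly empty, with a warning
#'   when no extrema are found). Each carries `start_idx`/`end_idx`
#'   (1-based, half-open), times, the driver extrema, and the 36-signal
#'   window both at the pipeline's wide band (`window`) and 2 Hz-smoothed
#'   (`window_smooth`).
#' @export
segment_repetitions <- function(ztrial, params = segmentation_params()) {
  stopifnot(inherits(ztrial, "zerog_trial"))
  if (is.null(ztrial$sensors[[params$sensor]]))
    stop("driver sensor not present in trial: ", params$sensor)
  rate <- ztrial$rate
  driver_raw <- if (identical(params$channel, "earth_z")) {
    zerog_earth(ztrial, params$sensor)[, 3]
  } else {
    ztrial$sensors[[params$sensor]]$acc0g[, as.integer(params$channel)]
  }
  driver <- lowpass(driver_raw, params$smooth_hz, params$smooth_order,
                    rate = rate)
  min_index <- max(1L, ceiling(ztrial$warmup_s * rate))
  cycles <- driver_cycles(driver, params, rate, min_index)
  if (is.null(cycles) || !nrow(cycles)) {
    warning("no repetition cycles found in driver signal")
    return(list())
  }
  # enforce ordering / non-overlap on half-open intervals
  segs <- list()
  smooth_trial <- lapply(ztrial$sensors, function(s) list(
    acc0g = lowpass(s$acc0g, params$smooth_hz, params$smooth_order, rate = rate),
    gyro = lowpass(s$gyro, params$smooth_hz, params$smooth_order, rate = rate)))
  prev_end <- 0L
  dropped <- 0L
  for (r in seq_len(nrow(cycles))) {
    s <- max(cycles$start[r], prev_end + 1L)
    e <- cycles$end[r]
    if (e <= s) { dropped <- dropped + 1L; next }
    win <- seq(s, e - 1L)
    segs[[length(segs) + 1L]] <- structure(list(
      start_idx = s, end_idx = e,
      t_start = ztrial$t[s], t_end = ztrial$t[e],
      driver_extrema = c(valley = cycles$valley[r], peak = cycles$peak[r]),
      window = lapply(ztrial$sensors, function(sn) list(
        acc0g = sn$acc0g[win, , drop = FALSE],
        gyro = sn$gyro[win, , drop = FALSE])),
      window_smooth = lapply(smooth_trial, function(sn) list(
        acc0g = sn$acc0g[win, , drop = FALSE],
        gyro = sn$gyro[win, , drop = FALSE])),
      rate = rate, label = ztrial$label), class = "rep_segment")
    prev_end <- e - 1L
  }
  if (dropped) message(dropped, " degenerate cycle(s) dropped")
  segs
}

#' @export
print.rep_segment <- function(x, ...) {
  cat(sprintf("<rep_segment> [%.2f, %.2f) s, %d samples @ %g Hz\n",
              x$t_start, x$t_end, x$end_idx - x$start_idx, x$rate))
  invisible(x)
}

#' Segment index table
#'
#' @param segments list of `rep_segment` objects.
#' @return data.frame `rep_id, start_idx, end_idx, start_s, end_s`
#'   (indices 0-based half-open, matching the on-disk convention).
#' @export
segments_index <- function(segments) {
  data.frame(
    rep_id = seq_along(segments) - 1L,
    start_idx = vapply(segments, function(s) s$start_idx - 1L, 0L),
    end_idx = vapply(segments, function(s) s$end_idx - 1L, 0L),
    start_s = vapply(segments, `[[`, 0, "t_start"),
    end_s = vapply(segments, `[[`, 0, "t_end"))
}
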