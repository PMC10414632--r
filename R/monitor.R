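# Simulated real-time monitoring: a sample-stream transport over a
# recorded/simulated trial, causal filtering and orientation updates, an
# online repetition segmenter (turning-point detection with a trailing
# zero-crossing confirmation and a short guard), and per-repetition
# classification with mixed-error advice.

#' Stream a trial as per-timestep sample bundles
#'
#' Transport abstraction replacing live sensor links: yields one bundle
#' per timestep containing the six sensors' 9-axis samples, in order.
#'
#' @param trial an aligned [imu_trial()].
#' @param speed playback speed multiplier; `Inf` (default) yields without
#'   pacing, 1 paces to wall-clock real time.
#' @return object of class `trial_stream` with functions `has_next()` and
#'   `next_bundle()`.
#' @export
stream_trial <- function(trial, speed = Inf) {
  stopifnot(inherits(trial, "imu_trial"))
  n <- length(trial$streams[[1]]$t)
  i <- 0L
  pace <- if (is.finite(speed) && speed > 0) (1 / trial$rate) / speed else 0
  structure(list(
    rate = trial$rate, n = n, label = trial$label, meta = trial$meta,
    has_next = function() i < n,
    next_bundle = function() {
      if (i >= n) return(NULL)
      i <<- i + 1L
      if (pace > 0) Sys.sleep(pace)
      list(t = trial$streams[[1]]$t[i],
           sensors = lapply(trial$streams, function(s) list(
             acc = s$acc[i, ], gyro = s$gyro[i, ],
             mag = if (is.null(s$mag)) NULL else s$mag[i, ])))
    }), class = "trial_stream")
}

#' Collect a stream back into a trial
#'
#' @param stream a [stream_trial()] object.
#' @return an [imu_trial()] equal to the streamed input.
#' @export
collect_stream <- function(stream) {
  bundles <- list()
  while (stream$has_next()) bundles[[length(bundles) + 1L]] <- stream$next_bundle()
  t <- vapply(bundles, `[[`, 0, "t")
  streams <- lapply(sensor_sites(), function(sid) {
    acc <- t(vapply(bundles, function(b) b$sensors[[sid]]$acc, numeric(3)))
    gyro <- t(vapply(bundles, function(b) b$sensors[[sid]]$gyro, numeric(3)))
    m1 <- bundles[[1]]$sensors[[sid]]$mag
    mag <- if (is.null(m1)) NULL
           else t(vapply(bundles, function(b) b$sensors[[sid]]$mag, numeric(3)))
    imu_stream(sid, t, acc, gyro, mag, stream$rate)
  })
  names(streams) <- sensor_sites()
  imu_trial(streams, label = stream$label, meta = stream$meta)
}

# Online turning-point extremum detector state machine: confirms an
# extremum once the signal has reversed away from it by the prominence
# threshold; same-kind confirmations closer than the separation keep the
# more extreme sample.
online_segmenter_events <- function(driver, rate, params, skip_n) {
  sep <- round(params$min_separation * rate)
  n <- length(driver)
  refresh <- max(1L, round(0.5 * rate))
  hist_n <- round(10 * rate)
  prom_thr <- Inf; amp_thr <- Inf
  cand_idx <- skip_n; cand_kind <- NA  # tracked running extremum
  pending_valley <- NA
  peaks <- integer(0); valleys <- integer(0)
  await <- NULL  # confirmed (valley, peak) waiting for its zero crossing
  guard <- round(0.25 * rate)
  out <- NULL
  for (i in seq(max(skip_n, 2L), n)) {
    if (i %% refresh == 0 || !is.finite(prom_thr)) {
      h <- driver[max(skip_n, i - hist_n):i]
      iq <- IQR(h)
      if (iq > 0) {
        prom_thr <- params$min_prominence * iq
        amp_thr <- max(params$zero_band, params$amp_frac * iq)
      }
    }
    x <- driver[i]
    if (is.na(cand_kind)) {
      if (x > driver[cand_idx] + prom_thr) { cand_kind <- "valley" }
      else if (x < driver[cand_idx] - prom_thr) { cand_kind <- "peak" }
      if (!is.na(cand_kind)) cand_idx <- i
    } else if (cand_kind == "peak") {
      # tracking a falling signal: candidate valley at the running minimum
      if (x < driver[cand_idx]) cand_idx <- i
      else if (x > driver[cand_idx] + prom_thr) {
        v <- cand_idx
        if (driver[v] < -amp_thr) {
          if (length(valleys) && v - valleys[length(valleys)] < sep) {
            if (driver[v] < driver[valleys[length(valleys)]])
              valleys[length(valleys)] <- v
          } else valleys <- c(valleys, v)
          pending_valley <- valleys[length(valleys)]
        }
        cand_kind <- "valley"; cand_idx <- i
      }
    } else {
      if (x > driver[cand_idx]) cand_idx <- i
      else if (x < driver[cand_idx] - prom_thr) {
        p <- cand_idx
        if (driver[p] > amp_thr && !is.na(pending_valley)) {
          if (!length(peaks) || p - peaks[length(peaks)] >= sep) {
            peaks <- c(peaks, p)
            await <- c(valley = pending_valley, peak = p)
            pending_valley <- NA
          }
        }
        cand_kind <- "peak"; cand_idx <- i
      }
    }
    if (!is.null(await) && i > await[["peak"]] &&
        driver[i] < params$zero_band) {
      end <- i
      start <- boundary_before_valley(driver, await[["valley"]], sep,
                                      params$zero_band)
      out <- rbind(out, data.frame(start = start, end = end,
                                   valley = await[["valley"]],
                                   peak = await[["peak"]],
                                   emit = min(n, end + guard)))
      await <- NULL
    }
  }
  out
}

#' Run the simulated real-time monitoring loop
#'
#' Processes a trial strictly causally - single-pass (non-zero-phase)
#' Butterworth filtering, sequential Mahony orientation updates, causal
#' gravity removal and an online segmenter - and classifies each
#' repetition as soon as its trailing zero crossing plus a 0.25 s guard
#' has streamed. No event's window extends past the samples already seen
#' at emission time.
#'
#' @param x an [imu_trial()] or a [stream_trial()] object.
#' @param model a [train()] result bundling scaler and feature selection.
#' @param params a [segmentation_params()].
#' @param gains a [mahony_gains()].
#' @param cutoff_hz wide-band causal pre-filter cutoff, Hz.
#' @param warmup_s seconds ignored while the orientation converges.
#' @return list of `monitor_event`s: `rep`, `t_start`, `t_end`,
#'   `t_emit`, `label`, `probs`, `advice`, `latency_ms`.
#' @export
online_monitor <- function(x, model, params = segmentation_params(),
                           gains = mahony_gains(), cutoff_hz = 20,
                           warmup_s = 5) {
  stopifnot(inherits(model, "squat_model"))
  if (is.null(model$scaler) || is.null(model$selection))
    stop("model bundle incomplete: scaler and feature selection are required before streaming")
  trial <- if (inherits(x, "trial_stream")) collect_stream(x) else x
  n <- length(trial$streams[[1]]$t)
  if (n == 0) return(list())
  rate <- trial$rate
  # causal preprocessing per sensor (filter, Mahony, gravity removal)
  sensors <- lapply(trial$streams, function(s) {
    sf <- lowpass(s, cutoff_hz, 6, zero_phase = FALSE)
    trk <- estimate_orientation(sf, gains)
    acc0g <- remove_gravity(sf, trk)
    list(acc0g = acc0g,
         gyro = sf$gyro,
         acc0g_sm = lowpass(acc0g, params$smooth_hz, params$smooth_order,
                            rate = rate, zero_phase = FALSE),
         gyro_sm = lowpass(sf$gyro, params$smooth_hz, params$smooth_order,
                           rate = rate, zero_phase = FALSE),
         track = trk)
  })
  drv_sensor <- sensors[[params$sensor]]
  driver_e <- quat_rotate(drv_sensor$track$q, drv_sensor$acc0g)[, 3]
  driver <- lowpass(driver_e, params$smooth_hz, params$smooth_order,
                    rate = rate, zero_phase = FALSE)
  cyc <- online_segmenter_events(driver, rate, params,
                                 skip_n = max(1L, round(warmup_s * rate)))
  if (is.null(cyc)) return(list())
  events <- list()
  for (r in seq_len(nrow(cyc))) {
    s <- cyc$start[r]; e <- cyc$end[r]
    if (e - s < 8) next
    win <- seq(s, e - 1L)
    seg <- structure(list(
      start_idx = s, end_idx = e,
      t_start = trial$streams[[1]]$t[s], t_end = trial$streams[[1]]$t[e],
      driver_extrema = c(valley = cyc$valley[r], peak = cyc$peak[r]),
      window = lapply(sensors, function(sn) list(
        acc0g = sn$acc0g[win, , drop = FALSE],
        gyro = sn$gyro[win, , drop = FALSE])),
      window_smooth = lapply(sensors, function(sn) list(
        acc0g = sn$acc0g_sm[win, , drop = FALSE],
        gyro = sn$gyro_sm[win, , drop = FALSE])),
      rate = rate, label = trial$label), class = "rep_segment")
    t0 <- proc.time()[["elapsed"]]
    row <- extract_features(seg)
    rep_report <- predict_report(model, row)
    lat <- (proc.time()[["elapsed"]] - t0) * 1000
    events[[length(events) + 1L]] <- structure(list(
      rep = length(events) + 1L,
      t_start = seg$t_start, t_end = seg$t_end,
      t_emit = trial$streams[[1]]$t[cyc$emit[r]],
      label = rep_report$label, probs = rep_report$probs,
      advice = rep_report$advice, latency_ms = lat),
      class = "monitor_event")
  }
  events
}

#' @export
print.monitor_event <- function(x, ...) {
  cat(sprintf("<monitor_event> rep %d [%.2f, %.2f) s -> %s (p=%.2f)%s\n",
              x$rep, x$t_start, x$t_end, x$label, max(x$probs),
              if (length(x$advice))
                paste0(" advice: ", paste(x$advice, collapse = "+")) else ""))
  invisible(x)
}

#' Default advice strings per error class
#'
#' @return named character vector mapping error classes to corrective
#'   feedback text.
#' @export
advice_table <- function() {
  c(KOT = "keep knees behind the toes",
    VK = "push knees outward",
    RB = "keep the back straight",
    RH = "keep heels on the ground",
    SH = "squat deeper")
}
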