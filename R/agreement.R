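# Paired-sensor validation: time-domain Pearson correlation and Welch
# magnitude squared coherence between co-located sensor systems, after
# integer-lag cross-correlation alignment.

#' Align two series (or streams) by integer-sample lag
#'
#' Finds the integer lag maximizing the normalized cross-correlation of
#' the two series and shifts the second onto the first, trimming to the
#' common span. When the correlation peak is weak (< `min_peak`) a zero
#' lag is used with a warning.
#'
#' @param a,b numeric vectors at a common rate (resample first if needed).
#' @param max_lag_s largest lag searched, s.
#' @param rate sample rate, Hz.
#' @param min_peak minimum acceptable normalized cross-correlation peak.
#' @return list with `a`, `b` (aligned, equal length) and `lag` (samples;
#'   positive means `b` lags `a`).
#' @export
align_pair <- function(a, b, rate, max_lag_s = 2, min_peak = 0.2) {
  n <- min(length(a), length(b))
  if (n < 3) stop("series too short to align")
  maxl <- min(n - 2, round(max_lag_s * rate))
  az <- a[seq_len(n)] - mean(a[seq_len(n)])
  bz <- b[seq_len(n)] - mean(b[seq_len(n)])
  cc <- vapply(-maxl:maxl, function(l) {
    if (l >= 0) {
      ai <- az[seq_len(n - l)]; bi <- bz[seq_len(n - l) + l]
    } else {
      ai <- az[seq_len(n + l) - l]; bi <- bz[seq_len(n + l)]
    }
    if (sd(ai) == 0 || sd(bi) == 0) return(0)
    cor(ai, bi)
  }, 0)
  lag <- (-maxl:maxl)[which.max(cc)]
  if (max(cc) < min_peak) {
    warning(sprintf("cross-correlation peak %.2f below %.2f; using zero lag",
                    max(cc), min_peak))
    lag <- 0L
  }
  if (lag >= 0) {
    list(a = a[seq_len(n - lag)], b = b[seq_len(n - lag) + lag], lag = lag)
  } else {
    list(a = a[seq_len(n + lag) - lag], b = b[seq_len(n + lag)], lag = lag)
  }
}

#' Pearson correlation of two aligned series
#'
#' @param a,b equal-length numeric vectors (length >= 3, non-constant).
#' @return Pearson R in `[-1, 1]`.
#' @export
pearson_r <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 3)
  if (sd(a) == 0 || sd(b) == 0)
    stop("correlation undefined for constant input")
  cor(a, b)
}

hann <- function(n) 0.5 - 0.5 * cos(2 * pi * seq(0, n - 1) / (n - 1))

welch_spectra <- function(a, b, rate, window_s, overlap) {
  nw <- round(window_s * rate)
  hop <- max(1L, round(nw * (1 - overlap)))
  n <- min(length(a), length(b))
  starts <- if (n >= nw + hop) seq(1L, n - nw + 1L, by = hop) else integer(0)
  if (length(starts) < 2)
    stop("fewer than 2 Welch windows; coherence of a single window is identically 1")
  w <- hann(nw)
  m <- floor(nw / 2) + 1L
  paa <- pbb <- numeric(m)
  pab <- complex(m)
  for (s in starts) {
    ai <- a[s:(s + nw - 1)]; bi <- b[s:(s + nw - 1)]
    fa <- fft((ai - mean(ai)) * w)[seq_len(m)]
    fb <- fft((bi - mean(bi)) * w)[seq_len(m)]
    paa <- paa + Mod(fa)^2
    pbb <- pbb + Mod(fb)^2
    pab <- pab + Conj(fa) * fb
  }
  list(freq = (seq_len(m) - 1) * rate / nw,
       paa = paa / length(starts), pbb = pbb / length(starts),
       pab = pab / length(starts))
}

#' Welch magnitude squared coherence
#'
#' Cross-spectral coherence |P_ab|^2 / (P_aa P_bb) estimated with Hann
#' windows and 50% overlap, plus a scalar summary averaged over the
#' movement band (default 0.1-5 Hz, where squat energy lives).
#'
#' @param a,b aligned numeric vectors at `rate` Hz.
#' @param rate sample rate, Hz.
#' @param window_s Welch window length, s.
#' @param overlap window overlap fraction.
#' @param band summary frequency band, Hz.
#' @param weighted when TRUE the band summary weights each bin by the
#'   geometric-mean auto-power, so near-periodic movement (a line
#'   spectrum) is judged at the frequencies that actually carry signal
#'   rather than diluted by empty inter-harmonic bins.
#' @return list with `band_msc` (scalar in `[0, 1]`), `freq`, `msc`
#'   (per-frequency curve).
#' @export
msc <- function(a, b, rate, window_s = 2, overlap = 0.5, band = c(0.1, 5),
                weighted = FALSE) {
  sp <- welch_spectra(a, b, rate, window_s, overlap)
  denom <- sp$paa * sp$pbb
  curve <- ifelse(denom > 0, Mod(sp$pab)^2 / denom, 0)
  curve <- pmin(1, pmax(0, curve))
  in_band <- sp$freq >= band[1] & sp$freq <= band[2]
  if (!any(in_band)) stop("summary band contains no frequency bins")
  w <- if (weighted) sqrt(denom[in_band]) else rep(1, sum(in_band))
  if (sum(w) <= 0) w <- rep(1, length(w))
  list(band_msc = sum(curve[in_band] * w) / sum(w),
       freq = sp$freq, msc = curve)
}

#' Paired-trial sensor agreement report
#'
#' Compares two co-located recordings of the same movement: per sensor and
#' axis, Pearson R and band-averaged MSC for raw acceleration, gravity-free
#' acceleration and angular velocity, averaged over axes and sensors into
#' one row per signal family (the shape of a sensor-validation summary
#' table). Streams are aligned with [align_pair()] on the driver channel.
#'
#' @param trial_a,trial_b aligned six-sensor [imu_trial()]s at a common
#'   rate.
#' @param gains a [mahony_gains()] for the gravity-removal step.
#' @param subject label for the report row.
#' @param msc_flag_threshold MSC level under which a family is flagged.
#' @param min_sd_frac channels whose standard deviation falls below this
#'   fraction of their family's most active channel are excluded from the
#'   family means (a channel that carries no movement, only noise, has no
#'   agreement information); they remain listed per channel.
#' @return list with `summary` (one-row data.frame: `subject, R_acc, R_0g,
#'   R_gyro, MSC_acc, MSC_0g, MSC_gyro, lag_samples, flagged`), and
#'   `per_channel`.
#' @export
sensor_agreement <- function(trial_a, trial_b, gains = mahony_gains(),
                             subject = "S01", msc_flag_threshold = 0.5,
                             min_sd_frac = 0.1) {
  stopifnot(abs(trial_a$rate - trial_b$rate) < 1e-9)
  rate <- trial_a$rate
  za <- simulate_microgravity(trial_a, gains)
  zb <- simulate_microgravity(trial_b, gains)
  drv_a <- zerog_earth(za)[, 3]; drv_b <- zerog_earth(zb)[, 3]
  al <- align_pair(drv_a, drv_b, rate)
  idx_a <- seq_along(al$a) + (if (al$lag < 0) -al$lag else 0L)
  idx_b <- seq_along(al$b) + (if (al$lag > 0) al$lag else 0L)
  rows <- NULL
  for (sid in sensor_sites()) {
    fam <- list(
      acc = list(trial_a$streams[[sid]]$acc, trial_b$streams[[sid]]$acc),
      `0g` = list(za$sensors[[sid]]$acc0g, zb$sensors[[sid]]$acc0g),
      gyro = list(za$sensors[[sid]]$gyro, zb$sensors[[sid]]$gyro))
    for (fn in names(fam)) {
      for (ax in 1:3) {
        xa <- fam[[fn]][[1]][idx_a, ax]; xb <- fam[[fn]][[2]][idx_b, ax]
        r <- if (sd(xa) == 0 || sd(xb) == 0) NA_real_ else pearson_r(xa, xb)
        mm <- tryCatch(msc(xa, xb, rate, weighted = TRUE)$band_msc,
                       error = function(e) NA_real_)
        rows <- rbind(rows, data.frame(sensor = sid, family = fn, axis = ax,
                                       sd_a = sd(xa), R = r, MSC = mm))
      }
    }
  }
  rows$active <- FALSE
  for (fn in unique(rows$family)) {
    sel <- rows$family == fn
    rows$active[sel] <- rows$sd_a[sel] >= min_sd_frac * max(rows$sd_a[sel])
  }
  fammean <- function(fn, col)
    mean(rows[rows$family == fn & rows$active, col], na.rm = TRUE)
  summary <- data.frame(subject = subject,
                        R_acc = fammean("acc", "R"),
                        R_0g = fammean("0g", "R"),
                        R_gyro = fammean("gyro", "R"),
                        MSC_acc = fammean("acc", "MSC"),
                        MSC_0g = fammean("0g", "MSC"),
                        MSC_gyro = fammean("gyro", "MSC"),
                        lag_samples = al$lag)
  summary$flagged <- with(summary, min(MSC_acc, MSC_0g, MSC_gyro) <
                            msc_flag_threshold)
  list(summary = summary, per_channel = rows)
}
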