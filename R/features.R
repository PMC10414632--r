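# Per-repetition feature bank: 375 features per sensor, 2250 per
# six-sensor repetition. Time-domain statistics are computed on the
# 2 Hz-smoothed signals (the band where squat kinematics live), spectral
# statistics on the 20 Hz signals (which still carry a spectrum). All
# statistics are length-invariant (means, not sums), so repetitions of
# different durations are comparable without resampling.

time_triaxial <- c("tAcc0g", "tGyro", "tAccJerk", "tGyroJerk")
time_scalar <- c("tAcc0gMag", "tGyroMag", "tAccJerkMag", "tGyroJerkMag")
freq_triaxial <- c("fAcc0g", "fGyro", "fAccJerk")
freq_scalar <- c("fAcc0gMag", "fGyroMag", "fAccJerkMag", "fGyroJerkMag")
stats_common <- c("mean", "sd", "mad", "max", "min", "energy", "iqr", "entropy")
stats_freq_only <- c("maxInds", "meanFreq", "skewness", "kurtosis")

per_sensor_inventory <- function() {
  rows <- list()
  add <- function(signal, statistic, axis) {
    rows[[length(rows) + 1L]] <<- data.frame(signal = signal,
                                             statistic = statistic,
                                             axis = axis)
  }
  for (sg in time_triaxial) {
    for (st in stats_common) for (ax in c("X", "Y", "Z")) add(sg, st, ax)
    add(sg, "sma", "XYZ")
    for (ax in c("X", "Y", "Z")) for (k in 1:4) add(sg, paste0("ar", k), ax)
    for (pr in c("XY", "XZ", "YZ")) add(sg, "corr", pr)
  }
  for (sg in time_scalar) {
    for (st in stats_common) add(sg, st, "mag")
    add(sg, "sma", "mag")
    for (k in 1:4) add(sg, paste0("ar", k), "mag")
  }
  for (sg in freq_triaxial) {
    for (st in stats_common) for (ax in c("X", "Y", "Z")) add(sg, st, ax)
    add(sg, "sma", "XYZ")
    for (st in stats_freq_only) for (ax in c("X", "Y", "Z")) add(sg, st, ax)
  }
  for (sg in freq_scalar) {
    for (st in c(stats_common, "sma", stats_freq_only)) add(sg, st, "mag")
  }
  do.call(rbind, rows)
}

#' The feature registry (2250 features, 375 per sensor)
#'
#' Ordered registry of (sensor, signal, statistic, axis) entries defining
#' the feature bank: for every sensor, time-domain gravity-free
#' acceleration, angular velocity and their jerk signals (per axis and as
#' Euclidean magnitudes) described by mean, SD, MAD, max, min, SMA,
#' energy, IQR and entropy, plus 4th-order Burg autoregressive
#' coefficients and axis-pair correlations; and one-sided spectra of the
#' same signal family described by the shared statistics plus index of the
#' spectral maximum (maxInds), power-weighted mean frequency, skewness and
#' kurtosis of the spectral magnitude distribution.
#'
#' @return object of class `feature_inventory`: data.frame with columns
#'   `index`, `sensor`, `signal`, `statistic`, `axis` and a `name` built
#'   as `sensor_signal_statistic_axis`.
#' @export
feature_inventory <- function() {
  per <- per_sensor_inventory()
  inv <- do.call(rbind, lapply(sensor_sites(), function(sid) {
    cbind(sensor = sid, per)
  }))
  inv$name <- paste(inv$sensor, inv$signal, inv$statistic, inv$axis, sep = "_")
  stopifnot(!anyDuplicated(inv$name))
  inv <- cbind(index = seq_len(nrow(inv)), inv)
  class(inv) <- c("feature_inventory", "data.frame")
  inv
}

#' @export
print.feature_inventory <- function(x, ...) {
  cat(sprintf("<feature_inventory> %d features (%d per sensor x %d sensors)\n",
              nrow(x), nrow(x) / length(sensor_sites()),
              length(sensor_sites())))
  invisible(x)
}

#' Write the feature manifest to a TSV file
#'
#' @param path destination; defaults to `feature_manifest.tsv`.
#' @param inventory a [feature_inventory()].
#' @return the path, invisibly.
#' @export
write_feature_manifest <- function(path = "feature_manifest.tsv",
                                   inventory = feature_inventory()) {
  utils::write.table(as.data.frame(inventory), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

magnitude <- function(m) sqrt(rowSums(m^2))

one_sided_spectrum <- function(x, rate) {
  n <- length(x)
  m <- floor(n / 2) + 1L
  list(mag = Mod(fft(x))[seq_len(m)] / n,
       freq = (seq_len(m) - 1) * rate / n)
}

#' Derived signal set of one repetition
#'
#' Builds, per sensor, the time-domain triaxial signals (gravity-free
#' acceleration, angular velocity, and their jerks - first differences
#' scaled by the rate), their Euclidean-magnitude scalars, and one-sided
#' FFT magnitude spectra of the signal family. Time-domain signals come
#' from the 2 Hz-smoothed window, spectra from the 20 Hz window.
#'
#' @param segment a `rep_segment` (see [segment_repetitions()]).
#' @param min_len segments shorter than this are rejected.
#' @return named list per sensor; each entry holds `time` (named list of
#'   vectors/matrices) and `freq` (named list of `mag`/`freq` spectra per
#'   axis).
#' @export
derive_signals <- function(segment, min_len = 8) {
  stopifnot(inherits(segment, "rep_segment"))
  n <- segment$end_idx - segment$start_idx
  if (n < min_len)
    stop(sprintf("segment too short for feature extraction (%d < %d samples)",
                 n, min_len))
  rate <- segment$rate
  jerk <- function(m) {
    if (is.null(dim(m))) diff(m) * rate
    else apply(m, 2, function(c) diff(c) * rate)
  }
  lapply(sensor_sites(), function(sid) {
    sm <- segment$window_smooth[[sid]]
    wd <- segment$window[[sid]]
    tsig <- list(tAcc0g = sm$acc0g, tGyro = sm$gyro,
                 tAccJerk = jerk(sm$acc0g), tGyroJerk = jerk(sm$gyro))
    tsig$tAcc0gMag <- magnitude(tsig$tAcc0g)
    tsig$tGyroMag <- magnitude(tsig$tGyro)
    tsig$tAccJerkMag <- magnitude(tsig$tAccJerk)
    tsig$tGyroJerkMag <- magnitude(tsig$tGyroJerk)
    wsig <- list(fAcc0g = wd$acc0g, fGyro = wd$gyro,
                 fAccJerk = jerk(wd$acc0g))
    wsig$fAcc0gMag <- magnitude(wd$acc0g)
    wsig$fGyroMag <- magnitude(wd$gyro)
    wsig$fAccJerkMag <- magnitude(wsig$fAccJerk)
    wsig$fGyroJerkMag <- magnitude(jerk(wd$gyro))
    fsig <- lapply(wsig, function(s) {
      if (is.null(dim(s))) list(mag = one_sided_spectrum(s, rate))
      else lapply(seq_len(ncol(s)),
                  function(j) one_sided_spectrum(s[, j], rate))
    })
    list(time = tsig, freq = fsig)
  }) -> out
  names(out) <- sensor_sites()
  out
}

entropy_hist <- function(x, bins = 16) {
  r <- range(x)
  if (!all(is.finite(r)) || diff(r) == 0) return(0)
  p <- tabulate(pmin(bins, 1L + floor((x - r[1]) / diff(r) * bins)), bins)
  p <- p / sum(p)
  p <- p[p > 0]
  -sum(p * log(p))
}

spectral_entropy <- function(mag) {
  p <- mag^2
  s <- sum(p)
  if (s <= 0 || length(p) < 2) return(0)
  p <- p / s
  p <- p[p > 0]
  -sum(p * log(p)) / log(length(mag))
}

burg_ar4 <- function(x) {
  co <- tryCatch(stats::ar.burg(x, aic = FALSE, order.max = 4,
                                demean = TRUE)$ar,
                 error = function(e) numeric(0))
  out <- numeric(4)
  out[seq_along(co)] <- co
  out
}

common_stats <- function(x) {
  c(mean = mean(x), sd = sd(x), mad = mad(x), max = max(x), min = min(x),
    energy = mean(x^2), iqr = IQR(x), entropy = entropy_hist(x))
}

spectral_stats <- function(sp) {
  mag <- sp$mag; f <- sp$freq
  pw <- mag^2
  c(mean = mean(mag), sd = sd(mag), mad = mad(mag), max = max(mag),
    min = min(mag), energy = mean(mag^2), iqr = IQR(mag),
    entropy = spectral_entropy(mag),
    maxInds = which.max(mag),
    meanFreq = if (sum(pw) > 0) sum(f * pw) / sum(pw) else 0,
    skewness = e1071::skewness(mag),
    kurtosis = e1071::kurtosis(mag))
}

#' Extract the feature row of one repetition
#'
#' Computes every registry statistic for the segment, in registry order.
#' Non-finite results (degenerate spectra of constant signals and the
#' like) are set to 0 and counted in the `n_nonfinite` attribute.
#'
#' @param segment a `rep_segment`.
#' @param inventory a [feature_inventory()] (used to assert the declared
#'   layout; the computation follows the same registry construction).
#' @return named numeric vector of length `nrow(inventory)`.
#' @export
extract_features <- function(segment, inventory = feature_inventory()) {
  sigs <- derive_signals(segment)
  axcol <- c(X = 1L, Y = 2L, Z = 3L)
  row <- numeric(0)
  for (sid in sensor_sites()) {
    sn <- sigs[[sid]]
    vals <- list()
    for (sg in time_triaxial) {
      m <- sn$time[[sg]]
      cs3 <- lapply(1:3, function(j) common_stats(m[, j]))
      for (st in stats_common) for (ax in c("X", "Y", "Z"))
        vals[[paste(sg, st, ax, sep = "_")]] <- cs3[[axcol[[ax]]]][[st]]
      vals[[paste(sg, "sma", "XYZ", sep = "_")]] <- mean(rowSums(abs(m)))
      for (ax in c("X", "Y", "Z")) {
        ar <- burg_ar4(m[, axcol[[ax]]])
        for (k in 1:4) vals[[paste(sg, paste0("ar", k), ax, sep = "_")]] <- ar[k]
      }
      for (pr in list(c("X", "Y"), c("X", "Z"), c("Y", "Z"))) {
        r <- suppressWarnings(cor(m[, axcol[[pr[1]]]], m[, axcol[[pr[2]]]]))
        vals[[paste(sg, "corr", paste0(pr, collapse = ""), sep = "_")]] <- r
      }
    }
    for (sg in time_scalar) {
      x <- sn$time[[sg]]
      cs <- common_stats(x)
      for (st in stats_common) vals[[paste(sg, st, "mag", sep = "_")]] <- cs[[st]]
      vals[[paste(sg, "sma", "mag", sep = "_")]] <- mean(abs(x))
      ar <- burg_ar4(x)
      for (k in 1:4) vals[[paste(sg, paste0("ar", k), "mag", sep = "_")]] <- ar[k]
    }
    for (sg in freq_triaxial) {
      sps <- sn$freq[[sg]]
      st3 <- lapply(1:3, function(j) spectral_stats(sps[[j]]))
      for (st in stats_common) for (ax in c("X", "Y", "Z"))
        vals[[paste(sg, st, ax, sep = "_")]] <- st3[[axcol[[ax]]]][[st]]
      vals[[paste(sg, "sma", "XYZ", sep = "_")]] <-
        mean(abs(sps[[1]]$mag) + abs(sps[[2]]$mag) + abs(sps[[3]]$mag))
      for (st in stats_freq_only) for (ax in c("X", "Y", "Z"))
        vals[[paste(sg, st, ax, sep = "_")]] <- st3[[axcol[[ax]]]][[st]]
    }
    for (sg in freq_scalar) {
      sp <- sn$freq[[sg]]$mag
      ss <- spectral_stats(sp)
      for (st in stats_common) vals[[paste(sg, st, "mag", sep = "_")]] <- ss[[st]]
      vals[[paste(sg, "sma", "mag", sep = "_")]] <- mean(abs(sp$mag))
      for (st in stats_freq_only) vals[[paste(sg, st, "mag", sep = "_")]] <- ss[[st]]
    }
    v <- unlist(vals)
    names(v) <- paste(sid, names(v), sep = "_")
    row <- c(row, v)
  }
  if (!identical(names(row), inventory$name))
    stop("feature layout does not match the inventory")
  bad <- !is.finite(row)
  row[bad] <- 0
  attr(row, "n_nonfinite") <- sum(bad)
  row
}

#' Build a feature table from labelled segments
#'
#' @param segments list of `rep_segment` objects (e.g. pooled across
#'   trials); each must carry a label.
#' @param inventory a [feature_inventory()].
#' @param provenance optional data.frame (one row per segment).
#' @return object of class `feature_table`: `x` (repetitions x features
#'   matrix), `features`, `labels` (factor), `provenance`, `scaled`.
#' @export
feature_table <- function(segments, inventory = feature_inventory(),
                          provenance = NULL) {
  stopifnot(length(segments) > 0)
  x <- t(vapply(segments, function(s) as.numeric(extract_features(s, inventory)),
                numeric(nrow(inventory))))
  colnames(x) <- inventory$name
  labels <- squat_label(vapply(segments, function(s) as.character(s$label), ""))
  if (any(!is.finite(x))) stop("feature table contains non-finite values")
  structure(list(x = x, features = inventory$name, labels = labels,
                 provenance = provenance, scaled = FALSE),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %d repetitions x %d features (%s)\n",
              nrow(x$x), ncol(x$x),
              if (x$scaled) "scaled" else "raw"))
  print(table(x$labels))
  invisible(x)
}

#' Fit a robust scaler (median / IQR) on training rows
#'
#' @param table a [feature_table()].
#' @param train_rows integer or logical row selector; statistics are fitted
#'   on these rows only so no test information leaks into scaling.
#' @return object of class `scaler_params`: per-feature `center` (median)
#'   and `scale` (IQR; constant features get scale 1 and are flagged).
#' @export
fit_scaler <- function(table, train_rows = seq_len(nrow(table$x))) {
  x <- table$x[train_rows, , drop = FALSE]
  if (nrow(x) < 2) stop("need at least 2 training rows to fit the scaler")
  center <- apply(x, 2, median)
  scale <- apply(x, 2, IQR)
  constant <- scale <= 0
  scale[constant] <- 1
  structure(list(center = center, scale = scale, constant = constant,
                 features = table$features),
            class = "scaler_params")
}

#' Apply (or invert) a robust scaler
#'
#' @param table a [feature_table()].
#' @param params a [fit_scaler()] result.
#' @param invert logical; TRUE maps scaled values back to raw units.
#' @return a transformed [feature_table()].
#' @export
apply_scaler <- function(table, params, invert = FALSE) {
  stopifnot(inherits(params, "scaler_params"))
  idx <- match(table$features, params$features)
  if (any(is.na(idx))) stop("scaler was fitted on different features")
  ctr <- params$center[idx]; scl <- params$scale[idx]
  out <- table
  out$x <- if (invert) sweep(sweep(table$x, 2, scl, "*"), 2, ctr, "+")
           else sweep(sweep(table$x, 2, ctr, "-"), 2, scl, "/")
  out$scaled <- !invert
  out
}

svm_feature_importance <- function(x, y, cost = 1) {
  fit <- e1071::svm(x, y, kernel = "linear", cost = cost, scale = FALSE)
  w <- t(fit$coefs) %*% fit$SV  # one row per binary subproblem
  colSums(w^2)[match(colnames(x), colnames(fit$SV))]
}

#' Recursive feature elimination with a linear maximal-margin ranker
#'
#' Repeatedly fits a linear SVM and removes the 5% (of remaining)
#' lowest-importance features (squared weight summed over the one-vs-one
#' subproblems) until the target count remains. With a vector of target
#' counts, each candidate is scored by stratified cross-validation
#' accuracy of the ranker on the selected columns and the best count wins
#' (ties to the smaller count).
#'
#' @param table a scaled [feature_table()].
#' @param labels class labels (defaults to the table's own).
#' @param target_count single target or sweep vector of candidate counts.
#' @param step fraction of remaining features removed per round.
#' @param cv_k folds for the sweep scoring.
#' @param seed RNG seed controlling fold assignment.
#' @return object of class `selected_features`: `features` (ordered
#'   selected names), `target_count`, `ranking` (full elimination-order
#'   ranking, best first), and `sweep` (data.frame, when swept).
#' @export
select_features_rfe <- function(table, labels = table$labels, target_count,
                                step = 0.05, cv_k = 5, seed = 1) {
  stopifnot(inherits(table, "feature_table"))
  p <- ncol(table$x)
  if (any(target_count > p))
    stop("target_count exceeds available feature count (", p, ")")
  y <- squat_label(labels)
  goal <- min(target_count)
  x <- table$x
  elimination <- character(0)  # worst first
  while (ncol(x) > goal) {
    imp <- svm_feature_importance(x, y)
    ndrop <- min(max(1L, floor(step * ncol(x))), ncol(x) - goal)
    drop <- order(imp)[seq_len(ndrop)]
    elimination <- c(elimination, colnames(x)[drop[order(imp[drop])]])
    x <- x[, -drop, drop = FALSE]
  }
  # surviving features ranked by final importance, best first
  final_rank <- if (ncol(x) > 1) {
    imp <- svm_feature_importance(x, y)
    colnames(x)[order(imp, decreasing = TRUE)]
  } else colnames(x)
  ranking <- c(final_rank, rev(elimination))
  sweep_df <- NULL
  best <- goal
  if (length(target_count) > 1) {
    set.seed(seed)
    folds <- stratified_folds(y, cv_k)
    score <- vapply(sort(target_count), function(k) {
      feats <- ranking[seq_len(k)]
      acc <- vapply(seq_len(cv_k), function(f) {
        tr <- folds != f
        fit <- e1071::svm(table$x[tr, feats, drop = FALSE], y[tr],
                          kernel = "linear", cost = 1, scale = FALSE)
        mean(predict(fit, table$x[!tr, feats, drop = FALSE]) == y[!tr])
      }, 0)
      mean(acc)
    }, 0)
    sweep_df <- data.frame(target_count = sort(target_count), cv_accuracy = score)
    best <- sweep_df$target_count[which.max(sweep_df$cv_accuracy)]
  }
  structure(list(features = ranking[seq_len(best)], target_count = best,
                 ranking = ranking, sweep = sweep_df),
            class = "selected_features")
}

#' @export
print.selected_features <- function(x, ...) {
  cat(sprintf("<selected_features> %d of %d features\n",
              length(x$features), length(x$ranking)))
  invisible(x)
}

#' Optional repetition outlier screen
#'
#' Rejects rows whose raw feature vector had more than `max_nonfinite`
#' non-finite entries before zero-filling, or whose driving segment lasted
#' outside the plausible duration window. Disabled by default in the
#' pipeline; exposed for datasets with corrupted repetitions.
#'
#' @param segments list of `rep_segment` objects.
#' @param max_nonfinite maximum tolerated fraction of non-finite raw
#'   features.
#' @param duration_range plausible repetition duration, s.
#' @return logical keep-mask over segments.
#' @export
screen_segments <- function(segments, max_nonfinite = 0.01,
                            duration_range = c(1, 10)) {
  vapply(segments, function(s) {
    dur <- s$t_end - s$t_start
    if (dur < duration_range[1] || dur > duration_range[2]) return(FALSE)
    row <- extract_features(s)
    attr(row, "n_nonfinite") / length(row) <= max_nonfinite
  }, TRUE)
}
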