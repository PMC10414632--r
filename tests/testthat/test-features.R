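test_that("inventory declares 2250 features, 375 per sensor, matching the manifest", {
  inv <- feature_inventory()
  expect_identical(nrow(inv), 2250L)
  per <- table(inv$sensor)
  expect_true(all(per == 375))
  expect_false(anyDuplicated(inv$name) > 0)

  shipped <- utils::read.delim(system.file("extdata",
                                           "feature_manifest_per_sensor.tsv",
                                           package = "squatmon"))
  one <- inv[inv$sensor == "shank_L", ]
  expect_identical(one$signal, shipped$signal)
  expect_identical(one$statistic, shipped$statistic)
  expect_identical(one$axis, shipped$axis)
})

test_that("a six-sensor repetition yields a full finite feature row", {
  sim <- simulate_squat_trial(squat_config(n_reps = 3, seed = 8))
  zt <- simulate_microgravity(sim$trial)
  segs <- segment_repetitions(zt)
  row <- extract_features(segs[[1]])
  expect_length(row, 2250)
  expect_true(all(is.finite(row)))
})

test_that("constant signals produce their textbook statistics", {
  n <- 300
  seg <- make_segment(n, acc = list(sacrum = cbind(rep(3, n), 0, 0)))
  row <- extract_features(seg)
  expect_equal(row[["sacrum_tAcc0g_mean_X"]], 3)
  expect_equal(row[["sacrum_tAcc0g_sd_X"]], 0)
  expect_equal(row[["sacrum_tAcc0g_mad_X"]], 0)
  expect_equal(row[["sacrum_tAcc0g_max_X"]], 3)
  expect_equal(row[["sacrum_tAcc0g_min_X"]], 3)
  expect_equal(row[["sacrum_tAcc0g_energy_X"]], 9)
  expect_equal(row[["sacrum_tAcc0g_iqr_X"]], 0)
  # jerk of a constant is identically zero
  expect_equal(row[["sacrum_tAccJerk_max_X"]], 0)
  expect_equal(row[["sacrum_tAccJerk_min_X"]], 0)
})

test_that("derived signals obey closed forms: jerk of a sine, vector magnitude", {
  n <- 1000; rate <- 100
  t <- seq_len(n) / rate
  f0 <- 0.5
  acc <- cbind(sin(2 * pi * f0 * t), 0, 0)
  seg <- make_segment(n, rate = rate, acc = list(sacrum = acc,
                                                 sternum = cbind(rep(3, n), 4, 0)))
  sigs <- derive_signals(seg)
  jerk_amp <- max(abs(sigs$sacrum$time$tAccJerk[, 1]))
  expect_lt(abs(jerk_amp - 2 * pi * f0) / (2 * pi * f0), 0.02)
  expect_equal(unique(round(sigs$sternum$time$tAcc0gMag, 12)), 5)
})

test_that("single-tone spectra give the right meanFreq and maxInds bin", {
  n <- 1000; rate <- 100; f0 <- 0.5
  t <- seq_len(n) / rate
  seg <- make_segment(n, rate = rate,
                      acc = list(sacrum = cbind(sin(2 * pi * f0 * t), 0, 0)))
  row <- extract_features(seg)
  expect_lt(abs(row[["sacrum_fAcc0g_meanFreq_X"]] - f0), 0.1)
  # one-sided spectrum bins are (k-1) * rate/n Hz; 0.5 Hz sits at bin 6
  expect_identical(unname(row[["sacrum_fAcc0g_maxInds_X"]]), 6)
})

test_that("feature extraction is permutation-equivariant over sensors", {
  n <- 200
  set.seed(33)
  a <- matrix(rnorm(n * 3), n, 3); b <- matrix(rnorm(n * 3), n, 3)
  seg1 <- make_segment(n, acc = list(shank_L = a, thigh_R = b))
  seg2 <- make_segment(n, acc = list(shank_L = b, thigh_R = a))
  r1 <- extract_features(seg1); r2 <- extract_features(seg2)
  pick <- function(r, sid) unname(r[startsWith(names(r), paste0(sid, "_"))])
  expect_identical(pick(r1, "shank_L"), pick(r2, "thigh_R"))
  expect_identical(pick(r1, "thigh_R"), pick(r2, "shank_L"))
})

test_that("robust scaler matches hand computation and does not leak test rows", {
  x <- cbind(v = c(1, 2, 3, 4, 5, 100), w = rep(7, 6))
  tab <- make_table(x, c("CO", "CO", "KOT", "KOT", "VK", "VK"), scaled = FALSE)
  sc <- fit_scaler(tab, train_rows = 1:5)
  # train rows 1..5: median 3, IQR 2 -> value 5 scales to 1
  out <- apply_scaler(tab, sc)
  expect_equal(unname(out$x[5, "v"]), 1)
  expect_equal(unname(out$x[1:5, "w"]), rep(0, 5))  # constant column -> 0
  sc_all <- fit_scaler(tab, train_rows = 1:6)
  expect_false(isTRUE(all.equal(sc$center[["v"]], sc_all$center[["v"]])))

  back <- apply_scaler(out, sc, invert = TRUE)
  expect_lt(max(abs(back$x - x)), 1e-12)
})

test_that("RFE recovers planted informative features and honours bounds", {
  set.seed(77)
  n <- 120; p <- 100
  y <- rep(squat_classes(), each = n / 6)
  centers <- matrix(rnorm(6 * 10, sd = 3), 6, 10)
  x <- matrix(rnorm(n * p), n, p)
  x[, 1:10] <- centers[rep(1:6, each = n / 6), ] + x[, 1:10] * 0.5
  colnames(x) <- c(paste0("inf", 1:10), paste0("noise", 1:90))
  tab <- make_table(x, y)
  sel <- select_features_rfe(tab, target_count = 10, seed = 3)
  expect_gte(sum(startsWith(sel$features, "inf")), 8)

  all_sel <- select_features_rfe(tab, target_count = p, seed = 3)
  expect_setequal(all_sel$features, colnames(x))
  expect_error(select_features_rfe(tab, target_count = p + 1), "exceeds")
})

test_that("the optional outlier screen rejects implausible repetitions", {
  sim <- simulate_squat_trial(squat_config(n_reps = 3, seed = 8))
  segs <- segment_repetitions(simulate_microgravity(sim$trial))
  keep <- screen_segments(segs)
  expect_true(all(keep))
  long <- segs[[1]]; long$t_end <- long$t_start + 30
  expect_false(screen_segments(list(long)))
})
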