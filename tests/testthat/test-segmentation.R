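test_that("extrema detection finds analytic sine extrema and ignores flat signals", {
  rate <- 100
  t <- seq(0, 30, by = 1 / rate)
  expect_identical(nrow(detect_extrema(rep(1, 500), rate = rate)), 0L)

  x <- sin(2 * pi * t / 3)
  ext <- detect_extrema(x, rate = rate)
  peaks <- ext$index[ext$kind == "peak"]
  valleys <- ext$index[ext$kind == "valley"]
  expect_length(peaks, 10)
  expect_length(valleys, 10)
  expect_lte(max(abs(peaks - (0.75 + 3 * (0:9)) * rate - 1)), 1)
  expect_lte(max(abs(valleys - (2.25 + 3 * (0:9)) * rate - 1)), 1)

  set.seed(9)
  xn <- x + rnorm(length(x), 0, 0.05)
  extn <- detect_extrema(xn, rate = rate)
  expect_identical(table(extn$kind), table(ext$kind))
})

test_that("segment count survives 5% driver noise across seeds", {
  for (seed in c(3, 17, 29)) {
    cfg <- squat_config(n_reps = 8, seed = seed,
                        noise_sd = c(acc = 0.04, gyro = 0.005, mag = 0.005))
    zt <- simulate_microgravity(simulate_squat_trial(cfg)$trial)
    expect_length(segment_repetitions(zt), 8)
  }
})

test_that("simulator repetitions are recovered with tight boundaries", {
  cfg <- squat_config(n_reps = 10, seed = 4,
                      noise_sd = c(acc = 0, gyro = 0, mag = 0),
                      gyro_bias_sd = 0)
  sim <- simulate_squat_trial(cfg)
  zt <- simulate_microgravity(sim$trial)
  segs <- segment_repetitions(zt)
  expect_length(segs, 10)
  si <- segments_index(segs)
  tb <- sim$truth$boundaries
  expect_lt(max(abs(si$start_s - tb$start_s)), 0.15)
  expect_lt(max(abs(si$end_s - tb$end_s)), 0.15)
})

test_that("segments are disjoint, ordered, and hold one valley-peak pair each", {
  sim <- simulate_squat_trial(squat_config(n_reps = 6, seed = 12))
  zt <- simulate_microgravity(sim$trial)
  segs <- segment_repetitions(zt)
  si <- segments_index(segs)
  expect_true(all(diff(si$start_idx) > 0))
  expect_true(all(si$end_idx[-nrow(si)] <= si$start_idx[-1] + 1))
  for (s in segs) {
    expect_gte(s$driver_extrema[["valley"]], s$start_idx)
    expect_lte(s$driver_extrema[["peak"]], s$end_idx)
    expect_lt(s$driver_extrema[["valley"]], s$driver_extrema[["peak"]])
    expect_identical(nrow(s$window$sacrum$acc0g), s$end_idx - s$start_idx)
  }
})

test_that("a motionless trial yields no repetitions, with a warning", {
  zt <- simulate_microgravity(static_trial(dur = 12))
  expect_warning(segs <- segment_repetitions(zt), "no repetition")
  expect_length(segs, 0)
})
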