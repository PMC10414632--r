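test_that("quaternion rotation round trip is exact", {
  set.seed(1)
  q <- random_unit_quat(100)
  v <- matrix(rnorm(300), 100, 3)
  back <- quat_rotate_inv(q, quat_rotate(q, v))
  expect_lt(max(abs(back - v)), 1e-12)
  expect_lt(max(abs(rowSums(quat_multiply(q, quat_conjugate(q))[, 2:4]^2))),
            1e-24)
})

test_that("gravity removal is exact for any exact static orientation", {
  set.seed(2)
  q <- random_unit_quat(100)
  n <- nrow(q)
  # stationary sensor at attitude q measures the rotated specific force
  acc <- quat_rotate_inv(q, matrix(c(0, 0, G_MPS2), n, 3, byrow = TRUE))
  a0 <- remove_gravity(acc, q)
  expect_lt(max(abs(a0)), 1e-9)
})

test_that("zero-phase Butterworth keeps DC and the passband, kills the stopband", {
  rate <- 100
  t <- seq(0, 10, by = 1 / rate)
  s <- static_stream(dur = 8)
  out <- lowpass(s, 20, 6)
  expect_lt(max(abs(out$acc - s$acc)), 1e-9)  # constant channels unchanged

  x <- sin(2 * pi * 1 * t) + sin(2 * pi * 30 * t)
  y <- lowpass(x, 20, 6, rate = rate)
  amp <- function(v, f) {
    b <- cbind(sin(2 * pi * f * t), cos(2 * pi * f * t))
    sqrt(sum(coef(lm(v ~ b))[-1]^2))
  }
  expect_lt(abs(amp(y, 1) - 1), 0.01)          # passband within 1%
  expect_lt(amp(y, 30), 10^(-40 / 20))         # > 40 dB attenuation
  expect_error(lowpass(x, 60, 6, rate = rate), "Nyquist")
})

test_that("Mahony track holds a stationary attitude and recovers a 90 degree roll", {
  s <- static_stream()
  trk <- estimate_orientation(s)
  expect_lt(max(quat_angle(trk$q, c(1, 0, 0, 0))), 1e-6)
  expect_true(any(trk$converged))

  # sensor rolled 90 degrees about x: gravity appears along -y
  n <- 800
  s2 <- imu_stream("sacrum", seq(0, by = 0.01, length.out = n),
                   acc = cbind(0, -G_MPS2, numeric(n)),
                   gyro = matrix(0, n, 3), rate = 100)
  trk2 <- estimate_orientation(s2, mahony_gains(mode = "6-axis"),
                               init = c(1, 0, 0, 0))
  gdir <- quat_rotate_inv(trk2$q[500, ], c(0, 0, 1))
  err_deg <- acos(max(-1, min(1, sum(gdir * c(0, -1, 0))))) * 180 / pi
  expect_lt(err_deg, 0.5)
})

test_that("Mahony tracks the simulator ground-truth orientation", {
  sim <- simulate_squat_trial(squat_config(n_reps = 5, seed = 31))
  zt <- simulate_microgravity(sim$trial)
  for (sid in c("sacrum", "shank_L", "sternum")) {
    est <- zt$sensors[[sid]]$track$q
    err <- quat_angle(est, sim$truth$sensors[[sid]]$q)
    post <- seq(501, length(err))
    expect_lt(mean(err[post]) * 180 / pi, 2)
  }
})

test_that("remove_gravity demands aligned inputs and zeroes a stationary stream", {
  s <- static_stream()
  trk <- estimate_orientation(s)
  a0 <- remove_gravity(s, trk)
  expect_lt(max(abs(a0[200:nrow(a0), ])), 1e-6)
  expect_error(remove_gravity(s, trk$q[1:10, ]), "lengths differ")
})

test_that("simulate_microgravity yields 36 quiet channels on a static trial", {
  zt <- simulate_microgravity(static_trial(dur = 8))
  expect_length(zt$sensors, 6)
  for (sid in sensor_sites()) {
    expect_identical(ncol(zt$sensors[[sid]]$acc0g), 3L)
    expect_identical(ncol(zt$sensors[[sid]]$gyro), 3L)
    post <- seq(501, length(zt$t))
    rms <- sqrt(mean(zt$sensors[[sid]]$acc0g[post, ]^2))
    expect_lt(rms, 0.02 * G_MPS2)
  }
  expect_identical(length(zt$t), length(static_trial(dur = 8)$streams[[1]]$t))
})

test_that("9-axis request without magnetometer falls back with a warning", {
  trial <- static_trial(dur = 8, mag = FALSE)
  expect_warning(zt <- simulate_microgravity(trial, mahony_gains(mode = "9-axis")),
                 "6-axis")
  expect_length(zt$sensors, 6)
})

test_that("6-axis and 9-axis agree on gravity removal in a clean static case", {
  s <- static_stream(q = quat_from_axis_angle(c(1, 0, 0), 0.4))
  a6 <- remove_gravity(s, estimate_orientation(s, mahony_gains(mode = "6-axis")))
  a9 <- remove_gravity(s, estimate_orientation(s, mahony_gains(mode = "9-axis")))
  post <- 300:nrow(a6)
  expect_lt(max(abs(a6[post, ] - a9[post, ])), 1e-6)
})
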