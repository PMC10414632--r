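test_that("error classes deform the correct pattern as configured", {
  co <- joint_trajectories(squat_config(label = "CO"))
  for (lab in c("KOT", "VK", "RB", "RH", "SH")) {
    zero <- joint_trajectories(squat_config(label = lab, severity = 0))
    for (ch in c("ankle", "knee", "trunk", "knee_frontal", "heel_z"))
      expect_equal(zero[[ch]], co[[ch]], info = paste(lab, ch))
  }
  sh <- joint_trajectories(squat_config(label = "SH", severity = 1))
  expect_equal(max(sh$knee), 0.4 * max(co$knee), tolerance = 1e-9)
  # exactly n_reps knee-flexion cycles
  expect_identical(sum(diff(sign(diff(co$knee - max(co$knee) / 2))) < 0), 10L)
})

test_that("severity increases the deviation from the correct pattern monotonically", {
  co <- joint_trajectories(squat_config(label = "CO"))
  probe <- list(KOT = "ankle", VK = "knee_frontal", RB = "trunk",
                RH = "heel_z", SH = "knee")
  for (lab in names(probe)) {
    dev <- vapply(c(0.25, 0.5, 0.75, 1), function(s) {
      tr <- joint_trajectories(squat_config(label = lab, severity = s))
      mean(abs(tr[[probe[[lab]]]] - co[[probe[[lab]]]]))
    }, 0)
    expect_true(all(diff(dev) >= 0), info = lab)
  }
})

test_that("forward kinematics is stationary in the standing pose and mirror-symmetric", {
  cfg <- squat_config(n_reps = 1)
  ang <- joint_trajectories(cfg)
  still <- lapply(ang, function(v) if (is.numeric(v)) v * 0 else v)
  still$t <- ang$t
  kin <- forward_kinematics(still, cfg)
  for (site in sensor_sites()) {
    expect_lt(max(abs(diff(kin[[site]]$pos))), 1e-12)
    expect_lt(max(quat_angle(kin[[site]]$q, c(1, 0, 0, 0))), 1e-12)
  }
  kin2 <- forward_kinematics(joint_trajectories(squat_config(label = "VK")), cfg)
  mirror <- kin2$shank_L$pos * matrix(c(1, -1, 1), nrow(kin2$shank_L$pos), 3,
                                      byrow = TRUE)
  expect_lt(max(abs(kin2$shank_R$pos - mirror)), 1e-12)
})

test_that("a single rotating link matches the closed-form pendulum acceleration", {
  cfg <- squat_config(n_reps = 1, rate = 100)
  rate <- 100
  t <- seq(0, 10, by = 1 / rate)
  A <- 0.3; w <- 2 * pi / 3
  theta <- A * sin(w * t)
  ang <- list(t = t, ankle = theta, knee = numeric(length(t)),
              hip = numeric(length(t)), trunk = numeric(length(t)),
              knee_frontal = numeric(length(t)), heel_z = numeric(length(t)))
  kin <- forward_kinematics(ang, cfg)
  r <- 0.5 * cfg$shank
  td <- A * w * cos(w * t)       # theta dot
  tdd <- -A * w^2 * sin(w * t)   # theta double dot
  # mid-link acceleration r*(thetadd tangential - thetad^2 radial), sagittal
  ax <- r * (tdd * cos(theta) - td^2 * sin(theta))
  az <- r * (-tdd * sin(theta) - td^2 * cos(theta))
  dt <- 1 / rate
  num <- apply(kin$shank_L$pos, 2, function(p)
    (p[3:length(p)] - 2 * p[2:(length(p) - 1)] + p[1:(length(p) - 2)]) / dt^2)
  interior <- 2:(length(t) - 1)
  scale <- max(abs(c(ax, az)))
  expect_lt(max(abs(num[, 1] - ax[interior])) / scale, 1e-3)
  expect_lt(max(abs(num[, 3] - az[interior])) / scale, 1e-3)
})

test_that("rendered IMU signals honour statics, determinism and periodicity", {
  cfg0 <- squat_config(n_reps = 1, noise_sd = c(acc = 0, gyro = 0, mag = 0),
                       gyro_bias_sd = 0, depth = 1e-9, trunk_lean = 0,
                       ankle_df = 0, seed = 2)
  sim0 <- simulate_squat_trial(cfg0)
  for (sid in sensor_sites()) {
    nrm <- sqrt(rowSums(sim0$trial$streams[[sid]]$acc^2))
    expect_lt(max(abs(nrm - G_MPS2)), 1e-6)
  }

  cfg <- squat_config(n_reps = 4, seed = 77)
  s1 <- simulate_squat_trial(cfg); s2 <- simulate_squat_trial(cfg)
  expect_identical(serialize(s1, NULL), serialize(s2, NULL))

  # noise-free, jitter-free trials are exactly periodic cycle to cycle
  cfgp <- squat_config(n_reps = 3, noise_sd = c(acc = 0, gyro = 0, mag = 0),
                       gyro_bias_sd = 0)
  simp <- simulate_squat_trial(cfgp)
  acc <- simp$trial$streams$sacrum$acc
  period <- cfgp$rep_period * cfgp$rate
  i0 <- cfgp$lead_in_s * cfgp$rate + 50
  win <- seq(i0, i0 + period - 100)
  expect_lt(max(abs(acc[win, ] - acc[win + period, ])), 1e-9)
})

test_that("vertical velocity integrates to zero over each repetition", {
  cfg <- squat_config(n_reps = 3, noise_sd = c(acc = 0, gyro = 0, mag = 0),
                      gyro_bias_sd = 0)
  kin <- forward_kinematics(joint_trajectories(cfg), cfg)
  z <- kin$sacrum$pos[, 3]
  per <- cfg$rep_period * cfg$rate
  i0 <- cfg$lead_in_s * cfg$rate + 1
  for (r in 0:2) {
    dz <- z[i0 + (r + 1) * per] - z[i0 + r * per]  # integral of velocity
    expect_lt(abs(dz), 1e-9)
  }
})

test_that("the full preprocessing chain recovers the analytic 0g acceleration", {
  cfg <- squat_config(n_reps = 5, noise_sd = c(acc = 0, gyro = 0, mag = 0),
                      gyro_bias_sd = 0, seed = 3)
  sim <- simulate_squat_trial(cfg)
  zt <- simulate_microgravity(sim$trial)
  post <- seq(501, length(zt$t))
  for (sid in sensor_sites()) {
    d <- zt$sensors[[sid]]$acc0g[post, ] - sim$truth$sensors[[sid]]$acc0g[post, ]
    expect_lt(sqrt(mean(d^2)), 0.05 * G_MPS2)
  }
})

test_that("ground-truth boundaries count the configured repetitions", {
  for (nr in c(5, 12)) {
    sim <- simulate_squat_trial(squat_config(n_reps = nr, seed = nr))
    tb <- sim$truth$boundaries
    expect_identical(nrow(tb), as.integer(nr))
    expect_true(all(diff(tb$start_s) > 0))
    expect_true(all(tb$end_s > tb$start_s))
  }
})

test_that("the benchmark collection counts out subjects, classes and reps", {
  bm <- small_benchmark()
  expect_identical(nrow(bm$manifest), 12L)  # 6 classes x 2 subjects
  expect_identical(length(bm$trials), 12L)
  expect_true(all(table(bm$manifest$label) == 2))
  total <- sum(vapply(bm$trials, function(tr) nrow(tr$truth$boundaries), 0L))
  expect_identical(total, 60L)  # 12 trials x 5 ground-truth repetitions
  # manifest labels match the trials
  for (i in seq_len(nrow(bm$manifest)))
    expect_identical(bm$trials[[bm$manifest$trial_id[i]]]$truth$label,
                     bm$manifest$label[i])
})

test_that("a serialized benchmark trial round-trips through trial I/O", {
  sim <- small_benchmark()$trials[[1]]
  path <- withr::local_tempfile(fileext = ".csv")
  write_trial(sim$trial, path)
  back <- read_trial(path)
  expect_lt(max(abs(back$streams$sacrum$acc - sim$trial$streams$sacrum$acc)),
            1e-6)
  expect_identical(as.character(back$label), sim$truth$label)
})
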