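# Kinematic squat simulator: an articulated sagittal chain (foot-fixed
# ankle, shank, thigh, trunk) with one frontal-plane degree of freedom for
# valgus knees. It renders labelled six-sensor 9-axis trials with
# ground-truth orientations, analytic gravity-free accelerations and
# repetition boundaries - the test substrate for the whole pipeline.

#' Squat simulation configuration
#'
#' Defaults describe a parallel squat at a 3 s cadence: peak knee flexion
#' 1.4 rad, peak trunk pitch 0.35 rad, peak ankle dorsiflexion 0.35 rad,
#' a 6 s stationary lead-in (covering the orientation warm-up) and 2 s
#' tail. Execution-error classes perturb the base pattern with magnitude
#' `severity` in [0, 1]:
#' * RB - extra trunk pitch (severity x 0.5 rad),
#' * KOT - extra ankle dorsiflexion / shank pitch (severity x 0.3 rad),
#' * VK - frontal-plane knee oscillation (severity x 0.25 rad),
#' * RH - shank pitch offset (severity x 0.2 rad) plus a heel rise at the
#'   cycle bottom (severity x 0.02 m),
#' * SH - depth multiplied by (1 - 0.6 x severity).
#'
#' @param label squat class (see [squat_classes()]).
#' @param n_reps number of repetitions (>= 1).
#' @param rep_period repetition period, s.
#' @param depth peak knee flexion, rad, in (0, pi/2].
#' @param trunk_lean peak trunk pitch, rad.
#' @param ankle_df peak ankle dorsiflexion, rad.
#' @param severity error-mode magnitude in [0, 1] (ignored for CO).
#' @param jitter fractional SD applied per trial to depth, period, trunk
#'   lean and ankle dorsiflexion (subject variability).
#' @param noise_sd named vector: per-channel white-noise SDs - `acc`
#'   (m/s^2), `gyro` (rad/s), `mag` (unitless).
#' @param gyro_bias_sd SD of the constant per-trial gyroscope bias, rad/s.
#' @param rate sample rate, Hz.
#' @param seed RNG seed (NULL leaves the RNG state alone).
#' @param lead_in_s,tail_s stationary standing before/after the reps, s.
#' @param shank,thigh,trunk segment lengths, m.
#' @param hip_width lateral ankle-to-ankle distance, m.
#' @param mag_dip magnetic inclination, rad (field along +y North, dipping
#'   down).
#' @return object of class `squat_config`.
#' @export
squat_config <- function(label = "CO", n_reps = 10, rep_period = 3,
                         depth = 1.4, trunk_lean = 0.35, ankle_df = 0.35,
                         severity = 1.0, jitter = 0,
                         noise_sd = c(acc = 0.1, gyro = 0.02, mag = 0.005),
                         gyro_bias_sd = 0.02, rate = 100, seed = NULL,
                         lead_in_s = 6, tail_s = 2,
                         shank = 0.43, thigh = 0.42, trunk = 0.50,
                         hip_width = 0.30, mag_dip = pi / 3) {
  stopifnot(n_reps >= 1, rep_period > 0, depth > 0, depth <= pi / 2,
            severity >= 0, severity <= 1, rate > 0, jitter >= 0)
  label <- as.character(squat_label(label))
  ns <- c(acc = 0.1, gyro = 0.02, mag = 0.005)
  ns[names(noise_sd)] <- noise_sd
  structure(list(label = label, n_reps = as.integer(n_reps),
                 rep_period = rep_period, depth = depth,
                 trunk_lean = trunk_lean, ankle_df = ankle_df,
                 severity = severity, jitter = jitter, noise_sd = ns,
                 gyro_bias_sd = gyro_bias_sd, rate = rate, seed = seed,
                 lead_in_s = lead_in_s, tail_s = tail_s, shank = shank,
                 thigh = thigh, trunk = trunk, hip_width = hip_width,
                 mag_dip = mag_dip),
            class = "squat_config")
}

#' Joint-angle trajectories for a squat trial
#'
#' Raised-cosine cycles of the sagittal joint angles, with the configured
#' error-class perturbation applied (at severity 0 every class reduces to
#' the correct pattern).
#'
#' @param config a [squat_config()].
#' @return list with `t` and per-sample series `ankle` (shank pitch, rad),
#'   `knee` (knee flexion, rad), `hip` (hip flexion, rad), `trunk` (trunk
#'   pitch, rad), `knee_frontal` (frontal-plane angle, rad) and `heel_z`
#'   (heel rise, m).
#' @export
joint_trajectories <- function(config) {
  stopifnot(inherits(config, "squat_config"))
  dur <- config$lead_in_s + config$n_reps * config$rep_period + config$tail_s
  t <- seq(0, dur, by = 1 / config$rate)
  tm <- t - config$lead_in_s
  active <- tm >= 0 & tm <= config$n_reps * config$rep_period
  cyc <- numeric(length(t))
  cyc[active] <- (1 - cos(2 * pi * tm[active] / config$rep_period)) / 2
  s <- if (config$label == "CO") 0 else config$severity
  depth <- config$depth * if (config$label == "SH") 1 - 0.6 * s else 1
  ankle <- config$ankle_df * cyc
  if (config$label == "KOT") ankle <- ankle + s * 0.3 * cyc
  if (config$label == "RH") ankle <- ankle + s * 0.2 * cyc
  trunk <- config$trunk_lean * cyc
  if (config$label == "RB") trunk <- trunk + s * 0.5 * cyc
  knee_frontal <- if (config$label == "VK") s * 0.25 * cyc else numeric(length(t))
  heel_z <- if (config$label == "RH") s * 0.02 * cyc else numeric(length(t))
  knee <- depth * cyc
  thigh_pitch <- ankle - knee
  list(t = t, ankle = ankle, knee = knee, hip = trunk - thigh_pitch,
       trunk = trunk, knee_frontal = knee_frontal, heel_z = heel_z)
}

quat_pitch <- function(phi) cbind(cos(phi / 2), 0, sin(phi / 2), 0)
quat_roll <- function(gam) cbind(cos(gam / 2), sin(gam / 2), 0, 0)

# direction of a segment with pitch phi (about y) then roll gam (about x)
seg_dir <- function(phi, gam) {
  cbind(sin(phi), -sin(gam) * cos(phi), cos(gam) * cos(phi))
}

#' Forward kinematics of the sensor sites
#'
#' Places the six sensors on the articulated chain and returns their
#' positions and orientations over time. The ankle is the fixed origin
#' (plus any heel rise); knees and hips follow the shank/thigh pitch
#' (with the frontal-plane valgus rotation mirrored between legs), and the
#' sacrum/sternum ride on the trunk above the mid-hip point.
#'
#' @param angles a [joint_trajectories()] result (or any compatible list).
#' @param config a [squat_config()] (segment lengths are read from it).
#' @return named list (one entry per sensor site) of lists with `pos`
#'   (n x 3 m, Earth frame) and `q` (n x 4 unit quaternions,
#'   sensor -> Earth).
#' @export
forward_kinematics <- function(angles, config) {
  stopifnot(config$shank > 0, config$thigh > 0, config$trunk > 0)
  n <- length(angles$t)
  phi_sh <- angles$ankle
  phi_th <- angles$ankle - angles$knee
  phi_tr <- angles$trunk
  beta <- angles$knee_frontal
  w2 <- config$hip_width / 2
  out <- list()
  for (side in c("L", "R")) {
    gam <- if (side == "L") beta else -beta
    yoff <- if (side == "L") w2 else -w2
    ankle_pos <- cbind(0, yoff, angles$heel_z)
    d_sh <- seg_dir(phi_sh, gam)
    d_th <- seg_dir(phi_th, gam)
    knee_pos <- ankle_pos + config$shank * d_sh
    q_sh <- quat_multiply(quat_roll(gam), quat_pitch(phi_sh))
    q_th <- quat_multiply(quat_roll(gam), quat_pitch(phi_th))
    out[[paste0("shank_", side)]] <-
      list(pos = ankle_pos + 0.5 * config$shank * d_sh, q = q_sh)
    out[[paste0("thigh_", side)]] <-
      list(pos = knee_pos + 0.5 * config$thigh * d_th, q = q_th)
    out[[paste0("hip_", side)]] <- list(pos = knee_pos + config$thigh * d_th)
  }
  hip_mid <- (out$hip_L$pos + out$hip_R$pos) / 2
  d_tr <- seg_dir(phi_tr, numeric(n))
  q_tr <- quat_pitch(phi_tr)
  out$sacrum <- list(pos = hip_mid + 0.12 * config$trunk * d_tr, q = q_tr)
  out$sternum <- list(pos = hip_mid + 0.80 * config$trunk * d_tr, q = q_tr)
  out[c("hip_L", "hip_R")] <- NULL
  c(out[c("shank_L", "shank_R", "thigh_L", "thigh_R", "sacrum", "sternum")],
    list())
}

# second time derivative by central differences; end samples copy their
# nearest interior value (trials start and end stationary)
second_deriv <- function(m, dt) {
  n <- nrow(m)
  a <- matrix(0, n, ncol(m))
  if (n >= 3) {
    a[2:(n - 1), ] <- (m[3:n, , drop = FALSE] - 2 * m[2:(n - 1), , drop = FALSE] +
                         m[1:(n - 2), , drop = FALSE]) / dt^2
    a[1, ] <- a[2, ]; a[n, ] <- a[n - 1, ]
  }
  a
}

#' Render IMU signals from simulated kinematics
#'
#' Produces the accelerometer (specific force: kinematic acceleration minus
#' gravity, in the sensor frame - a stationary level sensor reads
#' (0, 0, +g)), gyroscope (sensor-frame angular velocity from the
#' quaternion track) and magnetometer (fixed Earth field direction in the
#' sensor frame), with white noise and a constant per-trial gyro bias drawn
#' under the configured seed. The ground truth carries the exact
#' orientation tracks, the analytic gravity-free sensor-frame
#' accelerations, and the repetition boundaries obtained by applying the
#' documented boundary rule (2 Hz smoothing + zero crossings around each
#' valley-peak pair) to the analytic sacrum vertical acceleration - no
#' rendered IMU data is involved in the truth.
#'
#' @param kin a [forward_kinematics()] result.
#' @param config a [squat_config()].
#' @param t time grid matching `kin`.
#' @return list with `trial` (an [imu_trial()]) and `truth` (class
#'   `squat_truth`): per-sensor `q` and `acc0g`, `boundaries` data.frame
#'   (`start_s`, `end_s`), `label`, `config`.
#' @export
render_imu <- function(kin, config, t) {
  g_e <- c(0, 0, G_MPS2)
  m_e <- c(0, cos(config$mag_dip), -sin(config$mag_dip))
  dt <- 1 / config$rate
  streams <- list(); truth_sensors <- list()
  for (site in sensor_sites()) {
    k <- kin[[site]]
    a_kin <- second_deriv(k$pos, dt)
    f_e <- a_kin + matrix(g_e, nrow(a_kin), 3, byrow = TRUE)
    acc <- quat_rotate_inv(k$q, f_e)
    gyro <- quat_track_to_gyro(k$q, dt)
    mag <- quat_rotate_inv(k$q, matrix(m_e, nrow(a_kin), 3, byrow = TRUE))
    bias <- rnorm(3, 0, config$gyro_bias_sd)
    n <- nrow(acc)
    acc <- acc + matrix(rnorm(3 * n, 0, config$noise_sd[["acc"]]), n, 3)
    gyro <- gyro + matrix(bias, n, 3, byrow = TRUE) +
      matrix(rnorm(3 * n, 0, config$noise_sd[["gyro"]]), n, 3)
    mag <- mag + matrix(rnorm(3 * n, 0, config$noise_sd[["mag"]]), n, 3)
    streams[[site]] <- imu_stream(site, t, acc, gyro, mag, config$rate)
    truth_sensors[[site]] <- list(q = k$q,
                                  acc0g = quat_rotate_inv(k$q, a_kin))
  }
  sac_az <- second_deriv(kin$sacrum$pos, dt)[, 3]
  drv <- lowpass(sac_az, 2, 6, rate = config$rate)
  cyc <- driver_cycles(drv, segmentation_params(), config$rate)
  boundaries <- if (is.null(cyc)) data.frame(start_s = numeric(0), end_s = numeric(0))
                else data.frame(start_s = t[cyc$start], end_s = t[cyc$end])
  trial <- imu_trial(streams, label = config$label,
                     meta = list(subject = "sim", session = "sim"))
  truth <- structure(list(sensors = truth_sensors, boundaries = boundaries,
                          label = config$label, config = config),
                     class = "squat_truth")
  list(trial = trial, truth = truth)
}

#' Simulate one labelled six-sensor squat trial
#'
#' Seeds the RNG, applies per-trial subject jitter to the kinematic
#' parameters, builds the joint trajectories and forward kinematics, and
#' renders the IMU signals. Identical seeds give bit-identical output.
#'
#' @param config a [squat_config()].
#' @return list with `trial` and `truth` (see [render_imu()]).
#' @export
simulate_squat_trial <- function(config = squat_config()) {
  stopifnot(inherits(config, "squat_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  if (config$jitter > 0) {
    jit <- function(x) x * max(0.5, min(1.5, 1 + rnorm(1, 0, config$jitter)))
    config$depth <- min(pi / 2, jit(config$depth))
    config$rep_period <- jit(config$rep_period)
    config$trunk_lean <- jit(config$trunk_lean)
    config$ankle_df <- jit(config$ankle_df)
  }
  ang <- joint_trajectories(config)
  kin <- forward_kinematics(ang, config)
  render_imu(kin, config, ang$t)
}

#' Generate a labelled multi-subject benchmark collection
#'
#' One trial per subject per class, with per-trial jittered kinematics.
#' This emulates the study design the classifiers are meant for: six
#' technique classes, several subjects, 5-20 repetitions per trial.
#'
#' @param n_subjects subjects per class.
#' @param n_reps repetitions per trial.
#' @param seed base seed; per-trial seeds are derived deterministically.
#' @param jitter subject variability (fractional SD).
#' @param severity error-mode magnitude.
#' @param noise_sd,rate passed to [squat_config()].
#' @return list with `trials` (list of `simulate_squat_trial` results) and
#'   `manifest` (data.frame: trial id, label, subject, seed, n_reps).
#' @export
make_benchmark <- function(n_subjects = 5, n_reps = 10, seed = 20230901,
                           jitter = 0.1, severity = 1.0,
                           noise_sd = c(acc = 0.1, gyro = 0.02, mag = 0.005),
                           rate = 100) {
  classes <- squat_classes()
  trials <- list(); rows <- NULL
  for (subj in seq_len(n_subjects)) {
    for (ci in seq_along(classes)) {
      tseed <- (seed + 1009L * subj + 101L * ci) %% 2147483647L
      cfg <- squat_config(label = classes[ci], n_reps = n_reps,
                          severity = severity, jitter = jitter,
                          noise_sd = noise_sd, rate = rate, seed = tseed)
      id <- sprintf("S%02d_%s", subj, classes[ci])
      trials[[id]] <- simulate_squat_trial(cfg)
      rows <- rbind(rows, data.frame(trial_id = id, label = classes[ci],
                                     subject = subj, seed = tseed,
                                     n_reps = n_reps))
    }
  }
  list(trials = trials, manifest = rows)
}
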