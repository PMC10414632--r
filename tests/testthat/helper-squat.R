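# Shared fixtures, all generated in code. Expensive shared objects are
# memoized per test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, make) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, make(), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

MAG_E <- c(0, cos(pi / 3), -sin(pi / 3))

# stationary stream at a fixed attitude: accelerometer reads the rotated
# specific force, magnetometer the rotated field direction
static_stream <- function(sensor = "sacrum", q = c(1, 0, 0, 0), dur = 8,
                          rate = 100, mag = TRUE) {
  n <- dur * rate
  t <- seq(0, by = 1 / rate, length.out = n)
  acc <- matrix(quat_rotate_inv(q, c(0, 0, G_MPS2)), n, 3, byrow = TRUE)
  m <- if (mag) matrix(quat_rotate_inv(q, MAG_E), n, 3, byrow = TRUE) else NULL
  imu_stream(sensor, t, acc, matrix(0, n, 3), m, rate)
}

static_trial <- function(dur = 8, rate = 100, mag = TRUE) {
  streams <- lapply(sensor_sites(), static_stream, q = c(1, 0, 0, 0),
                    dur = dur, rate = rate, mag = mag)
  names(streams) <- sensor_sites()
  imu_trial(streams, label = "CO")
}

random_unit_quat <- function(n) {
  q <- matrix(rnorm(4 * n), n, 4)
  q / sqrt(rowSums(q^2))
}

# hand-built repetition segment: per-sensor window matrices default to
# zeros; override entries via the acc/gyro arguments (named by sensor)
make_segment <- function(n = 300, rate = 100, acc = list(), gyro = list(),
                         label = "CO") {
  win <- function(over, sid) {
    m <- matrix(0, n, 3)
    if (!is.null(over[[sid]])) m <- over[[sid]]
    m
  }
  sensors <- lapply(sensor_sites(), function(sid)
    list(acc0g = win(acc, sid), gyro = win(gyro, sid)))
  names(sensors) <- sensor_sites()
  structure(list(start_idx = 1L, end_idx = n + 1L, t_start = 0,
                 t_end = n / rate,
                 driver_extrema = c(valley = 1L, peak = n %/% 2L),
                 window = sensors, window_smooth = sensors,
                 rate = rate, label = label),
            class = "rep_segment")
}

make_table <- function(x, labels, scaled = TRUE) {
  colnames(x) <- colnames(x) %||% paste0("f", seq_len(ncol(x)))
  structure(list(x = x, features = colnames(x),
                 labels = squat_label(labels), provenance = NULL,
                 scaled = scaled),
            class = "feature_table")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# six well-separated Gaussian clusters, one per class
separable_table <- function(n_per_class = 60, p = 20, sep = 10, seed = 42) {
  set.seed(seed)
  cls <- squat_classes()
  centers <- matrix(rnorm(6 * p), 6, p) * sep
  x <- do.call(rbind, lapply(1:6, function(k)
    matrix(centers[k, ], n_per_class, p, byrow = TRUE) +
      matrix(rnorm(n_per_class * p), n_per_class, p)))
  make_table(x, rep(cls, each = n_per_class))
}

small_benchmark <- function()
  cached("small_benchmark", function()
    make_benchmark(n_subjects = 2, n_reps = 5, seed = 11))

small_model <- function()
  cached("small_model", function()
    fit_pipeline(small_benchmark()$trials, algo = "RF",
                 target_count = 60, seed = 5))
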