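test_that("the stream transport yields every bundle in order and collects back", {
  sim <- simulate_squat_trial(squat_config(n_reps = 1, seed = 6,
                                           lead_in_s = 0.5, tail_s = 0))
  trial <- sim$trial
  n <- length(trial$streams[[1]]$t)
  st <- stream_trial(trial)
  ts <- numeric(0)
  while (st$has_next()) ts <- c(ts, st$next_bundle()$t)
  expect_length(ts, n)
  expect_true(all(diff(ts) > 0))

  st2 <- stream_trial(trial)
  back <- collect_stream(st2)
  expect_equal(back$streams$sacrum$acc, trial$streams$sacrum$acc)
  expect_identical(as.character(back$label), as.character(trial$label))
})

test_that("the monitor refuses an incomplete model bundle", {
  tab <- separable_table(n_per_class = 12)
  bare <- train(tab, algo = "KNN", seed = 1)  # no scaler/selection attached
  sim <- simulate_squat_trial(squat_config(n_reps = 1, seed = 1))
  expect_error(online_monitor(sim$trial, bare), "bundle incomplete")
})

test_that("online monitoring emits one causal event per repetition", {
  model <- small_model()
  sim <- simulate_squat_trial(squat_config(label = "CO", n_reps = 10,
                                           seed = 55))
  events <- online_monitor(sim$trial, model)
  expect_length(events, 10)
  starts <- vapply(events, `[[`, 0, "t_start")
  ends <- vapply(events, `[[`, 0, "t_end")
  emits <- vapply(events, `[[`, 0, "t_emit")
  expect_true(all(diff(starts) > 0))
  expect_true(all(starts[-1] >= ends[-length(ends)]))  # disjoint spans
  expect_true(all(emits >= ends))                      # causality
  for (e in events) expect_equal(sum(e$probs), 1, tolerance = 1e-9)
})

test_that("online and batch pipelines agree on most repetition labels", {
  model <- small_model()
  labs_on <- character(0); labs_off <- character(0)
  for (lab in c("CO", "RB", "SH")) {
    sim <- simulate_squat_trial(squat_config(label = lab, n_reps = 5,
                                             seed = 70 + nchar(lab)))
    events <- online_monitor(sim$trial, model)
    labs_on <- c(labs_on, vapply(events, `[[`, "", "label"))
    zt <- simulate_microgravity(sim$trial)
    segs <- segment_repetitions(zt)
    ft <- feature_table(segs)
    labs_off <- c(labs_off, vapply(seq_len(nrow(ft$x)), function(r)
      predict_report(model, ft$x[r, ])$label, ""))
  }
  expect_identical(length(labs_on), length(labs_off))
  expect_gte(mean(labs_on == labs_off), 0.8)
})

test_that("an empty stream produces no events", {
  streams <- lapply(sensor_sites(), function(sid)
    imu_stream(sid, numeric(0), matrix(0, 0, 3), matrix(0, 0, 3), rate = 100))
  names(streams) <- sensor_sites()
  empty <- imu_trial(streams)
  expect_length(online_monitor(empty, small_model()), 0)
})
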