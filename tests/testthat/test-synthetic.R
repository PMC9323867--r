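# small, fast simulation settings used throughout this file
fast <- list(duration_s = 3600, fs = 10, n_channels = 2)

test_that("identical protocol and seed give bit-identical recordings", {
  proto <- preset_healthy(duration_s = fast$duration_s, fs = fast$fs,
                          n_channels = fast$n_channels)
  s1 <- simulate_recording(proto, seed = 99)
  s2 <- simulate_recording(proto, seed = 99)
  expect_identical(s1$channels$values, s2$channels$values)
  expect_identical(s1$truth$states, s2$truth$states)
  s3 <- simulate_recording(proto, seed = 100)
  expect_false(identical(s1$channels$values, s3$channels$values))
})

test_that("protocol validation lists every violation", {
  err <- tryCatch(
    synthetic_protocol(duration_s = 10, fs = 0.4, breathing_freq_hz = 0.25,
                       movement_interval_s = -5),
    error = function(e) conditionMessage(e))
  expect_match(err, "duration_s")
  expect_match(err, "twice the breathing frequency")
  expect_match(err, "movement_interval_s")
  expect_error(preset_insomnia(duration_s = 3600, fs = 10,
                               absence = list(c(3000, 5000))),
               "within the recording")
})

test_that("an empty bed with no breathing stays far below the absence level", {
  proto <- synthetic_protocol(duration_s = 1200, fs = 10, n_channels = 2,
                              breathing_amp = 0,
                              absence = list(c(0, 1200)))
  sim <- simulate_recording(proto, seed = 1)
  env <- sliding_std_envelope(sim$channels)
  # normalize against a reference movement-level segment: power relative to
  # a saturation-scale burst stays below 1% everywhere
  rel_power <- (env$values / 1)^2
  expect_true(all(rel_power < 0.01))
  expect_true(all(sim$truth$states == "ABS"))
})

test_that("ground-truth indexes apply the refinement rule to intended states", {
  gt <- structure(list(states = c(rep("MID", 1200), "DI", rep("MID", 300)),
                       events = data.frame(), duration_s = 1501L),
                  class = "ground_truth")
  idx <- ground_truth_indexes(gt, min_qs_s = 900)
  expect_equal(idx$qs_pct * 1501 / 100, 1200, tolerance = 1e-9)
  expect_equal(idx$ds_pct * 1501 / 100, 300, tolerance = 1e-9)
  # all-MID truth is all quiet sleep for any feasible minimum
  gt2 <- structure(list(states = rep("MID", 2000), events = data.frame(),
                        duration_s = 2000L), class = "ground_truth")
  expect_equal(ground_truth_indexes(gt2, 900)$qs_pct, 100)
  # identical to running the states pipeline on the intended labels
  coarse <- gt$states
  expect_equal(idx$qs_pct,
               summarize_states(refine_qs_ds(coarse, 900))$qs_pct)
})

test_that("presets encode their scenario", {
  pa <- preset_apnea("S")
  expect_true(pa$apnea_enabled)
  expect_gte(pa$apnea_rate_per_h, 30)
  expect_gte(preset_apnea("Mi")$apnea_rate_per_h, 5)
  expect_lt(preset_apnea("Mi")$apnea_rate_per_h, 15)
  expect_equal(preset_healthy()$movement_interval_s, 5400)
  expect_gte(length(preset_insomnia()$absence), 1)
})

test_that("healthy nights produce roughly one displacement per 1.5 h", {
  proto <- preset_healthy(duration_s = 4 * 3600, fs = 5, n_channels = 2)
  n_events <- sapply(1:12, function(s) {
    nrow(simulate_recording(proto, seed = s)$truth$events)
  })
  # 12 recordings x 4 h at 1/1.5h: expect ~32 events in total, Poisson noise
  expect_gt(sum(n_events), 32 - 4 * sqrt(32))
  expect_lt(sum(n_events), 32 + 4 * sqrt(32))
})

test_that("apnea-burst durations have their mode near 5 s", {
  proto <- preset_apnea("S", duration_s = 2 * 3600, fs = 5, n_channels = 2)
  durs <- unlist(lapply(1:5, function(s) {
    ev <- simulate_recording(proto, seed = s)$truth$events
    ev$duration_s[ev$type == "apnea"]
  }))
  tab <- table(durs)
  mode_s <- as.integer(names(tab)[which.max(tab)])
  expect_gte(mode_s, 3)
  expect_lte(mode_s, 7)
})

test_that("absence intervals and restless bursts appear in the insomnia preset", {
  proto <- preset_insomnia(duration_s = 2 * 3600, fs = 5, n_channels = 2)
  sim <- simulate_recording(proto, seed = 7)
  expect_true(any(sim$truth$states == "ABS"))
  expect_true(any(sim$truth$events$type == "restless"))
  # restless bursts are deliberately not displacement ground truth
  rest <- sim$truth$events[sim$truth$events$type == "restless", ]
  expect_true(any(sim$truth$states[rest$start_s + 1] == "MID"))
})
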