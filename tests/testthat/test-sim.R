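test_that("the simulator is a pure function of its configuration", {
  cfg <- tiny_sim(seed = 42)
  r1 <- simulate_recording(cfg)
  r2 <- simulate_recording(cfg)
  expect_identical(r1$samples, r2$samples)
  expect_identical(r1$annotations, r2$annotations)

  r3 <- simulate_recording(tiny_sim(seed = 43))
  expect_false(all(r1$samples[seq_len(min(length(r1$samples),
                                          length(r3$samples)))] ==
                     r3$samples[seq_len(min(length(r1$samples),
                                            length(r3$samples)))]))

  c1 <- simulate_cohort(cfg, 3)
  c2 <- simulate_cohort(cfg, 3)
  expect_identical(lapply(c1, `[[`, "samples"), lapply(c2, `[[`, "samples"))
})

test_that("annotations respect the configured shot structure", {
  rec <- simulate_recording(sim_config(seed = 7))
  ann <- rec$annotations
  expect_identical(nrow(ann), 6L)
  durations <- ann$t_off - ann$t_on
  expect_true(all(durations >= 0.3 & durations <= 5.0))
  expect_true(all(diff(ann$t_on) > 0))
  expect_true(all(ann$t_on[-1] >= ann$t_off[-nrow(ann)]))
  expect_true(all(ann$t_on >= 0 & ann$t_off <= recording_duration(rec)))
})

test_that("noiseless configuration yields flat QE plateaus", {
  cfg <- tiny_sim(seed = 5, noise_sd = 0, drift_amplitude = 0, blink_rate = 0)
  rec <- simulate_recording(cfg)
  expect_identical(nrow(rec$annotations), cfg$n_shots)
  for (k in seq_len(nrow(rec$annotations))) {
    i0 <- ceiling(rec$annotations$t_on[k] * cfg$fs) + 1L
    i1 <- floor(rec$annotations$t_off[k] * cfg$fs) - 1L
    expect_lt(max(abs(diff(rec$samples[i0:i1]))), 1e-9)
  }
})

test_that("gaze stability separates QE from the rest of each shot", {
  cfg <- sim_config(seed = 9)
  rec <- simulate_recording(cfg, keep_components = TRUE)
  gaze <- rec$components$gaze
  fs <- cfg$fs
  bound <- 1 # uV per sample: plateaus are flat, saccade ramps are steep
  ann <- rec$annotations
  for (k in seq_len(nrow(ann))) {
    qe_idx <- (ceiling(ann$t_on[k] * fs) + 1L):(floor(ann$t_off[k] * fs) - 1L)
    expect_lt(max(abs(diff(gaze[qe_idx]))), bound)
    aim_idx <- (round((ann$t_on[k] - 2.5) * fs) + 1L):(round(ann$t_on[k] * fs))
    expect_gt(max(abs(diff(gaze[aim_idx]))), bound)
  }
})

test_that("drift raises sub-0.1 Hz power relative to the drift-free signal", {
  with_drift <- simulate_recording(sim_config(seed = 3, drift_amplitude = 60))
  without <- simulate_recording(sim_config(seed = 3, drift_amplitude = 0))
  expect_gt(qeyed:::low_freq_power(with_drift$samples, 200),
            qeyed:::low_freq_power(without$samples, 200))
})

test_that("a too-short fixed duration errors and a generous one pads", {
  expect_error(simulate_recording(sim_config(seed = 1, duration_s = 20)),
               "duration_s")
  rec <- simulate_recording(tiny_sim(seed = 1, duration_s = 120))
  expect_identical(length(rec$samples), 120L * 200L)
})

test_that("cohorts have distinct participants and derived seeds", {
  cfg <- tiny_sim(seed = 21)
  cohort <- simulate_cohort(cfg, 4)
  expect_identical(vapply(cohort, `[[`, "", "participant_id"),
                   c("P01", "P02", "P03", "P04"))
  # singleton cohort equals a direct call with the derived seed
  single <- simulate_cohort(cfg, 1)[[1]]
  cfg1 <- cfg
  cfg1$seed <- cfg$seed + 1L
  expect_identical(single$samples, simulate_recording(cfg1)$samples)
  expect_error(simulate_cohort(cfg, 0), "at least 1")
})

test_that("recordings round-trip through the text format", {
  rec <- simulate_recording(tiny_sim(seed = 31))
  path <- withr::local_tempfile(fileext = ".txt")
  write_recording(rec, path)
  back <- read_recording(path)
  expect_equal(back$samples, rec$samples, tolerance = 1e-6)
  expect_identical(back$fs, rec$fs)
  expect_identical(back$participant_id, rec$participant_id)
  expect_equal(back$annotations$t_on, rec$annotations$t_on, tolerance = 1e-6)
  expect_equal(back$annotations$t_off, rec$annotations$t_off,
               tolerance = 1e-6)
})
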