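test_that("bandpass matches the analytic Butterworth response", {
  fs <- 200
  t <- (0:3999) / fs
  # DC is far below the 0.1 Hz edge; the 0.1 Hz corner settles over several
  # seconds, so judge the middle of a 40 s record
  dc <- bandpass_filter(rep(1, 8000), fs)
  expect_lt(max(abs(dc[3500:4500])), 0.05)
  # 5 Hz tone sits mid-passband: steady-state amplitude within 5% of unity
  y5 <- bandpass_filter(sin(2 * pi * 5 * t), fs)
  amp5 <- max(abs(y5[1000:3000]))
  expect_lt(abs(amp5 - 1), 0.05)
  # 50 Hz tone is one octave-plus beyond the 20 Hz edge: >= 20 dB down
  y50 <- bandpass_filter(sin(2 * pi * 50 * t), fs)
  amp50 <- max(abs(y50[1000:3000]))
  expect_lt(20 * log10(amp50), -20)
})

test_that("zero-phase filtering leaves passband tones undelayed", {
  fs <- 200
  t <- (0:3999) / fs
  x <- sin(2 * pi * 5 * t)
  y <- bandpass_filter(x, fs, filter_spec(zero_phase = TRUE))
  mid <- 1001:3000
  cc <- stats::ccf(y[mid], x[mid], lag.max = 10, plot = FALSE)
  expect_equal(as.numeric(cc$lag[which.max(cc$acf)]), 0)
})

test_that("invalid filter settings error", {
  expect_error(filter_spec(low_hz = 0), "low_hz")
  expect_error(bandpass_filter(rnorm(100), fs = 30, filter_spec(high_hz = 20)),
               "Nyquist")
})

test_that("scenario switch applies the expected stages", {
  rec <- simulate_recording(sim_config(seed = 11))
  a <- apply_scenario(rec, "A")
  expect_identical(a$samples, rec$samples)
  expect_identical(a$annotations, rec$annotations)

  # both stages kill a constant signal
  const <- eog_recording(rep(5, 4096), fs = 200)
  c_out <- apply_scenario(const, "C", wavelet_spec("db4", 5))
  expect_lt(max(abs(c_out$samples[500:3500])), 1e-6)

  # on a drift-heavy simulation, C suppresses sub-0.1 Hz power below B
  drifty <- simulate_recording(sim_config(seed = 12, drift_amplitude = 150))
  b <- apply_scenario(drifty, "B")
  cc <- apply_scenario(drifty, "C")
  expect_lt(qeyed:::low_freq_power(cc$samples, 200),
            qeyed:::low_freq_power(b$samples, 200))

  # all stages preserve length, sampling rate and annotations
  expect_identical(length(b$samples), length(drifty$samples))
  expect_identical(length(cc$samples), length(drifty$samples))
  expect_identical(cc$annotations, drifty$annotations)
  expect_identical(cc$fs, drifty$fs)
})
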