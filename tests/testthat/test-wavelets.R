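test_that("single-level decomposition matches independent DWT reference", {
  # Reference coefficients for x = 1..12, Daubechies-4, symmetric padding,
  # precomputed with an independent wavelet implementation.
  d <- decompose_signal(1:12, wavelet_spec("db4", levels = 1))
  ref_cA <- c(7.06453146, 4.23073611, 1.41360717, 2.83605428, 5.66448141,
              8.49290853, 11.32024485, 14.15404020, 16.97116914)
  ref_cD <- c(0.0237131306, 0.0409620864, -0.0646752170, 0, 0, 0,
              -0.0237131306, -0.0409620864, 0.0646752170)
  expect_equal(d$approx, ref_cA, tolerance = 1e-7)
  expect_equal(d$details[[1]], ref_cD, tolerance = 1e-7)
})

test_that("multilevel decomposition reconstructs the signal exactly", {
  for (seed in 1:5) {
    x <- withr::with_seed(seed, cumsum(rnorm(1500)) + rnorm(1500))
    for (mother in c("db2", "db4")) {
      spec <- wavelet_spec(mother, levels = 5)
      rec <- reconstruct_signal(decompose_signal(x, spec))
      expect_lt(max(abs(rec - x)), 1e-8 * max(abs(x)))
    }
  }
})

test_that("degenerate inputs behave linearly", {
  spec <- wavelet_spec("db4", levels = 4)
  z <- decompose_signal(numeric(300), spec)
  expect_true(all(abs(z$approx) == 0))
  expect_true(all(vapply(z$details, function(d) all(abs(d) == 0), TRUE)))

  const <- decompose_signal(rep(3.7, 512), wavelet_spec("db4", 6))
  expect_lt(max(vapply(const$details, function(d) max(abs(d)), 0)), 1e-10)
  expect_lt(max(abs(remove_baseline(rep(3.7, 512), wavelet_spec("db4", 6)))),
            1e-10)

  # linearity of the baseline-removal operator
  x <- withr::with_seed(2, rnorm(800))
  y <- withr::with_seed(3, cumsum(rnorm(800)))
  spec <- wavelet_spec("db4", 5)
  expect_equal(remove_baseline(x + y, spec),
               remove_baseline(x, spec) + remove_baseline(y, spec),
               tolerance = 1e-10)
})

test_that("over-deep decomposition errors with the feasible depth", {
  expect_error(decompose_signal(rnorm(100), wavelet_spec("db4", 10)),
               "at most")
})

test_that("baseline removal keeps a mid-band tone and drops a slow ramp", {
  fs <- 200
  t <- (0:11999) / fs
  tone <- sin(2 * pi * 5 * t)
  ramp <- 10 * t / max(t) + 10 * sin(2 * pi * 0.01 * t)
  cleaned <- remove_baseline(tone + ramp, wavelet_spec("db4", 10))
  expect_gt(stats::cor(cleaned, tone), 0.99)
})
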