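test_that("cross-validation yields one metrics row per fold", {
  segs <- segment_cohort(simulate_cohort(tiny_sim(seed = 14), 4),
                         window_spec(0.5, 1.0))
  folds <- make_folds(segs, k = 2, seed = 1)
  cv <- cross_validate(segs, folds, detector_spec("svm"),
                       train_config(epochs = 1, seed = 1), tolerance = 0.1)
  expect_identical(nrow(cv$folds), 2L)
  expect_identical(cv$folds$fold, 1:2)
  # summary mean is the arithmetic mean of the per-fold values
  expect_equal(cv$summary$mean[cv$summary$metric == "accuracy"],
               mean(cv$folds$accuracy))
  td <- tidy(cv)
  expect_identical(td$family, rep("svm", 2))
  g <- glance(cv)
  expect_identical(g$k, 2L)
  expect_true(all(c("f1", "f1_sd", "mae_onset_ms") %in% names(g)))
})

test_that("augmented copies train but are not scored", {
  segs <- augment_segments(
    segment_cohort(simulate_cohort(tiny_sim(seed = 15), 4),
                   window_spec(0.5, 1.0)),
    augment_spec(copies_per_segment = 1, seed = 2))
  folds <- make_folds(segs, k = 2, seed = 3)
  cv <- cross_validate(segs, folds, detector_spec("svm"),
                       train_config(epochs = 1, seed = 1))
  # each fold's test half holds 4 original segments (2 participants x 2 shots)
  expect_identical(unique(cv$folds$n_segments), 4L)
})

test_that("metric bounds hold on every cross-validated report", {
  segs <- segment_cohort(simulate_cohort(tiny_sim(seed = 16), 4),
                         window_spec(0.5, 1.0))
  folds <- make_folds(segs, k = 2, seed = 1)
  cv <- cross_validate(segs, folds, detector_spec("cnn1d", width_scale = 0.1),
                       train_config(epochs = 2, batch_size = 4, seed = 2,
                                    validation_fraction = 0))
  ok <- function(v) all(is.na(v) | (v >= 0 & v <= 1))
  expect_true(ok(cv$folds$accuracy))
  expect_true(ok(cv$folds$ppv))
  expect_true(ok(cv$folds$sen))
  expect_true(ok(cv$folds$f1))
  with(cv$folds, {
    defined <- !is.na(ppv) & !is.na(sen) & (ppv + sen) > 0
    expect_equal(f1[defined], (2 * ppv * sen / (ppv + sen))[defined])
  })
})
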