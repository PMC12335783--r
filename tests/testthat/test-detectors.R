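# Detector-contract tests run on short segments (L = 300 at 200 Hz) so the
# whole file stays fast; the full-length end-to-end behaviour is covered by
# the acceptance suite.

fit_tiny <- function(family, segs, epochs = 3, seed = 1, ...) {
  det <- build_detector(detector_spec(family, width_scale = 0.1, ...),
                        ncol(segs$x), seed = seed)
  fit_detector(det, segs, train_config(epochs = epochs, batch_size = 4,
                                       seed = seed, validation_fraction = 0))
}

test_that("every family maps a segment to an equal-length probability trace", {
  L <- 300L
  X <- matrix(rnorm(2 * L), 2, L)
  for (fam in c("cnn1d", "transformer", "unet", "cnn_gru", "cnn_lstm")) {
    det <- build_detector(detector_spec(fam, width_scale = 0.1, heads = 2), L,
                          seed = 4)
    fw <- qeyed:::.net_forward(det$net, X, train = FALSE)
    expect_identical(dim(fw$logits), c(2L, L))
    probs <- stats::plogis(fw$logits)
    expect_true(all(is.finite(probs)))
    expect_true(all(probs >= 0 & probs <= 1))
    # untrained response to an all-zero input is also finite and in range
    fw0 <- qeyed:::.net_forward(det$net, matrix(0, 1, L), train = FALSE)
    expect_true(all(is.finite(stats::plogis(fw0$logits))))
  }
})

test_that("lengths indivisible by the pooling depth are padded and cropped", {
  det <- build_detector(detector_spec("unet", width_scale = 0.1), 1700L,
                        seed = 1)
  fw <- qeyed:::.net_forward(det$net, matrix(rnorm(1700), 1, 1700),
                             train = FALSE)
  expect_identical(ncol(fw$logits), 1700L) # padded to 1704 internally
  expect_identical(det$net$config$pad, 8L)
})

test_that("training reduces the loss and is reproducible under a seed", {
  segs <- tiny_segments(seed = 10, n_participants = 3)
  m1 <- fit_tiny("cnn1d", segs, epochs = 8, seed = 2)
  m2 <- fit_tiny("cnn1d", segs, epochs = 8, seed = 2)
  expect_identical(tidy(m1), tidy(m2))
  lg <- tidy(m1)
  expect_lte(lg$loss[nrow(lg)], lg$loss[1])
  expect_identical(nrow(lg), 8L)

  expect_error(train_config(epochs = 0), "epochs")
})

test_that("prediction is deterministic and respects the threshold", {
  segs <- tiny_segments(seed = 11, n_participants = 2)
  det <- fit_tiny("cnn_gru", segs, epochs = 2)
  p1 <- predict(det, segs)
  p2 <- predict(det, segs)
  expect_identical(p1$probs, p2$probs)
  expect_identical(p1$mask, p2$mask)
  expect_identical(dim(p1$probs), dim(segs$x))
  expect_identical(p1$mask, matrix(as.integer(p1$probs >= 0.5),
                                   nrow = nrow(p1$probs)))

  short <- tiny_segments(seed = 11, n_participants = 2,
                         win = window_spec(0.25, 0.5))
  expect_error(predict(det, short), "does not match")
  expect_error(predict(build_detector(detector_spec("cnn1d"), 300), segs),
               "fitted")
})

test_that("the SVM baseline learns an amplitude-separable labeling", {
  # piecewise signal whose QE plateau sits at a distinct amplitude: a
  # per-timepoint RBF on standardized amplitude must recover the labels
  L <- 200L
  n <- 8L
  x <- matrix(rnorm(n * L, sd = 0.1), n, L)
  mask <- matrix(0L, n, L)
  for (i in seq_len(n)) {
    x[i, 80:140] <- x[i, 80:140] + 5
    mask[i, 80:140] <- 1L
  }
  segs <- qeyed:::new_qe_segments(x, mask,
                                  tibble::tibble(participant_id = rep(c("A", "B"),
                                                                      each = 4),
                                                 shot_id = rep(1:4, 2),
                                                 augmented = FALSE,
                                                 parent = NA_integer_),
                                  fs = 200, window = window_spec(0.5, 0.5))
  det <- build_detector(detector_spec("svm", max_train_points = 500), L)
  det <- fit_detector(det, segs, train_config(epochs = 1, seed = 3))
  pr <- predict(det, segs)
  expect_gt(mean(pr$mask == segs$mask), 0.95)
  expect_true(all(pr$probs >= 0 & pr$probs <= 1))
})

test_that("single-class training masks warn but do not abort", {
  segs <- tiny_segments(seed = 12, n_participants = 2)
  segs$mask[] <- 0L
  expect_warning(fit_tiny("cnn1d", segs, epochs = 1), "single class")
})

test_that("training logs expose validation curves when requested", {
  segs <- tiny_segments(seed = 13, n_participants = 3)
  det <- build_detector(detector_spec("cnn1d", width_scale = 0.1),
                        ncol(segs$x), seed = 5)
  det <- fit_detector(det, segs,
                      train_config(epochs = 2, batch_size = 4, seed = 5,
                                   validation_fraction = 0.25))
  lg <- tidy(det)
  expect_true(all(c("val_loss", "val_accuracy") %in% names(lg)))
  expect_true(all(is.finite(lg$val_loss)))
  g <- glance(det)
  expect_identical(g$family, "cnn1d")
  expect_identical(g$epochs, 2L)
})
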