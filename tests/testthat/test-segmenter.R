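test_that("the default window yields 1700-sample segments", {
  expect_identical(window_length(window_spec(), 200), 1700L)
  rec <- simulate_recording(tiny_sim(seed = 2))
  segs <- extract_segments(rec)
  expect_identical(ncol(segs$x), 1700L)
  expect_identical(nrow(segs$x), nrow(rec$annotations))
  expect_identical(dim(segs$x), dim(segs$mask))
})

test_that("masks cover exactly the annotated half-open interval", {
  rec <- manual_recording(n = 4000, t_on = 6, t_off = 8) # 2.0 s QE
  segs <- extract_segments(rec)
  expect_lte(abs(sum(segs$mask[1, ]) - 400L), 1L)
  # mask starts at the sample whose time is t_on: index pre_s * fs (0-based)
  first_one <- which(segs$mask[1, ] == 1L)[1]
  expect_identical(first_one, 501L)
  # samples are the raw signal on the expected absolute index range
  s0 <- round((6 - 2.5) * 200)
  expect_identical(segs$x[1, ], rec$samples[(s0 + 1):(s0 + 1700)])
})

test_that("windows crossing a recording edge are skipped with a warning", {
  rec <- manual_recording(n = 4000, t_on = 1.0, t_off = 2.0)
  expect_warning(segs <- extract_segments(rec), "skipped")
  expect_identical(nrow(segs$x), 0L)
  expect_identical(attr(segs, "n_skipped"), 1L)
})

test_that("every emitted mask is one contiguous run", {
  segs <- segment_cohort(simulate_cohort(sim_config(seed = 6), 3))
  for (i in seq_len(n_segments(segs))) {
    runs <- rle(segs$mask[i, ])
    expect_identical(sum(runs$values == 1L), 1L)
  }
})

test_that("null augmentation copies segments except the flag", {
  segs <- tiny_segments(seed = 3)
  aug <- augment_segments(segs, augment_spec(max_shift_s = 0, noise_sd = 0,
                                             copies_per_segment = 1))
  n <- n_segments(segs)
  expect_identical(n_segments(aug), 2L * n)
  expect_identical(aug$x[n + seq_len(n), ], segs$x)
  expect_identical(aug$mask[n + seq_len(n), ], segs$mask)
  expect_true(all(aug$meta$augmented[n + seq_len(n)]))
  expect_identical(aug$meta$parent[n + seq_len(n)], seq_len(n))
})

test_that("augmentation preserves QE run length and is seed-deterministic", {
  segs <- segment_cohort(simulate_cohort(tiny_sim(seed = 4), 2))
  spec <- augment_spec(max_shift_s = 0.25, copies_per_segment = 2, seed = 9)
  a1 <- augment_segments(segs, spec)
  a2 <- augment_segments(segs, spec)
  expect_identical(a1$x, a2$x)
  n <- n_segments(segs)
  for (i in seq_len(n_segments(a1) - n)) {
    parent <- a1$meta$parent[n + i]
    expect_identical(sum(a1$mask[n + i, ]), sum(segs$mask[parent, ]))
    runs <- rle(a1$mask[n + i, ])
    expect_identical(sum(runs$values == 1L), 1L)
  }
})

test_that("noise-only augmentation perturbs samples but not masks", {
  segs <- tiny_segments(seed = 5)
  aug <- augment_segments(segs, augment_spec(max_shift_s = 0, noise_sd = 2,
                                             copies_per_segment = 1, seed = 2))
  n <- n_segments(segs)
  L <- ncol(segs$x)
  for (i in seq_len(n)) {
    expect_identical(aug$mask[n + i, ], segs$mask[i, ])
    diffs <- aug$x[n + i, ] - segs$x[i, ]
    expect_gt(sd(diffs), 0)
    expect_lt(abs(mean(diffs)), 3 * 2 / sqrt(L))
  }
})

test_that("folds partition segments and never split a participant", {
  segs <- segment_cohort(simulate_cohort(sim_config(seed = 1), 10))
  expect_identical(n_segments(segs), 60L)
  folds <- make_folds(segs, k = 5, seed = 3)
  test_sets <- lapply(folds, `[[`, "test")
  expect_identical(sort(unlist(test_sets)), seq_len(60L))
  expect_identical(unique(lengths(test_sets)), 12L)
  for (f in folds) {
    expect_length(intersect(f$train, f$test), 0)
    shared <- intersect(segs$meta$participant_id[f$train],
                        segs$meta$participant_id[f$test])
    expect_length(shared, 0)
  }
})

test_that("augmented copies land in the same fold as their parent", {
  segs <- augment_segments(segment_cohort(simulate_cohort(tiny_sim(1), 4)),
                           augment_spec(copies_per_segment = 1, seed = 5))
  folds <- make_folds(segs, k = 2, seed = 6)
  fold_of <- integer(n_segments(segs))
  for (f in seq_along(folds)) fold_of[folds[[f]]$test] <- f
  aug_rows <- which(segs$meta$augmented)
  expect_identical(fold_of[aug_rows], fold_of[segs$meta$parent[aug_rows]])
})

test_that("too many folds for the participant pool errors", {
  segs <- tiny_segments(seed = 7, n_participants = 2)
  expect_error(make_folds(segs, k = 5), "k <= 2")
})

test_that("segment stores round-trip through the text format", {
  segs <- augment_segments(tiny_segments(seed = 8),
                           augment_spec(copies_per_segment = 1, seed = 1))
  dir <- withr::local_tempdir()
  write_segments(segs, dir)
  back <- read_segments(dir)
  expect_equal(back$x, segs$x, tolerance = 1e-9)
  expect_identical(back$mask, segs$mask)
  expect_identical(back$meta$participant_id, segs$meta$participant_id)
  expect_identical(back$meta$augmented, segs$meta$augmented)
  expect_identical(back$fs, segs$fs)
  expect_identical(back$window$pre_s, segs$window$pre_s)
})
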