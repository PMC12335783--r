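# The package's standard seeded benchmark: a fully synthetic re-run of the
# study design (10 participants x 6 shots, 5-fold participant-grouped CV)
# at desk scale, used by the test-suite and the acceptance script.

#' Run the standard synthetic QE-detection benchmark
#'
#' Simulates a cohort, preprocesses it under the requested scenarios,
#' segments/augments it, and cross-validates the requested detector families,
#' returning per-model-per-scenario metric summaries. Everything derives
#' deterministically from `seed`.
#'
#' The desk-scale sizing (narrow networks via `width_scale`, shortened
#' training) keeps a full 5-fold run of the recurrent hybrids tractable on a
#' single CPU; see the methods vignette for the rationale.
#'
#' @param families Character vector of detector families to run.
#' @param scenarios Preprocessing scenarios (subset of `"A"`, `"B"`, `"C"`).
#' @param seed Master seed.
#' @param n_participants,n_shots Cohort size (defaults mirror the study
#'   design: 10 participants, 6 shots each).
#' @param k Cross-validation folds.
#' @param epochs Training epochs: a single number, or a named vector with
#'   per-family entries (unnamed families fall back to `30`). The defaults
#'   give the recurrent hybrids the longest schedule, which their loss
#'   curves need to level off, and the cheap families proportionally less.
#' @param batch_size,width_scale Desk-scale training budget.
#' @param augment_copies Augmented copies per segment used for training.
#' @param tolerance Event-matching tolerance in seconds.
#' @param sim Optional [sim_config()] overriding the default simulation
#'   (its seed is still replaced by `seed`).
#' @param quiet If `FALSE`, prints per-stage progress.
#' @return A `qe_benchmark` object: tibble `results` (scenario, family,
#'   per-fold metrics), tibble `summaries` (one row per scenario x family),
#'   and the settings used.
#' @export
qe_benchmark <- function(families = c("cnn_lstm", "cnn_gru", "cnn1d", "svm"),
                         scenarios = "C", seed = 1L, n_participants = 10L,
                         n_shots = 6L, k = 5L,
                         epochs = c(cnn_lstm = 22L, cnn_gru = 10L,
                                    cnn1d = 15L, transformer = 15L,
                                    unet = 15L, svm = 1L),
                         batch_size = 2L, width_scale = 0.25,
                         augment_copies = 1L, tolerance = 0.1, sim = NULL,
                         quiet = TRUE) {
  say <- function(...) if (!quiet) message(sprintf(...))
  epochs_for <- function(fam) {
    if (length(epochs) == 1L && is.null(names(epochs))) return(as.integer(epochs))
    as.integer(epochs[[fam]] %||% 30L)
  }
  base_sim <- sim %||% sim_config()
  base_sim$seed <- as.integer(seed)
  base_sim$n_shots <- as.integer(n_shots)
  say("simulating %d participants x %d shots", n_participants, n_shots)
  cohort <- simulate_cohort(base_sim, n_participants)
  all_folds <- list(); all_glance <- list()
  for (sc in scenarios) {
    say("scenario %s: preprocess + segment", sc)
    processed <- lapply(cohort, apply_scenario, scenario = sc)
    segs <- segment_cohort(processed)
    if (augment_copies > 0L) {
      segs <- augment_segments(segs, augment_spec(
        copies_per_segment = augment_copies, seed = seed + 2000L))
    }
    folds <- make_folds(segs, k = k, seed = seed + 3000L)
    for (fam in families) {
      say("scenario %s: cross-validating %s", sc, fam)
      spec <- detector_spec(fam, width_scale = width_scale)
      cfg <- train_config(epochs = epochs_for(fam), batch_size = batch_size,
                          seed = seed + 1000L, validation_fraction = 0)
      cv <- cross_validate(segs, folds, spec, cfg, tolerance = tolerance)
      all_folds[[length(all_folds) + 1L]] <-
        dplyr::mutate(tidy(cv), scenario = sc)
      all_glance[[length(all_glance) + 1L]] <-
        dplyr::mutate(glance(cv), scenario = sc)
    }
  }
  structure(list(results = dplyr::relocate(dplyr::bind_rows(all_folds),
                                           "scenario"),
                 summaries = dplyr::relocate(dplyr::bind_rows(all_glance),
                                             "scenario"),
                 seed = seed, k = k, tolerance = tolerance,
                 width_scale = width_scale, epochs = epochs),
            class = "qe_benchmark")
}

#' @export
print.qe_benchmark <- function(x, ...) {
  cat(sprintf("<qe_benchmark> seed %d, %d-fold, width x%g\n",
              x$seed, x$k, x$width_scale))
  print(x$summaries)
  invisible(x)
}

#' @describeIn qe_benchmark Per-fold results table.
#' @param x A `qe_benchmark`.
#' @param ... Unused.
#' @export
tidy.qe_benchmark <- function(x, ...) x$results

#' @describeIn qe_benchmark Scenario x family summary table.
#' @export
glance.qe_benchmark <- function(x, ...) x$summaries
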