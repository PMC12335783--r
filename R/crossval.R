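# Cross-validated training/evaluation of detectors over participant-grouped
# folds, producing per-fold and pooled metric tables.

#' Event-level evaluation of predictions against ground-truth masks
#'
#' For every segment, events are extracted from the predicted and true masks,
#' matched under the tolerance, and pooled into one [compute_metrics()]
#' report.
#'
#' @param predictions A `qe_predictions` from [predict.qe_detector()].
#' @param segments The `qe_segments` the predictions were made on.
#' @param tolerance Event-matching tolerance in seconds.
#' @return A `qe_metrics` tibble row.
#' @export
evaluate_predictions <- function(predictions, segments, tolerance = 0.1) {
  fs <- segments$fs
  matches <- lapply(seq_len(nrow(predictions$mask)), function(i) {
    match_events(extract_events(predictions$mask[i, ], fs),
                 extract_events(segments$mask[i, ], fs),
                 tolerance = tolerance)
  })
  compute_metrics(matches, predictions$mask, segments$mask)
}

.subset_segments <- function(segments, idx) {
  new_qe_segments(segments$x[idx, , drop = FALSE],
                  segments$mask[idx, , drop = FALSE],
                  segments$meta[idx, ], segments$fs, segments$window)
}

#' k-fold cross-validation of one detector
#'
#' Trains the detector on each fold's training split and evaluates
#' event-level and per-sample metrics on its test split. Augmented copies
#' are used for training but excluded from test-set scoring, so reported
#' metrics refer to original (unaugmented) segments.
#'
#' @param segments A `qe_segments` container.
#' @param folds Folds from [make_folds()].
#' @param spec A [detector_spec()].
#' @param cfg A [train_config()]. Per-fold model initialization derives its
#'   seed from `cfg$seed` plus the fold number.
#' @param tolerance Event-matching tolerance in seconds.
#' @return A `qe_cv` object: `folds` (per-fold `qe_metrics` with a `fold`
#'   column), `summary` (mean and sd per metric), the spec and settings.
#' @examples
#' \donttest{
#' segs <- segment_cohort(simulate_cohort(sim_config(seed = 1), 5))
#' folds <- make_folds(segs, k = 2)
#' cv <- cross_validate(segs, folds, detector_spec("svm"),
#'                      train_config(epochs = 1))
#' glance(cv)
#' }
#' @export
cross_validate <- function(segments, folds, spec, cfg = train_config(),
                           tolerance = 0.1) {
  per_fold <- vector("list", length(folds))
  fits <- vector("list", length(folds))
  for (f in seq_along(folds)) {
    tr <- .subset_segments(segments, folds[[f]]$train)
    te_idx <- folds[[f]]$test
    te_idx <- te_idx[!segments$meta$augmented[te_idx]]
    te <- .subset_segments(segments, te_idx)
    model <- build_detector(spec, ncol(segments$x), seed = cfg$seed + f)
    model <- fit_detector(model, tr, cfg)
    preds <- predict(model, te)
    met <- evaluate_predictions(preds, te, tolerance)
    met$fold <- f
    per_fold[[f]] <- met
    fits[[f]] <- model$log
  }
  fold_tbl <- dplyr::bind_rows(per_fold)
  metric_cols <- c("accuracy", "ppv", "sen", "f1", "mae_onset_ms",
                   "mae_offset_ms")
  summary <- dplyr::bind_rows(lapply(metric_cols, function(m) {
    v <- fold_tbl[[m]]
    tibble(metric = m, mean = mean(v, na.rm = TRUE),
           sd = sd(v, na.rm = TRUE))
  }))
  structure(list(folds = fold_tbl, summary = summary, spec = spec,
                 cfg = cfg, tolerance = tolerance, training_logs = fits),
            class = "qe_cv")
}

#' @export
print.qe_cv <- function(x, ...) {
  cat(sprintf("<qe_cv> %s, %d fold(s), tolerance %g s\n", x$spec$family,
              nrow(x$folds), x$tolerance))
  print(x$summary)
  invisible(x)
}

#' @describeIn cross_validate Per-fold metrics table.
#' @param x A `qe_cv`.
#' @param ... Unused.
#' @export
tidy.qe_cv <- function(x, ...) {
  dplyr::relocate(dplyr::mutate(x$folds, family = x$spec$family),
                  "family", "fold")
}

#' @describeIn cross_validate One-row summary (mean over folds, pooled
#'   events).
#' @export
glance.qe_cv <- function(x, ...) {
  s <- x$summary
  g <- stats::setNames(as.list(s$mean), s$metric)
  sdcols <- stats::setNames(as.list(s$sd), paste0(s$metric, "_sd"))
  dplyr::bind_cols(tibble(family = x$spec$family, k = nrow(x$folds)),
                   as_tibble(g), as_tibble(sdcols))
}

#' @describeIn cross_validate Per-fold metric distribution plot.
#' @param object A `qe_cv`.
#' @export
autoplot.qe_cv <- function(object, ...) {
  df <- tidyr::pivot_longer(object$folds,
                            dplyr::all_of(c("accuracy", "ppv", "sen", "f1")),
                            names_to = "metric")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.1, alpha = 0.6) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(title = sprintf("%s: per-fold metrics",
                                  object$spec$family),
                  x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}
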