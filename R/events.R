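# Event-level scoring: masks -> onset/offset events, tolerance matching of
# predicted vs ground-truth events, and the summary metrics (per-sample
# accuracy, PPV, SEN, F1, timing biases, MAE).

#' Extract onset/offset events from a binary mask
#'
#' Chronological transition scan: a 0-to-1 transition at (0-based) index `i`
#' emits an onset at `i / fs` seconds; a 1-to-0 transition at index `j` emits
#' an offset at `j / fs`. A run still open at the segment end is closed at
#' `L / fs`; a run open at the start opens at 0, so events touching the
#' segment boundary are kept with clamped endpoints.
#'
#' @param mask Numeric/integer vector of 0s and 1s.
#' @param fs Sampling rate in Hz.
#' @return A tibble with columns `onset`, `offset` (seconds), one row per
#'   event, chronologically ordered.
#' @examples
#' extract_events(c(0, 0, 1, 1, 1, 0), fs = 200)
#' @export
extract_events <- function(mask, fs) {
  mask <- as.vector(mask)
  if (!all(mask %in% c(0, 1))) abort("`mask` must be 0/1 valued.")
  n <- length(mask)
  if (n == 0L || !any(mask == 1)) return(tibble(onset = numeric(), offset = numeric()))
  d <- diff(c(0, mask, 0))
  on_idx0 <- which(d == 1) - 1L   # 0-based index of the first 1 in each run
  off_idx0 <- which(d == -1) - 1L # 0-based index of the first 0 after each run
  tibble(onset = on_idx0 / fs, offset = off_idx0 / fs)
}

#' Rebuild a binary mask from an event list
#'
#' Inverse of [extract_events()] for events aligned to the sample grid:
#' sample `i` (0-based) is 1 iff `i / fs` lies in some `[onset, offset)`.
#'
#' @param events Tibble with `onset` and `offset` columns (seconds).
#' @param n_samples Output mask length.
#' @param fs Sampling rate in Hz.
#' @return Integer 0/1 vector of length `n_samples`.
#' @export
events_to_mask <- function(events, n_samples, fs) {
  m <- integer(n_samples)
  times <- (seq_len(n_samples) - 1L) / fs
  for (k in seq_len(nrow(events))) {
    m[times >= events$onset[k] - 1e-9 & times < events$offset[k] - 1e-9] <- 1L
  }
  m
}

# Chronological greedy tolerance matching of two sorted time vectors.
# For each true time (in order) take the earliest unmatched prediction within
# the tolerance window. For matching points to equal-width windows on a line
# this greedy is maximum-cardinality (exchange argument), which a
# nearest-prediction rule is not.
.match_times <- function(pred, truth, tol) {
  matched_pred <- integer(0)
  bias <- numeric(0)
  j <- 1L
  np <- length(pred)
  used <- logical(np)
  for (t in truth) {
    while (j <= np && (used[j] || pred[j] < t - tol - 1e-12)) j <- j + 1L
    if (j <= np && pred[j] <= t + tol + 1e-12) {
      used[j] <- TRUE
      matched_pred <- c(matched_pred, j)
      bias <- c(bias, pred[j] - t)
    }
  }
  list(tp = length(bias), fp = np - length(bias),
       fn = length(truth) - length(bias), bias = bias)
}

#' Match predicted events to ground truth under a time tolerance
#'
#' Onsets and offsets are matched independently, one-to-one and
#' chronologically: a predicted event is a true positive when a ground-truth
#' event of the same type lies within `tolerance` seconds (|bias| <=
#' tolerance). Unmatched predictions are false positives; unmatched truths
#' are false negatives. For each matched pair the signed bias
#' (predicted - true, seconds) is recorded.
#'
#' @param pred,truth Event tibbles from [extract_events()].
#' @param tolerance Matching tolerance in seconds (default 0.1, i.e. 100 ms).
#' @return A `qe_match` object: TP/FP/FN counts per event type, signed bias
#'   vectors, and the tolerance.
#' @examples
#' truth <- tibble::tibble(onset = 2.5, offset = 4.5)
#' pred <- tibble::tibble(onset = 2.58, offset = 4.46)
#' match_events(pred, truth)
#' @export
match_events <- function(pred, truth, tolerance = 0.1) {
  if (tolerance < 0) abort("`tolerance` must be >= 0.")
  m_on <- .match_times(sort(pred$onset), sort(truth$onset), tolerance)
  m_off <- .match_times(sort(pred$offset), sort(truth$offset), tolerance)
  structure(list(tp_on = m_on$tp, fp_on = m_on$fp, fn_on = m_on$fn,
                 tp_off = m_off$tp, fp_off = m_off$fp, fn_off = m_off$fn,
                 onset_biases = m_on$bias, offset_biases = m_off$bias,
                 tolerance = tolerance),
            class = "qe_match")
}

#' @export
print.qe_match <- function(x, ...) {
  cat(sprintf(paste0("<qe_match> tol %g s | onsets TP %d FP %d FN %d | ",
                     "offsets TP %d FP %d FN %d\n"),
              x$tolerance, x$tp_on, x$fp_on, x$fn_on,
              x$tp_off, x$fp_off, x$fn_off))
  invisible(x)
}

#' @describeIn match_events One row per matched event with its signed bias.
#' @param x A `qe_match`.
#' @param ... Unused.
#' @export
tidy.qe_match <- function(x, ...) {
  dplyr::bind_rows(
    tibble(event = "onset", bias_s = x$onset_biases),
    tibble(event = "offset", bias_s = x$offset_biases))
}

#' Pool match reports into summary metrics
#'
#' TP/FP/FN are pooled over all match reports with onset and offset events
#' together; PPV = TP/(TP+FP), SEN = TP/(TP+FN) and F1 = 2*PPV*SEN/(PPV+SEN)
#' are computed from the pooled counts. Per-sample accuracy is the fraction
#' of samples where the predicted and true masks agree. MAE is the mean
#' absolute bias over matched onsets (resp. offsets), in milliseconds.
#' Metrics with a zero denominator are reported as `NA` rather than a silent
#' zero.
#'
#' @param matches A `qe_match` or list of them.
#' @param pred_masks,truth_masks Matrices (segments in rows) or lists of
#'   equal-length 0/1 vectors.
#' @return A `qe_metrics` tibble row: `accuracy`, `ppv`, `sen`, `f1`,
#'   `mae_onset_ms`, `mae_offset_ms`, `bias_onset_ms`, `bias_offset_ms`,
#'   pooled counts `tp`, `fp`, `fn`, and `n_segments`.
#' @examples
#' truth <- tibble::tibble(onset = 2.5, offset = 4.5)
#' pred <- tibble::tibble(onset = 2.52, offset = 4.48)
#' m <- match_events(pred, truth)
#' mask <- c(rep(0, 500), rep(1, 400), rep(0, 800))
#' compute_metrics(m, mask, mask)
#' @export
compute_metrics <- function(matches, pred_masks, truth_masks) {
  if (inherits(matches, "qe_match")) matches <- list(matches)
  if (length(matches) == 0L) abort("`matches` must be non-empty.")
  as_mat <- function(m) {
    if (is.list(m)) do.call(rbind, m) else rbind(m)
  }
  pm <- as_mat(pred_masks); tm <- as_mat(truth_masks)
  if (!all(dim(pm) == dim(tm))) {
    abort("Predicted and true masks must have matching dimensions.")
  }
  tp <- sum(vapply(matches, function(m) m$tp_on + m$tp_off, 0))
  fp <- sum(vapply(matches, function(m) m$fp_on + m$fp_off, 0))
  fn <- sum(vapply(matches, function(m) m$fn_on + m$fn_off, 0))
  safe_div <- function(num, den) if (den > 0) num / den else NA_real_
  ppv <- safe_div(tp, tp + fp)
  sen <- safe_div(tp, tp + fn)
  f1 <- if (!is.na(ppv) && !is.na(sen) && (ppv + sen) > 0) {
    2 * ppv * sen / (ppv + sen)
  } else {
    NA_real_
  }
  on_bias <- unlist(lapply(matches, `[[`, "onset_biases"))
  off_bias <- unlist(lapply(matches, `[[`, "offset_biases"))
  mean_or_na <- function(v) if (length(v) > 0) mean(v) else NA_real_
  structure(
    tibble(accuracy = mean(pm == tm),
           ppv = ppv, sen = sen, f1 = f1,
           mae_onset_ms = 1000 * mean_or_na(abs(on_bias)),
           mae_offset_ms = 1000 * mean_or_na(abs(off_bias)),
           bias_onset_ms = 1000 * mean_or_na(on_bias),
           bias_offset_ms = 1000 * mean_or_na(off_bias),
           tp = tp, fp = fp, fn = fn, n_segments = nrow(pm)),
    class = c("qe_metrics", class(tibble())))
}

#' Paired comparison of per-fold metric values
#'
#' Two-sided paired t-test on fold-wise differences between two runs (for
#' example the same model under two preprocessing scenarios).
#'
#' @param metrics_a,metrics_b Equal-length numeric vectors of per-fold metric
#'   values (length >= 2).
#' @return Tibble with `t`, `df`, `p_value`, `mean_diff`. With zero variance
#'   of the differences the statistic is undefined and reported as `NA`.
#' @export
paired_compare <- function(metrics_a, metrics_b) {
  if (length(metrics_a) != length(metrics_b) || length(metrics_a) < 2L) {
    abort("Need equal-length paired vectors with at least 2 folds.")
  }
  d <- metrics_a - metrics_b
  if (all(d == 0)) {
    # identical folds: no effect, t = 0, p = 1
    return(tibble(t = 0, df = length(d) - 1L, p_value = 1, mean_diff = 0))
  }
  # (near-)constant nonzero differences have an undefined statistic
  # (zero variance, nonzero mean); t.test refuses them
  tt <- tryCatch(t.test(metrics_a, metrics_b, paired = TRUE),
                 error = function(e) NULL)
  if (is.null(tt)) {
    return(tibble(t = NA_real_, df = length(d) - 1L, p_value = NA_real_,
                  mean_diff = mean(d)))
  }
  tibble(t = unname(tt$statistic), df = unname(tt$parameter),
         p_value = tt$p.value, mean_diff = unname(tt$estimate))
}
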