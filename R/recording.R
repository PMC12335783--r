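#' Construct an EOG recording
#'
#' Bundles one channel's amplitude series with its sampling rate and per-shot
#' Quiet Eye (QE) annotations. Sample `i` (1-based) covers the time interval
#' `[(i-1)/fs, i/fs)` seconds, so annotation times live on a continuous axis
#' starting at 0 at the first sample.
#'
#' @param samples Numeric amplitude series in microvolts.
#' @param fs Sampling rate in Hz (positive scalar).
#' @param channel `"horizontal"` or `"vertical"`.
#' @param participant_id Participant identifier string.
#' @param annotations Tibble/data frame with columns `shot_id` (integer),
#'   `t_on`, `t_off` (seconds from recording start). Must be chronologically
#'   ordered, non-overlapping, with `0 <= t_on < t_off <= length(samples)/fs`.
#' @param components Optional named list of additive signal components (used
#'   by the simulator to expose ground-truth gaze/drift/artifact/noise parts).
#'
#' @return An `eog_recording` object.
#' @export
eog_recording <- function(samples, fs, channel = c("horizontal", "vertical"),
                          participant_id = "P01",
                          annotations = empty_annotations(),
                          components = NULL) {
  channel <- match.arg(channel)
  samples <- as.numeric(samples)
  if (length(fs) != 1L || !is.finite(fs) || fs <= 0) {
    abort("`fs` must be a single positive number (Hz).")
  }
  if (length(samples) < 1L) abort("`samples` must contain at least one value.")
  annotations <- as_tibble(annotations)
  validate_annotations(annotations, n_samples = length(samples), fs = fs)
  structure(list(samples = samples, fs = fs, channel = channel,
                 participant_id = as.character(participant_id),
                 annotations = annotations, components = components),
            class = "eog_recording")
}

#' @rdname eog_recording
#' @export
empty_annotations <- function() {
  tibble(shot_id = integer(), t_on = numeric(), t_off = numeric())
}

validate_annotations <- function(annotations, n_samples, fs) {
  req <- c("shot_id", "t_on", "t_off")
  if (!all(req %in% names(annotations))) {
    abort("`annotations` needs columns shot_id, t_on, t_off.")
  }
  if (nrow(annotations) == 0L) return(invisible(annotations))
  with(annotations, {
    if (any(t_off <= t_on)) abort("Every annotation must satisfy t_off > t_on.")
    if (any(t_on < 0) || any(t_off > n_samples / fs)) {
      abort("Annotations must lie within [0, length(samples)/fs].")
    }
    if (is.unsorted(t_on, strictly = TRUE)) {
      abort("Annotations must be chronologically ordered.")
    }
    if (nrow(annotations) > 1L &&
        any(t_on[-1L] < t_off[-nrow(annotations)])) {
      abort("Annotations must not overlap.")
    }
  })
  invisible(annotations)
}

#' @export
print.eog_recording <- function(x, ...) {
  cat(sprintf("<eog_recording> %s channel, participant %s\n", x$channel,
              x$participant_id))
  cat(sprintf("  %d samples @ %g Hz (%.2f s), %d QE annotation(s)\n",
              length(x$samples), x$fs, length(x$samples) / x$fs,
              nrow(x$annotations)))
  invisible(x)
}

#' Recording duration in seconds
#' @param recording An `eog_recording`.
#' @return Length of the recording in seconds.
#' @export
recording_duration <- function(recording) {
  length(recording$samples) / recording$fs
}

#' @describeIn eog_recording Long-format view: one row per sample with
#'   `time` (s), `amplitude` (uV) and a logical `qe` flag from the
#'   annotations.
#' @param x An `eog_recording`.
#' @param ... Unused.
#' @export
tidy.eog_recording <- function(x, ...) {
  n <- length(x$samples)
  time <- (seq_len(n) - 1) / x$fs
  qe <- rep(FALSE, n)
  for (k in seq_len(nrow(x$annotations))) {
    qe[time >= x$annotations$t_on[k] & time < x$annotations$t_off[k]] <- TRUE
  }
  tibble(participant_id = x$participant_id, channel = x$channel,
         time = time, amplitude = x$samples, qe = qe)
}

#' @describeIn eog_recording Plot the amplitude trace with QE intervals
#'   shaded.
#' @param object An `eog_recording`.
#' @export
autoplot.eog_recording <- function(object, ...) {
  df <- tidy(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$amplitude)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time (s)", y = "amplitude (µV)",
                  title = sprintf("EOG, participant %s (%s)",
                                  object$participant_id, object$channel)) +
    ggplot2::theme_minimal()
  if (nrow(object$annotations) > 0L) {
    p <- p + ggplot2::geom_rect(
      data = object$annotations,
      ggplot2::aes(xmin = .data$t_on, xmax = .data$t_off,
                   ymin = -Inf, ymax = Inf),
      inherit.aes = FALSE, fill = "red", alpha = 0.15)
  }
  p
}

#' Write / read a recording as delimited text
#'
#' The signal file starts with `#`-prefixed header lines (`fs`, `channel`,
#' `participant_id`, and any extra provenance fields) followed by one
#' amplitude value per line. Annotations go to a companion tab-separated file
#' with columns `shot_id`, `t_on`, `t_off` (seconds, 6 decimal places).
#'
#' @param recording An `eog_recording`.
#' @param path Signal file path. The annotation file is `<path>.annotations.tsv`
#'   unless `annotation_path` is given.
#' @param annotation_path Optional explicit annotation file path.
#' @param extra_header Named character vector of extra provenance header
#'   fields.
#' @return `write_recording()` returns `path` invisibly; `read_recording()`
#'   returns an `eog_recording`.
#' @export
write_recording <- function(recording, path, annotation_path = NULL,
                            extra_header = NULL) {
  hdr <- c(fs = format(recording$fs), channel = recording$channel,
           participant_id = recording$participant_id, extra_header)
  lines <- c(sprintf("# %s: %s", names(hdr), unname(hdr)),
             sprintf("%.6f", recording$samples))
  writeLines(lines, path)
  ann_path <- annotation_path %||% paste0(path, ".annotations.tsv")
  ann <- recording$annotations
  utils::write.table(
    data.frame(shot_id = ann$shot_id,
               t_on = sprintf("%.6f", ann$t_on),
               t_off = sprintf("%.6f", ann$t_off)),
    ann_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path, annotation_path = NULL) {
  lines <- readLines(path)
  is_hdr <- startsWith(lines, "#")
  hdr_lines <- lines[is_hdr]
  kv <- regmatches(hdr_lines, regexec("^# ([^:]+): (.*)$", hdr_lines))
  hdr <- stats::setNames(vapply(kv, `[`, "", 3L), vapply(kv, `[`, "", 2L))
  samples <- as.numeric(lines[!is_hdr])
  ann_path <- annotation_path %||% paste0(path, ".annotations.tsv")
  ann <- if (file.exists(ann_path)) {
    as_tibble(utils::read.table(ann_path, header = TRUE, sep = "\t"))
  } else {
    empty_annotations()
  }
  ann$shot_id <- as.integer(ann$shot_id)
  eog_recording(samples, fs = as.numeric(hdr[["fs"]]),
                channel = hdr[["channel"]],
                participant_id = hdr[["participant_id"]],
                annotations = ann)
}
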