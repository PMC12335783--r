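# Windowing annotated recordings into fixed-length segments with per-sample
# binary QE masks, augmentation, and participant-grouped CV folds.
#
# Index convention (0-based in the arithmetic, 1-based in R storage): sample
# i covers time [i/fs, (i+1)/fs); intervals are half-open [on, off). The
# window is anchored at the QE onset: [t_on - pre_s, t_on + post_s), which at
# the 2.5 s / 6 s defaults and 200 Hz gives exactly 1700 samples.

#' Segmentation window settings
#'
#' @param pre_s Seconds of signal kept before each QE onset.
#' @param post_s Seconds kept after the onset (covering the QE event and its
#'   aftermath).
#' @return A `window_spec` object.
#' @export
window_spec <- function(pre_s = 2.5, post_s = 6.0) {
  if (pre_s <= 0 || post_s <= 0) abort("`pre_s` and `post_s` must be > 0.")
  structure(list(pre_s = pre_s, post_s = post_s), class = "window_spec")
}

#' @export
print.window_spec <- function(x, ...) {
  cat(sprintf("<window_spec> %g s before onset, %g s after\n",
              x$pre_s, x$post_s))
  invisible(x)
}

#' Window length in samples for a given sampling rate
#' @param win A [window_spec()].
#' @param fs Sampling rate in Hz.
#' @return Integer number of samples per segment.
#' @export
window_length <- function(win, fs) {
  as.integer(round((win$pre_s + win$post_s) * fs))
}

new_qe_segments <- function(x, mask, meta, fs, window) {
  stopifnot(nrow(x) == nrow(mask), nrow(x) == nrow(meta),
            ncol(x) == ncol(mask))
  structure(list(x = x, mask = mask, meta = meta, fs = fs, window = window),
            class = "qe_segments")
}

#' @export
print.qe_segments <- function(x, ...) {
  cat(sprintf("<qe_segments> %d segment(s) x %d samples @ %g Hz (%d augmented)\n",
              nrow(x$x), ncol(x$x), x$fs, sum(x$meta$augmented)))
  invisible(x)
}

#' Number of segments
#' @param segments A `qe_segments` container.
#' @return Integer count.
#' @export
n_segments <- function(segments) nrow(segments$x)

#' Cut an annotated recording into fixed-length QE segments
#'
#' One segment per annotation: samples on the half-open index window starting
#' at `round((t_on - pre_s) * fs)`, with a binary mask that is 1 exactly on
#' samples whose times fall in `[t_on, t_off)`. Annotations whose window
#' would cross either recording edge are skipped with a warning.
#'
#' @param recording An [eog_recording()].
#' @param win A [window_spec()].
#' @return A `qe_segments` container: sample matrix `x` (segments in rows),
#'   integer mask matrix `mask`, metadata tibble `meta` (`participant_id`,
#'   `shot_id`, `augmented`, `parent`), plus `fs` and the window spec. The
#'   number of skipped annotations is attached as attribute `"n_skipped"`.
#' @examples
#' rec <- simulate_recording(sim_config(seed = 2))
#' seg <- extract_segments(rec)
#' dim(seg$x)
#' @export
extract_segments <- function(recording, win = window_spec()) {
  fs <- recording$fs
  L <- window_length(win, fs)
  n <- length(recording$samples)
  ann <- recording$annotations
  rows_x <- list(); rows_m <- list(); keep <- logical(nrow(ann))
  for (k in seq_len(nrow(ann))) {
    s0 <- round((ann$t_on[k] - win$pre_s) * fs) # 0-based start index
    if (s0 < 0 || s0 + L > n) next
    idx0 <- s0:(s0 + L - 1L) # 0-based
    times <- idx0 / fs
    keep[k] <- TRUE
    rows_x[[length(rows_x) + 1L]] <- recording$samples[idx0 + 1L]
    rows_m[[length(rows_m) + 1L]] <-
      as.integer(times >= ann$t_on[k] - 1e-9 & times < ann$t_off[k] - 1e-9)
  }
  n_skip <- sum(!keep)
  if (n_skip > 0L) {
    warn(sprintf("%d annotation(s) skipped: window crosses a recording edge.",
                 n_skip))
  }
  x <- do.call(rbind, rows_x)
  m <- do.call(rbind, rows_m)
  if (is.null(x)) {
    x <- matrix(numeric(0), 0L, L)
    m <- matrix(integer(0), 0L, L)
  }
  meta <- tibble(participant_id = rep(recording$participant_id, sum(keep)),
                 shot_id = ann$shot_id[keep],
                 augmented = rep(FALSE, sum(keep)),
                 parent = NA_integer_)
  out <- new_qe_segments(x, m, meta, fs, win)
  attr(out, "n_skipped") <- n_skip
  out
}

#' Combine segment containers from several recordings
#' @param segment_list List of `qe_segments` with identical `fs` and window.
#' @return One pooled `qe_segments`.
#' @export
bind_segments <- function(segment_list) {
  segment_list <- segment_list[vapply(segment_list, n_segments, 0L) > 0L]
  if (length(segment_list) == 0L) abort("No non-empty segment containers.")
  fs <- segment_list[[1L]]$fs
  if (!all(vapply(segment_list, function(s) s$fs == fs, TRUE))) {
    abort("All containers must share one sampling rate.")
  }
  new_qe_segments(do.call(rbind, lapply(segment_list, `[[`, "x")),
                  do.call(rbind, lapply(segment_list, `[[`, "mask")),
                  dplyr::bind_rows(lapply(segment_list, `[[`, "meta")),
                  fs, segment_list[[1L]]$window)
}

#' Segment an entire cohort
#' @param recordings List of [eog_recording()]s.
#' @param win A [window_spec()].
#' @return Pooled `qe_segments` over all recordings.
#' @export
segment_cohort <- function(recordings, win = window_spec()) {
  bind_segments(lapply(recordings, extract_segments, win = win))
}

#' Augmentation settings
#'
#' @param max_shift_s Maximum temporal displacement in seconds (uniform
#'   integer sample shift in `[-max_shift_s * fs, +max_shift_s * fs]`,
#'   applied to samples and mask together).
#' @param noise_sd Gaussian noise standard deviation in microvolts added to
#'   the samples only. The default `NULL` uses 5% of each segment's sample
#'   standard deviation ("low-intensity" noise).
#' @param copies_per_segment Augmented copies generated per original segment.
#' @param seed Integer seed; augmentation is deterministic given the seed.
#' @return An `augment_spec` object.
#' @export
augment_spec <- function(max_shift_s = 0.25, noise_sd = NULL,
                         copies_per_segment = 2L, seed = 1L) {
  if (max_shift_s < 0) abort("`max_shift_s` must be >= 0.")
  if (!is.null(noise_sd) && noise_sd < 0) abort("`noise_sd` must be >= 0.")
  structure(list(max_shift_s = max_shift_s, noise_sd = noise_sd,
                 copies_per_segment = as.integer(copies_per_segment),
                 seed = as.integer(seed)),
            class = "augment_spec")
}

# circular roll of a vector by s (positive = later)
.roll <- function(v, s) {
  n <- length(v)
  s <- ((s %% n) + n) %% n
  if (s == 0) v else c(v[(n - s + 1L):n], v[1L:(n - s)])
}

#' Augment segments by time shifting and Gaussian noise
#'
#' Returns the original segments followed by `copies_per_segment` augmented
#' copies of each: samples and mask are rolled together by a uniform integer
#' shift, then Gaussian noise is added to the samples only, so the QE run
#' length (mask sum) is preserved exactly. Shifts that would push the mask's
#' 1-run across a segment edge are resampled (up to 20 tries), after which
#' that copy is skipped with a warning.
#'
#' @param segments A `qe_segments` container.
#' @param spec An [augment_spec()].
#' @return A `qe_segments` container; augmented rows have `augmented = TRUE`
#'   and `parent` pointing at the originating row.
#' @export
augment_segments <- function(segments, spec = augment_spec()) {
  if (n_segments(segments) == 0L) abort("`segments` is empty.")
  fs <- segments$fs
  L <- ncol(segments$x)
  max_shift <- round(spec$max_shift_s * fs)
  with_local_seed(spec$seed, {
    xs <- list(); ms <- list(); parent <- integer(0)
    n_fail <- 0L
    for (i in seq_len(n_segments(segments))) {
      xi <- segments$x[i, ]; mi <- segments$mask[i, ]
      has_run <- any(mi == 1L)
      run <- if (has_run) range(which(mi == 1L)) else c(1L, 0L)
      sd_i <- spec$noise_sd %||% (0.05 * sd(xi))
      for (cp in seq_len(spec$copies_per_segment)) {
        ok <- FALSE
        for (try in 1:20) {
          s <- if (max_shift > 0) sample(seq.int(-max_shift, max_shift), 1L) else 0L
          if (has_run && (run[1] + s < 1L || run[2] + s > L)) next
          ok <- TRUE
          break
        }
        if (!ok) { n_fail <- n_fail + 1L; next }
        xs[[length(xs) + 1L]] <- .roll(xi, s) +
          if (sd_i > 0) rnorm(L, 0, sd_i) else 0
        ms[[length(ms) + 1L]] <- .roll(mi, s)
        parent <- c(parent, i)
      }
    }
    if (n_fail > 0L) {
      warn(sprintf("%d augmented cop%s skipped: no admissible shift found.",
                   n_fail, if (n_fail == 1L) "y" else "ies"))
    }
    aug_meta <- segments$meta[parent, ]
    aug_meta$augmented <- TRUE
    aug_meta$parent <- parent
    new_qe_segments(rbind(segments$x, do.call(rbind, xs)),
                    rbind(segments$mask, do.call(rbind, ms)),
                    dplyr::bind_rows(segments$meta, aug_meta),
                    fs, segments$window)
  })
}

#' Participant-grouped cross-validation folds
#'
#' Splits segments into `k` test folds grouped by `participant_id`: no
#' participant ever spans train and test, which also forces augmented copies
#' into the same fold as their parent (they share a participant).
#'
#' @param segments A `qe_segments` container.
#' @param k Number of folds (>= 2).
#' @param seed Integer seed for the participant shuffle.
#' @return List of `k` lists with integer `train` and `test` row indices.
#'   The participant-to-fold assignment is attached as attribute
#'   `"assignment"`.
#' @export
make_folds <- function(segments, k = 5L, seed = 1L) {
  k <- as.integer(k)
  if (k < 2L) abort("`k` must be at least 2.")
  pid <- segments$meta$participant_id
  participants <- unique(pid)
  if (length(participants) < k) {
    abort(sprintf(paste0("Only %d participant group(s) for %d folds: use ",
                         "k <= %d."),
                  length(participants), k, length(participants)))
  }
  with_local_seed(seed, {
    shuffled <- sample(participants)
    fold_of <- stats::setNames(rep(seq_len(k), length.out = length(shuffled)),
                               shuffled)
    folds <- lapply(seq_len(k), function(f) {
      test <- which(as.vector(fold_of[pid]) == f)
      list(train = setdiff(seq_along(pid), test), test = test)
    })
    attr(folds, "assignment") <- tibble(participant_id = shuffled,
                                        fold = unname(fold_of[shuffled]))
    folds
  })
}

#' Write / read a segment container as delimited text
#'
#' Three files under `dir`: `segments_x.tsv` (one row per segment),
#' `segments_mask.tsv`, and `segments_meta.tsv` (participant, shot,
#' augmented, parent, plus `fs`, `pre_s`, `post_s` header comment).
#'
#' @param segments A `qe_segments`.
#' @param dir Output directory (created if needed).
#' @return `write_segments()` returns `dir` invisibly; `read_segments()`
#'   returns a `qe_segments`.
#' @export
write_segments <- function(segments, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(segments$x, file.path(dir, "segments_x.tsv"),
                     sep = "\t", row.names = FALSE, col.names = FALSE)
  utils::write.table(segments$mask, file.path(dir, "segments_mask.tsv"),
                     sep = "\t", row.names = FALSE, col.names = FALSE)
  meta_path <- file.path(dir, "segments_meta.tsv")
  hdr <- sprintf("# fs: %g\n# pre_s: %g\n# post_s: %g", segments$fs,
                 segments$window$pre_s, segments$window$post_s)
  writeLines(hdr, meta_path)
  suppressWarnings(
    utils::write.table(segments$meta, meta_path, sep = "\t",
                       row.names = FALSE, quote = FALSE, append = TRUE))
  invisible(dir)
}

#' @rdname write_segments
#' @export
read_segments <- function(dir) {
  x <- as.matrix(utils::read.table(file.path(dir, "segments_x.tsv"),
                                   sep = "\t"))
  m <- as.matrix(utils::read.table(file.path(dir, "segments_mask.tsv"),
                                   sep = "\t"))
  dimnames(x) <- dimnames(m) <- NULL
  meta_path <- file.path(dir, "segments_meta.tsv")
  lines <- readLines(meta_path)
  hdr_lines <- lines[startsWith(lines, "#")]
  kv <- regmatches(hdr_lines, regexec("^# ([^:]+): (.*)$", hdr_lines))
  hdr <- stats::setNames(as.numeric(vapply(kv, `[`, "", 3L)),
                         vapply(kv, `[`, "", 2L))
  meta <- as_tibble(utils::read.table(meta_path, header = TRUE, sep = "\t",
                                      comment.char = "#"))
  meta$parent <- as.integer(meta$parent)
  new_qe_segments(x, m, meta, hdr[["fs"]],
                  window_spec(hdr[["pre_s"]], hdr[["post_s"]]))
}
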