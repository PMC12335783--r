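# Cleaning stages for raw EOG: wavelet baseline-drift removal and Butterworth
# bandpass filtering, plus the scenario switch (A raw, B bandpass only,
# C baseline removal + bandpass) used to compare detector inputs.

#' Butterworth bandpass settings
#'
#' @param low_hz Lower passband edge in Hz. EOG content starts around 0.1 Hz;
#'   anything below is electrode drift.
#' @param high_hz Upper passband edge in Hz. EOG content is confined below
#'   about 20 Hz; higher bands are amplifier/muscle noise.
#' @param order Butterworth order (per pass). Order 4 gives >20 dB
#'   attenuation one octave beyond the 20 Hz edge at 200 Hz sampling.
#' @param zero_phase If `TRUE` (default) the filter runs forward-backward
#'   (`signal::filtfilt`), doubling the effective order and leaving event
#'   onsets/offsets undelayed -- important because QE timing is later scored
#'   to a 100 ms tolerance.
#' @return A `filter_spec` object.
#' @export
filter_spec <- function(low_hz = 0.1, high_hz = 20, order = 4L,
                        zero_phase = TRUE) {
  if (low_hz <= 0 || high_hz <= low_hz) {
    abort("Need 0 < low_hz < high_hz.")
  }
  if (order < 1L) abort("`order` must be >= 1.")
  structure(list(low_hz = low_hz, high_hz = high_hz, order = as.integer(order),
                 zero_phase = isTRUE(zero_phase)),
            class = "filter_spec")
}

#' @export
print.filter_spec <- function(x, ...) {
  cat(sprintf("<filter_spec> %g-%g Hz Butterworth, order %d, %s\n",
              x$low_hz, x$high_hz, x$order,
              if (x$zero_phase) "zero-phase" else "causal"))
  invisible(x)
}

#' Bandpass-filter an amplitude series
#'
#' Applies the Butterworth bandpass described by `spec`. With
#' `zero_phase = TRUE` the signal is filtered forward and backward so the
#' passband group delay is zero.
#'
#' @param signal Numeric amplitude series.
#' @param fs Sampling rate in Hz.
#' @param spec A [filter_spec()].
#' @return Filtered series of the same length.
#' @examples
#' fs <- 200
#' x <- sin(2 * pi * 5 * (0:999) / fs)
#' y <- bandpass_filter(x, fs)
#' @export
bandpass_filter <- function(signal, fs, spec = filter_spec()) {
  if (spec$high_hz >= fs / 2) {
    abort(sprintf("high_hz (%g) must be below the Nyquist frequency (%g).",
                  spec$high_hz, fs / 2))
  }
  bf <- signal::butter(spec$order, c(spec$low_hz, spec$high_hz) / (fs / 2),
                       type = "pass")
  x <- as.numeric(signal)
  if (spec$zero_phase) {
    as.numeric(signal::filtfilt(bf, x))
  } else {
    as.numeric(signal::filter(bf, x))
  }
}

#' Remove baseline drift via the deepest wavelet approximation
#'
#' Decomposes the signal to `spec$levels` levels, reconstructs the deepest
#' approximation band alone (all detail bands zeroed) to full signal length,
#' and subtracts it. At 10 levels and 200 Hz the approximation band lies
#' below ~0.1 Hz, so this removes electrode drift while leaving saccades and
#' fixation structure untouched.
#'
#' @inheritParams bandpass_filter
#' @param spec A [wavelet_spec()].
#' @return Drift-corrected series of the same length.
#' @export
remove_baseline <- function(signal, spec = wavelet_spec()) {
  dec <- decompose_signal(signal, spec)
  as.numeric(signal) - reconstruct_signal(dec, keep_details = FALSE)
}

#' Preprocessing scenarios
#'
#' `"A"` feeds the raw signal through untouched, `"B"` applies only the
#' Butterworth bandpass, and `"C"` removes the wavelet baseline first and
#' then applies the bandpass.
#'
#' @param recording An [eog_recording()].
#' @param scenario `"A"`, `"B"` or `"C"`.
#' @param wspec [wavelet_spec()] for scenario C.
#' @param fspec [filter_spec()] for scenarios B and C.
#' @return An [eog_recording()] with processed samples; annotations, sampling
#'   rate and identifiers are unchanged.
#' @examples
#' rec <- simulate_recording(sim_config(seed = 3))
#' clean <- apply_scenario(rec, "C")
#' @export
apply_scenario <- function(recording, scenario = c("C", "A", "B"),
                           wspec = wavelet_spec(), fspec = filter_spec()) {
  scenario <- match.arg(toupper(scenario), c("C", "A", "B"))
  x <- recording$samples
  y <- switch(scenario,
    A = x,
    B = bandpass_filter(x, recording$fs, fspec),
    C = bandpass_filter(remove_baseline(x, wspec), recording$fs, fspec))
  out <- recording
  out$samples <- y
  out$components <- NULL
  out
}

# Total power below `f_hz` from a raw periodogram; used to verify drift
# suppression in tests and reports.
low_freq_power <- function(signal, fs, f_hz = 0.1) {
  n <- length(signal)
  sp <- Mod(stats::fft(signal - mean(signal)))^2 / n
  freqs <- (seq_len(n) - 1) * fs / n
  sum(sp[freqs > 0 & freqs < f_hz])
}
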