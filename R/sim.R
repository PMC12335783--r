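# Synthetic single-channel EOG with ground-truth Quiet Eye annotations.
#
# The generative model is additive: gaze (piecewise fixation plateaus joined
# by short raised-cosine saccade ramps) + slow sinusoidal baseline drift +
# transient artifacts (blinks between shots, a release artifact at each QE
# offset) + white measurement noise. Each simulated shot follows the archery
# timeline: aiming-phase gaze shifts, a final saccade onto the target whose
# ramp ends exactly at the annotated QE onset, a stable plateau for the QE
# duration, and a release artifact at the annotated offset.

#' Simulation settings for synthetic EOG recordings
#'
#' Defaults emulate 200 Hz archery EOG: six shots per recording, QE durations
#' of a few hundred milliseconds to a few seconds, saccades of tens to
#' hundreds of microvolts, slow electrode drift well below the 0.1 Hz EOG
#' passband, occasional blinks between shots, and additive white noise.
#'
#' @param fs Sampling rate in Hz.
#' @param n_shots Shots (annotated QE events) per recording.
#' @param inter_shot_gap Seconds from one arrow release to the start of the
#'   next aiming phase.
#' @param qe_duration_range Two seconds: QE durations are drawn from a
#'   log-normal (median 1.5 s) clipped to this range.
#' @param saccade_amplitude_sd Standard deviation (microvolts) of fixation
#'   plateau levels; sets typical saccade step sizes.
#' @param drift_amplitude Scale of the baseline drift in microvolts: the
#'   peak amplitude for the sinusoidal model, the stationary standard
#'   deviation for the random-walk model.
#' @param drift_freq Fundamental drift frequency in Hz; must sit below the
#'   0.1 Hz bandpass low edge.
#' @param drift_model `"sinusoid"` (two slow sinusoids; smooth, narrowband,
#'   easy for a model to learn around) or `"stochastic"` (a band-limited
#'   Gaussian process synthesized from random-phase components below
#'   0.05 Hz: electrode wander whose offset and slope vary unpredictably
#'   from window to window, yet lies entirely below the 0.1 Hz edge that
#'   baseline removal targets).
#' @param blink_rate Blink events per minute, placed outside QE intervals.
#' @param noise_sd White-noise standard deviation in microvolts.
#' @param seed Integer seed; together with the other fields it fully
#'   determines the simulated recording.
#' @param pre_aim_s Aiming-phase length before each QE onset (seconds). Must
#'   exceed the 2.5 s segmentation look-back so windows fit.
#' @param tail_s Recording tail after the final release (seconds).
#' @param saccade_ramp_s Raised-cosine saccade ramp length (seconds); 20 ms
#'   is the shortest transition 200 Hz sampling can meaningfully resolve.
#' @param duration_s Optional fixed total recording length (seconds). When
#'   given, the shot layout must fit inside it (error otherwise) and the
#'   remainder is filled with idle gaze.
#' @param channel Recorded channel label.
#'
#' @return A `sim_config` object (named list).
#' @examples
#' cfg <- sim_config(seed = 7)
#' rec <- simulate_recording(cfg)
#' rec$annotations
#' @export
sim_config <- function(fs = 200, n_shots = 6L, inter_shot_gap = 4.5,
                       qe_duration_range = c(0.3, 5.0),
                       saccade_amplitude_sd = 120, drift_amplitude = 60,
                       drift_freq = 0.02, drift_model = c("sinusoid",
                                                          "stochastic"),
                       blink_rate = 4, noise_sd = 3,
                       seed = 1L, pre_aim_s = 3.5, tail_s = 6.0,
                       saccade_ramp_s = 0.02, duration_s = NULL,
                       channel = "horizontal") {
  drift_model <- match.arg(drift_model)
  if (fs <= 0) abort("`fs` must be positive.")
  if (n_shots < 1L) abort("`n_shots` must be at least 1.")
  if (length(qe_duration_range) != 2L ||
      qe_duration_range[1] <= 0 ||
      qe_duration_range[2] <= qe_duration_range[1]) {
    abort("`qe_duration_range` must be increasing positive (lo, hi) seconds.")
  }
  if (drift_freq >= 0.1) {
    abort("`drift_freq` must lie below the 0.1 Hz bandpass low edge.")
  }
  if (noise_sd < 0 || blink_rate < 0 || drift_amplitude < 0) {
    abort("`noise_sd`, `blink_rate` and `drift_amplitude` must be >= 0.")
  }
  structure(list(fs = fs, n_shots = as.integer(n_shots),
                 inter_shot_gap = inter_shot_gap,
                 qe_duration_range = qe_duration_range,
                 saccade_amplitude_sd = saccade_amplitude_sd,
                 drift_amplitude = drift_amplitude, drift_freq = drift_freq,
                 drift_model = drift_model,
                 blink_rate = blink_rate, noise_sd = noise_sd,
                 seed = as.integer(seed), pre_aim_s = pre_aim_s,
                 tail_s = tail_s, saccade_ramp_s = saccade_ramp_s,
                 duration_s = duration_s, channel = channel),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(paste0("<sim_config> fs=%g Hz, %d shots, QE %.1f-%.1f s, ",
                     "drift %g uV @ %g Hz, noise %g uV, seed %d\n"),
              x$fs, x$n_shots, x$qe_duration_range[1], x$qe_duration_range[2],
              x$drift_amplitude, x$drift_freq, x$noise_sd, x$seed))
  invisible(x)
}

# Evaluate `code` under `seed` without disturbing the caller's RNG stream.
with_local_seed <- function(seed, code) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

# Raised-cosine transition from l0 to l1 over k samples.
.ramp <- function(l0, l1, k) {
  u <- seq_len(k) / k
  l0 + (l1 - l0) * (1 - cos(pi * u)) / 2
}

# Write a smooth bump (positive lobe then scaled negative rebound) into `sig`.
.add_biphasic <- function(sig, fs, t0, width, amp, rebound = 0.3) {
  n <- length(sig)
  k1 <- max(3L, round(width * 0.7 * fs))
  k2 <- max(2L, round(width * 0.3 * fs))
  i0 <- round(t0 * fs) + 1L
  lobe <- c(amp * sin(pi * seq_len(k1) / (k1 + 1))^2,
            -rebound * amp * sin(pi * seq_len(k2) / (k2 + 1))^2)
  idx <- i0:(i0 + length(lobe) - 1L)
  keep <- idx >= 1L & idx <= n
  sig[idx[keep]] <- sig[idx[keep]] + lobe[keep]
  sig
}

#' Simulate one EOG recording with ground-truth QE annotations
#'
#' @param cfg A [sim_config()].
#' @param participant_id Participant identifier for the recording.
#' @param keep_components If `TRUE`, the returned recording carries a
#'   `components` list (`gaze`, `drift`, `artifact`, `noise`) that sums to
#'   `samples`; used for property checks on the generator.
#'
#' @return An [eog_recording()] with exactly `cfg$n_shots` annotations. The
#'   same `cfg` (including its seed) always yields bit-identical output.
#' @export
simulate_recording <- function(cfg = sim_config(), participant_id = "P01",
                               keep_components = FALSE) {
  with_local_seed(cfg$seed, {
    .simulate_recording_impl(cfg, participant_id, keep_components)
  })
}

.simulate_recording_impl <- function(cfg, participant_id, keep_components) {
  fs <- cfg$fs
  ramp_k <- max(2L, round(cfg$saccade_ramp_s * fs))
  lo <- cfg$qe_duration_range[1]; hi <- cfg$qe_duration_range[2]
  draw_duration <- function() {
    min(max(exp(rnorm(1, log(1.5), 0.45)), lo), hi)
  }
  # Plan the shot timeline first so the total length is known up front.
  t <- 0
  t_on <- t_off <- numeric(cfg$n_shots)
  aim_len <- rel_w <- numeric(cfg$n_shots)
  for (s in seq_len(cfg$n_shots)) {
    aim_len[s] <- cfg$pre_aim_s + runif(1, -0.2, 0.3)
    t_on[s] <- t + aim_len[s]
    t_off[s] <- t_on[s] + draw_duration()
    rel_w[s] <- runif(1, 0.10, 0.18)
    t <- t_off[s] + cfg$inter_shot_gap
  }
  total_s <- t_off[cfg$n_shots] + cfg$tail_s
  if (!is.null(cfg$duration_s)) {
    if (total_s > cfg$duration_s) {
      abort(sprintf(paste0("%d shot(s) need %.1f s but `duration_s` is ",
                           "%.1f s: reduce n_shots, inter_shot_gap or QE ",
                           "durations."),
                    cfg$n_shots, total_s, cfg$duration_s))
    }
    total_s <- cfg$duration_s
  }
  n <- ceiling(total_s * fs)

  # Gaze: sequence of (change time, new level) pairs, ramped transitions.
  lvl_sd <- cfg$saccade_amplitude_sd
  target_base <- rnorm(1, 0, lvl_sd / 2)
  changes_t <- numeric(0); changes_l <- numeric(0)
  level0 <- rnorm(1, 0, lvl_sd)
  last_level <- level0
  push <- function(tc, lv) {
    changes_t <<- c(changes_t, tc); changes_l <<- c(changes_l, lv)
    last_level <<- lv
  }
  for (s in seq_len(cfg$n_shots)) {
    aim_start <- t_on[s] - aim_len[s]
    # aiming-phase scanning: a renewal process of short fixations, the
    # normal 2-4 saccades/s of target alignment. The QE plateau stands out
    # as the one long quiet hold, which is how QE is defined.
    tt <- aim_start + runif(1, 0.05, 0.2)
    while (tt < t_on[s] - 0.35) {
      push(tt, rnorm(1, 0, lvl_sd))
      tt <- tt + runif(1, 0.25, 0.7)
    }
    # final saccade onto the target; ramp finishes exactly at t_on
    target <- target_base + rnorm(1, 0, 12)
    if (abs(target - last_level) < 0.5 * lvl_sd) {
      target <- target + sign(target - last_level + 1e-9) * 0.5 * lvl_sd
    }
    push(t_on[s] - ramp_k / fs, target)
    # leave the target shortly after the release artifact, then relax into
    # slower idle scanning during the inter-shot gap
    push(t_off[s] + rel_w[s] + 0.05, rnorm(1, 0, lvl_sd))
    gap_lo <- t_off[s] + rel_w[s] + 0.4
    gap_hi <- if (s < cfg$n_shots) t_on[s + 1] - aim_len[s + 1] else total_s - 0.5
    tt <- gap_lo + runif(1, 0.1, 0.4)
    while (tt < gap_hi - 0.3) {
      push(tt, rnorm(1, 0, lvl_sd))
      tt <- tt + runif(1, 0.5, 1.5)
    }
  }
  ord <- order(changes_t)
  changes_t <- changes_t[ord]; changes_l <- changes_l[ord]
  gaze <- rep(level0, n)
  cur <- level0
  for (k in seq_along(changes_t)) {
    i0 <- round(changes_t[k] * fs) + 1L
    if (i0 > n) break
    i1 <- min(i0 + ramp_k - 1L, n)
    gaze[i0:i1] <- .ramp(cur, changes_l[k], i1 - i0 + 1L)
    if (i1 < n) gaze[(i1 + 1L):n] <- changes_l[k]
    cur <- changes_l[k]
  }

  # Baseline drift.
  tv <- (seq_len(n) - 1) / fs
  drift <- if (cfg$drift_amplitude <= 0) {
    numeric(n)
  } else if ((cfg$drift_model %||% "sinusoid") == "sinusoid") {
    # two slow sinusoids with random phase: smooth, narrowband wander
    cfg$drift_amplitude * (0.7 * sin(2 * pi * cfg$drift_freq * tv +
                                       runif(1, 0, 2 * pi)) +
                             0.3 * sin(2 * pi * cfg$drift_freq / 2.7 * tv +
                                         runif(1, 0, 2 * pi)))
  } else {
    # band-limited electrode wander: random-phase components strictly below
    # 0.05 Hz, scaled to a stationary sd of drift_amplitude
    freqs <- seq(0.004, 0.05, by = 0.004)
    amps <- abs(rnorm(length(freqs))) / freqs # red-tilted spectrum
    phases <- runif(length(freqs), 0, 2 * pi)
    d <- rowSums(sapply(seq_along(freqs), function(j) {
      amps[j] * sin(2 * pi * freqs[j] * tv + phases[j])
    }))
    d * (cfg$drift_amplitude / sd(d))
  }

  # Artifacts: release transient at each offset, blinks between shots.
  artifact <- numeric(n)
  for (s in seq_len(cfg$n_shots)) {
    artifact <- .add_biphasic(artifact, fs, t_off[s], rel_w[s],
                              amp = runif(1, 140, 260), rebound = 0.45)
  }
  if (cfg$blink_rate > 0) {
    n_blink <- rpois(1, cfg$blink_rate * total_s / 60)
    placed <- 0L; tries <- 0L
    while (placed < n_blink && tries < 50L * n_blink) {
      tries <- tries + 1L
      bt <- runif(1, 0.5, total_s - 1)
      bw <- runif(1, 0.2, 0.4)
      clash <- any(bt + bw > t_on - 0.3 & bt < t_off + rel_w + 0.4)
      if (!clash) {
        artifact <- .add_biphasic(artifact, fs, bt, bw,
                                  amp = runif(1, 250, 400), rebound = 0.25)
        placed <- placed + 1L
      }
    }
  }

  noise <- if (cfg$noise_sd > 0) rnorm(n, 0, cfg$noise_sd) else numeric(n)

  ann <- tibble(shot_id = seq_len(cfg$n_shots), t_on = t_on, t_off = t_off)
  eog_recording(gaze + drift + artifact + noise, fs = fs,
                channel = cfg$channel, participant_id = participant_id,
                annotations = ann,
                components = if (keep_components) {
                  list(gaze = gaze, drift = drift, artifact = artifact,
                       noise = noise)
                })
}

#' Simulate a cohort of participants
#'
#' Each participant gets an independent recording with a derived seed
#' (`cfg$seed + participant index`), so the whole cohort is a pure function
#' of `cfg` and `n_participants`.
#'
#' @param cfg A [sim_config()]; its `seed` acts as the master seed.
#' @param n_participants Number of participants (>= 1).
#' @inheritParams simulate_recording
#' @return List of [eog_recording()]s with participant ids `"P01"`,
#'   `"P02"`, ...
#' @export
simulate_cohort <- function(cfg = sim_config(), n_participants = 10L,
                            keep_components = FALSE) {
  n_participants <- as.integer(n_participants)
  if (is.na(n_participants) || n_participants < 1L) {
    abort("`n_participants` must be at least 1.")
  }
  lapply(seq_len(n_participants), function(i) {
    cfg_i <- cfg
    cfg_i$seed <- cfg$seed + i
    simulate_recording(cfg_i, participant_id = sprintf("P%02d", i),
                       keep_components = keep_components)
  })
}
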