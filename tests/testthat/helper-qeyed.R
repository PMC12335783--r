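# Shared fixtures and independent oracles for the test-suite.

# A short, fast simulation: two shots, compact gaps.
tiny_sim <- function(seed = 1, ...) {
  sim_config(n_shots = 2L, inter_shot_gap = 3.5, tail_s = 6.0, seed = seed,
             ...)
}

# Independent run-length scanner for extract_events (simple explicit loop).
scan_events_loop <- function(mask, fs) {
  on <- off <- numeric(0)
  open <- FALSE
  for (i in seq_along(mask)) {
    if (!open && mask[i] == 1) {
      on <- c(on, (i - 1) / fs)
      open <- TRUE
    } else if (open && mask[i] == 0) {
      off <- c(off, (i - 1) / fs)
      open <- FALSE
    }
  }
  if (open) off <- c(off, length(mask) / fs)
  tibble::tibble(onset = on, offset = off)
}

# Exhaustive maximum-cardinality tolerance matching (recursive search).
# Independent oracle for the chronological greedy matcher.
max_matching_count <- function(pred, truth, tol) {
  n <- length(truth)
  best <- 0L
  recurse <- function(ti, used, count) {
    if (count + (n - ti + 1L) <= best) return() # bound
    if (ti > n) {
      best <<- max(best, count)
      return()
    }
    compatible <- which(!used & abs(pred - truth[ti]) <= tol + 1e-12)
    for (j in compatible) {
      used[j] <- TRUE
      recurse(ti + 1L, used, count + 1L)
      used[j] <- FALSE
    }
    recurse(ti + 1L, used, count) # leave truth ti unmatched
    invisible(NULL)
  }
  if (length(pred) == 0L || n == 0L) return(0L)
  recurse(1L, logical(length(pred)), 0L)
  best
}

# Random event-time instance for matcher property tests.
random_match_instance <- function(max_events = 5L, span = 10) {
  list(pred = sort(runif(sample.int(max_events + 1L, 1L) - 1L, 0, span)),
       truth = sort(runif(sample.int(max_events + 1L, 1L) - 1L, 0, span)))
}

# Small annotated recording with exactly controlled annotation times.
manual_recording <- function(n = 4000, fs = 200, t_on = 6, t_off = 8,
                             seed = 1) {
  withr::with_seed(seed, {
    eog_recording(rnorm(n), fs = fs,
                  annotations = tibble::tibble(shot_id = 1L, t_on = t_on,
                                               t_off = t_off))
  })
}

# Tiny segment set with short windows for fast detector fits.
tiny_segments <- function(seed = 1, n_participants = 2L,
                          win = window_spec(0.5, 1.0)) {
  recs <- simulate_cohort(tiny_sim(seed = seed), n_participants)
  segment_cohort(recs, win)
}
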