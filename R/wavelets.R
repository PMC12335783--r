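# Multilevel discrete wavelet decomposition (Mallat pyramid) with symmetric
# boundary extension, used to estimate and subtract slow baseline drift from
# EOG recordings. The deepest approximation band captures components far below
# the 0.1 Hz EOG passband.

# Scaling (lowpass decomposition) filters, Daubechies family. The highpass and
# reconstruction filters follow from the quadrature-mirror relations.
.wavelet_filters <- list(
  haar = c(0.7071067811865476, 0.7071067811865476),
  db1  = c(0.7071067811865476, 0.7071067811865476),
  db2  = c(-0.12940952255126037, 0.2241438680420134, 0.8365163037378079,
           0.48296291314453416),
  db4  = c(-0.010597401785069032, 0.0328830116668852, 0.030841381835560764,
           -0.18703481171909309, -0.027983769416859854, 0.6308807679298589,
           0.7148465705529157, 0.2303778133088965),
  db8  = c(-0.00011747678412476953, 0.0006754494064505693,
           -0.00039174037337694705, -0.004870352993451574,
           0.008746094047405777, 0.013981027917398282,
           -0.044088253930794755, -0.017369301001807547,
           0.12874742662047847, 0.0004724845739132828, -0.2840155429615469,
           -0.015829105256349306, 0.5853546836542067, 0.6756307362972898,
           0.31287159091429995, 0.05441584224310401)
)

.wavelet_bank <- function(mother) {
  dec_lo <- .wavelet_filters[[mother]]
  if (is.null(dec_lo)) {
    abort(paste0("Unknown mother wavelet '", mother, "'. Available: ",
                 paste(names(.wavelet_filters), collapse = ", ")))
  }
  len <- length(dec_lo)
  dec_hi <- rev(dec_lo) * rep(c(-1, 1), len / 2)
  list(dec_lo = dec_lo, dec_hi = dec_hi,
       rec_lo = rev(dec_lo), rec_hi = rev(dec_hi), length = len)
}

#' Wavelet decomposition settings
#'
#' Describes the multilevel discrete wavelet decomposition used for
#' baseline-drift estimation: the mother wavelet and the decomposition depth.
#' EOG baselines are removed by reconstructing the deepest approximation band
#' and subtracting it from the signal (see [remove_baseline()]).
#'
#' @param mother Mother wavelet name. One of `"haar"`/`"db1"`, `"db2"`,
#'   `"db4"`, `"db8"`. Daubechies-4 is the default: a standard choice for
#'   step-like biosignals whose shape resembles saccadic EOG transitions.
#' @param levels Decomposition depth. Ten levels at 200 Hz place the deepest
#'   approximation band below ~0.1 Hz, isolating electrode drift.
#'
#' @return A `wavelet_spec` object (a named list).
#' @examples
#' wavelet_spec()
#' wavelet_spec("db2", levels = 4)
#' @export
wavelet_spec <- function(mother = "db4", levels = 10L) {
  levels <- as.integer(levels)
  if (length(levels) != 1L || is.na(levels) || levels < 1L) {
    abort("`levels` must be a single integer >= 1.")
  }
  bank <- .wavelet_bank(mother) # validates the name
  structure(list(mother = mother, levels = levels, filter_length = bank$length),
            class = "wavelet_spec")
}

#' @export
print.wavelet_spec <- function(x, ...) {
  cat("<wavelet_spec> mother:", x$mother, " levels:", x$levels, "\n")
  invisible(x)
}

# Maximum feasible decomposition depth for a signal of length n: every
# analysis step needs at least one full filter length of signal.
dwt_max_level <- function(n, filter_length) {
  lev <- 0L
  while (n >= filter_length) {
    n <- (n + filter_length - 1L) %/% 2L
    lev <- lev + 1L
  }
  lev
}

# Symmetric (half-sample mirror) extension by `k` samples on both sides.
.sym_ext <- function(x, k) {
  n <- length(x)
  left <- rev(x[seq_len(min(k, n))])
  right <- rev(x[seq.int(n - min(k, n) + 1L, n)])
  while (length(left) < k) left <- c(rev(left), left)[seq_len(k)] # tiny-signal guard
  while (length(right) < k) right <- c(right, rev(right))[seq_len(k)]
  c(left, x, right)
}

# One analysis step: symmetric extension, convolution, dyadic downsampling.
.dwt_step <- function(x, bank) {
  len <- bank$length
  ext <- .sym_ext(x, len - 1L)
  nv <- length(ext) - len + 1L
  conv_valid <- function(h) {
    # y[n] = sum_j h[j] * ext[n + L - j]  (true convolution, valid part)
    y <- stats::filter(ext, h, method = "convolution", sides = 1L)
    as.numeric(y[seq.int(len, length(ext))])
  }
  lo <- conv_valid(bank$dec_lo)
  hi <- conv_valid(bank$dec_hi)
  keep <- seq.int(2L, nv, by = 2L)
  list(cA = lo[keep], cD = hi[keep])
}

# One synthesis step; inverse of .dwt_step. `n_out` is the pre-analysis length.
.idwt_step <- function(cA, cD, bank, n_out) {
  len <- bank$length
  n <- length(cA)
  up <- function(cc) {
    u <- numeric(2L * n)
    u[seq.int(1L, 2L * n, by = 2L)] <- cc
    u
  }
  conv_full <- function(u, h) {
    # full convolution: pad so stats::filter covers the leading partial sums
    x <- c(numeric(len - 1L), u, numeric(len - 1L))
    y <- stats::filter(x, h, method = "convolution", sides = 1L)
    as.numeric(y[seq.int(len, length(u) + 2L * (len - 1L))])
  }
  y <- conv_full(up(cA), bank$rec_lo) + conv_full(up(cD), bank$rec_hi)
  y[seq.int(len - 1L, len - 2L + n_out)]
}

#' Multilevel wavelet decomposition of an amplitude series
#'
#' Runs the discrete wavelet transform pyramid: at each level the current
#' approximation is split into a coarser approximation (`cA`, low-frequency)
#' and a detail band (`cD`, high-frequency). The original signal equals the
#' deepest approximation plus all detail bands, so [reconstruct_signal()]
#' inverts this decomposition exactly (to floating-point precision).
#'
#' @param signal Numeric amplitude series (microvolts).
#' @param spec A [wavelet_spec()].
#'
#' @return A `wavelet_decomposition` object: list with `approx` (the deepest
#'   approximation coefficients), `details` (list of detail coefficient
#'   vectors, level 1 = finest), `lengths` (pre-analysis lengths per level,
#'   needed for exact inversion), and `spec`.
#' @seealso [reconstruct_signal()], [remove_baseline()]
#' @examples
#' x <- sin(2 * pi * 5 * seq(0, 1, by = 1 / 200))
#' d <- decompose_signal(x, wavelet_spec(levels = 3))
#' max(abs(reconstruct_signal(d) - x))
#' @export
decompose_signal <- function(signal, spec = wavelet_spec()) {
  signal <- as.numeric(signal)
  bank <- .wavelet_bank(spec$mother)
  max_lev <- dwt_max_level(length(signal), bank$length)
  if (spec$levels > max_lev) {
    abort(paste0("Signal of length ", length(signal), " supports at most ",
                 max_lev, " decomposition level(s) with ", spec$mother,
                 " (filter length ", bank$length, "); requested ",
                 spec$levels, "."))
  }
  details <- vector("list", spec$levels)
  lengths <- integer(spec$levels)
  cur <- signal
  for (lev in seq_len(spec$levels)) {
    lengths[lev] <- length(cur)
    st <- .dwt_step(cur, bank)
    details[[lev]] <- st$cD
    cur <- st$cA
  }
  structure(list(approx = cur, details = details, lengths = lengths,
                 spec = spec),
            class = "wavelet_decomposition")
}

#' @export
print.wavelet_decomposition <- function(x, ...) {
  cat("<wavelet_decomposition>", x$spec$mother, "x", x$spec$levels,
      "levels; signal length", x$lengths[1L], "\n")
  invisible(x)
}

#' Invert a multilevel wavelet decomposition
#'
#' Reconstructs the original amplitude series from a
#' [decompose_signal()] result. With untouched coefficients the round trip is
#' exact to floating-point precision; zeroing detail bands before
#' reconstruction yields the corresponding smoothed (approximation-only)
#' signal at full length, which is how the drift estimate is produced.
#'
#' @param decomposition A `wavelet_decomposition`.
#' @param keep_details Logical: if `FALSE`, all detail bands are zeroed and
#'   the result is the deepest approximation band upsampled to the original
#'   signal length (the baseline-drift estimate).
#'
#' @return Numeric vector with the original signal length.
#' @export
reconstruct_signal <- function(decomposition, keep_details = TRUE) {
  bank <- .wavelet_bank(decomposition$spec$mother)
  levels <- decomposition$spec$levels
  cur <- decomposition$approx
  for (lev in rev(seq_len(levels))) {
    cD <- decomposition$details[[lev]]
    if (!keep_details) cD <- numeric(length(cD))
    cur <- .idwt_step(cur, cD, bank, decomposition$lengths[lev])
  }
  cur
}
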