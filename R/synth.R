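#' Consciousness states and their BIS ranges
#'
#' The four discrete depth-of-anaesthesia classes used throughout the
#' package, each tied to a bin of the 0-100 BIS-like consciousness index:
#' fully awake (80-100), semi awake (60-80), operative (40-60) and very low
#' brain activity (0-40). Bins are half-open `[low, high)` except AWAKE,
#' which includes 100, so the four bins are disjoint and cover `[0, 100]`.
#'
#' @return A data.frame with columns `label`, `bis_low`, `bis_high` ordered
#'   from most awake to deepest.
#' @export
#' @examples
#' doa_states()
doa_states <- function() {
  data.frame(
    label    = c("AWAKE", "SEMI_AWAKE", "OPERATIVE", "VERY_LOW"),
    bis_low  = c(80, 60, 40, 0),
    bis_high = c(100, 80, 60, 40),
    stringsAsFactors = FALSE
  )
}

doa_state_labels <- function() doa_states()$label

#' State spectrum descriptor for the synthetic EEG generator
#'
#' Describes the stationary statistics of one consciousness state's EEG:
#' which frequency bands carry power, the overall RMS amplitude, and (for
#' burst suppression) the suppressed-time fraction and burst rate.
#'
#' @param band_powers matrix or data.frame with columns `low`, `high`
#'   (Hz) and `power` (relative, must sum to 1).
#' @param rms_amplitude target RMS amplitude in microvolts of the active
#'   (non-suppressed) signal.
#' @param suppression_ratio fraction of time in iso-electric suppression,
#'   in `[0, 1]`; only nonzero for the deepest state.
#' @param burst_rate burst-suppression cycles per minute (ignored when
#'   `suppression_ratio == 0`).
#' @return An object of class `state_spectrum`.
#' @export
state_spectrum <- function(band_powers, rms_amplitude,
                           suppression_ratio = 0, burst_rate = 6) {
  bp <- as.data.frame(band_powers)
  names(bp) <- c("low", "high", "power")
  if (any(bp$low <= 0) || any(bp$high <= bp$low))
    stop("band edges must satisfy 0 < low < high", call. = FALSE)
  if (abs(sum(bp$power) - 1) > 1e-8)
    stop("relative band powers must sum to 1", call. = FALSE)
  stopifnot_scalar_pos(rms_amplitude, "rms_amplitude")
  if (suppression_ratio < 0 || suppression_ratio > 1)
    stop("`suppression_ratio` must lie in [0, 1]", call. = FALSE)
  structure(list(band_powers = bp, rms_amplitude = rms_amplitude,
                 suppression_ratio = suppression_ratio,
                 burst_rate = burst_rate),
            class = "state_spectrum")
}

#' Default per-state spectra
#'
#' Engineering defaults chosen to reproduce the qualitative
#' neurophysiology of increasing anaesthetic depth: low-amplitude
#' broadband beta when awake, growing theta/alpha at moderate sedation,
#' high-amplitude slow-delta plus alpha at operative depth
#' (propofol-like anteriorisation), and burst suppression at the deepest
#' level. Amplitudes rise and median frequency falls with depth.
#'
#' @return Named list of [state_spectrum()] objects, one per state label.
#' @export
default_state_spectra <- function() {
  list(
    AWAKE = state_spectrum(
      rbind(c(8, 13, 0.30), c(13, 30, 0.60), c(30, 45, 0.10)),
      rms_amplitude = 10),
    SEMI_AWAKE = state_spectrum(
      rbind(c(4, 8, 0.35), c(8, 13, 0.45), c(13, 30, 0.20)),
      rms_amplitude = 20),
    OPERATIVE = state_spectrum(
      rbind(c(0.5, 4, 0.55), c(4, 8, 0.15), c(8, 13, 0.30)),
      rms_amplitude = 40),
    VERY_LOW = state_spectrum(
      rbind(c(0.5, 4, 0.60), c(4, 8, 0.40)),
      rms_amplitude = 45, suppression_ratio = 0.5, burst_rate = 6)
  )
}

# Band-limited Gaussian noise: white noise shaped in the frequency domain
# by raised-cosine-edged band masks, then rescaled per band so relative
# powers hold. Returns a zero-mean series with unit variance.
band_noise <- function(n, fs, band_powers) {
  e <- rnorm(n)
  E <- fft(e)
  freq <- (seq_len(n) - 1) / n * fs
  freq <- pmin(freq, fs - freq)          # two-sided -> folded frequency
  out <- numeric(n)
  for (b in seq_len(nrow(band_powers))) {
    lo <- band_powers$low[b]; hi <- band_powers$high[b]
    w <- 0.1 * (hi - lo)                 # transition width
    mask <- rep(0, n)
    core <- freq >= lo & freq <= hi
    mask[core] <- 1
    rise <- freq > lo - w & freq < lo
    mask[rise] <- 0.5 * (1 + cos(pi * (lo - freq[rise]) / w))
    fall <- freq > hi & freq < hi + w
    mask[fall] <- 0.5 * (1 + cos(pi * (freq[fall] - hi) / w))
    comp <- Re(fft(E * mask, inverse = TRUE)) / n
    s <- sd(comp)
    if (s > 0) out <- out + sqrt(band_powers$power[b]) * comp / s
  }
  s <- sd(out)
  if (s > 0) out / s else out
}

# Alternating burst/suppression activity mask from a two-state renewal
# process. Gamma dwell times (shape 4) give regular-ish cycling; mean
# dwells derive from burst_rate (cycles/min) and the suppression ratio.
suppression_mask <- function(n, fs, suppression_ratio, burst_rate) {
  if (suppression_ratio <= 0) return(rep(1, n))
  if (suppression_ratio >= 1) return(rep(0, n))
  cycle <- 60 / burst_rate
  mean_supp <- cycle * suppression_ratio
  mean_burst <- cycle * (1 - suppression_ratio)
  mask <- numeric(0)
  in_burst <- runif(1) > suppression_ratio
  shape <- 4
  while (length(mask) < n) {
    mu <- if (in_burst) mean_burst else mean_supp
    dwell <- stats::rgamma(1, shape = shape, rate = shape / mu)
    k <- max(1L, round(dwell * fs))
    mask <- c(mask, rep(if (in_burst) 1 else 0, k))
    in_burst <- !in_burst
  }
  mask[seq_len(n)]
}

#' Simulate one consciousness-state EEG epoch
#'
#' Generates `n_samples` of synthetic EEG (microvolts) whose power
#' spectral density concentrates in the bands of `spectrum`. For states
#' with `suppression_ratio > 0` the series alternates bursts of
#' band-limited activity with near-iso-electric suppression (residual
#' 1.5 uV RMS noise floor), switching via a two-state renewal process.
#' Output is a pure function of the arguments including `seed`.
#'
#' @param state one of `"AWAKE"`, `"SEMI_AWAKE"`, `"OPERATIVE"`,
#'   `"VERY_LOW"`.
#' @param spectrum a [state_spectrum()]; default taken from
#'   [default_state_spectra()] for `state`.
#' @param n_samples number of samples (must be >= `fs`).
#' @param fs sampling rate in Hz (default 128).
#' @param seed integer RNG seed.
#' @return Numeric vector of length `n_samples` (microvolts).
#' @export
#' @examples
#' x <- simulate_state_epoch("AWAKE", n_samples = 1280, seed = 1)
#' sd(x)
simulate_state_epoch <- function(state, spectrum = NULL, n_samples,
                                 fs = 128, seed) {
  state <- match.arg(state, doa_state_labels())
  stopifnot_scalar_pos(fs, "fs")
  if (!is.numeric(n_samples) || n_samples < fs)
    stop("`n_samples` must be a positive count >= fs", call. = FALSE)
  n_samples <- as.integer(n_samples)
  if (is.null(spectrum)) spectrum <- default_state_spectra()[[state]]
  with_seed(seed, {
    x <- band_noise(n_samples, fs, spectrum$band_powers) *
      spectrum$rms_amplitude
    if (spectrum$suppression_ratio > 0) {
      mask <- suppression_mask(n_samples, fs, spectrum$suppression_ratio,
                               spectrum$burst_rate)
      # soften edges over ~60 ms so bursts wax/wane rather than gate
      k <- max(1L, round(0.06 * fs))
      padded <- c(rep(mask[1], k), mask, rep(mask[n_samples], k))
      sm <- stats::filter(padded, rep(1 / k, k), sides = 2)
      mask <- as.numeric(sm[(k + 1):(k + n_samples)])
      floor_noise <- rnorm(n_samples, sd = 1.5)
      x <- x * mask + floor_noise
    }
    x
  })
}

#' Simulate a full sedation session (EEG plus BIS-like trace)
#'
#' Concatenates per-state epochs into one recording and draws a
#' BIS-like index every 5 s, uniform within the active state's BIS bin,
#' so binning the trace recovers the generating state.
#'
#' @param states character vector of state labels, one per segment.
#' @param durations numeric vector of segment durations in seconds
#'   (recycled to `length(states)`); must be positive.
#' @param fs sampling rate in Hz.
#' @param seed integer master seed; per-segment child seeds derive from it.
#' @param subject_id identifier string carried in the record.
#' @param spectra named list of [state_spectrum()] overrides; defaults to
#'   [default_state_spectra()].
#' @return An `eeg_record`: list with `signal` (uV), `fs`, `bis_trace`
#'   (one value per 5 s), `subject_id`, `seed`, and `state_spans`
#'   (per-segment bookkeeping).
#' @export
#' @examples
#' rec <- simulate_session(c("AWAKE", "VERY_LOW"), durations = 20, seed = 1)
#' length(rec$signal); rec$bis_trace
simulate_session <- function(states, durations, fs = 128, seed,
                             subject_id = "synthetic",
                             spectra = default_state_spectra()) {
  if (length(states) == 0) stop("empty state sequence", call. = FALSE)
  states <- vapply(states, function(s) match.arg(s, doa_state_labels()), "")
  durations <- rep_len(as.numeric(durations), length(states))
  if (any(!is.finite(durations)) || any(durations <= 0))
    stop("durations must be positive", call. = FALSE)
  stopifnot_scalar_pos(fs, "fs")

  st <- doa_states()
  sig <- vector("list", length(states))
  spans <- data.frame(label = states, start = NA_integer_, end = NA_integer_)
  pos <- 0L
  for (i in seq_along(states)) {
    n_i <- as.integer(round(durations[i] * fs))
    sig[[i]] <- simulate_state_epoch(states[i], spectra[[states[i]]],
                                     n_samples = n_i, fs = fs,
                                     seed = child_seed(seed, i))
    spans$start[i] <- pos + 1L
    spans$end[i] <- pos + n_i
    pos <- pos + n_i
  }
  signal <- unlist(sig, use.names = FALSE)

  block <- as.integer(5 * fs)
  n_bis <- length(signal) %/% block
  bis <- numeric(n_bis)
  bis_seed <- child_seed(seed, length(states) + 1L)
  with_seed(bis_seed, {
    for (b in seq_len(n_bis)) {
      # a BIS value labels the preceding 5 s of signal
      last <- b * block
      seg <- which(spans$start <= last & spans$end >= last)[1]
      row <- match(states[seg], st$label)
      bis[b] <- runif(1, st$bis_low[row], st$bis_high[row])
    }
  })

  structure(list(signal = signal, fs = fs, bis_trace = bis,
                 subject_id = subject_id, seed = seed,
                 state_spans = spans),
            class = "eeg_record")
}

#' @export
print.eeg_record <- function(x, ...) {
  cat(sprintf("<eeg_record> subject=%s  fs=%g Hz  %d samples (%.1f s)  %d BIS values\n",
              x$subject_id, x$fs, length(x$signal),
              length(x$signal) / x$fs, length(x$bis_trace)))
  invisible(x)
}
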