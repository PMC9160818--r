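#' NA-MEMD configuration
#'
#' Parameters of the noise-assisted multivariate empirical mode
#' decomposition. Defaults follow the study protocol: a 4-channel
#' multivariate input (the EEG plus 3 independent white-noise
#' channels), 8 projection directions (twice the channel count),
#' sifting stop vector `[0.075, 0.75, 0.075]`, and noise intensity 1
#' (noise SD equals the signal SD).
#'
#' @param n_channels total multichannel width (signal + noise).
#' @param n_directions projection directions on the hypersphere;
#'   defaults to `2 * n_channels`.
#' @param stop_vector three-parameter sifting stop criterion
#'   `(sd, sd2, tol)`: sifting stops once the envelope-mean amplitude
#'   ratio is below `sd` on all but a `tol` fraction of samples and
#'   below `sd2` everywhere.
#' @param noise_intensity noise channel SD relative to the signal SD.
#' @param seed integer seed for the noise channels.
#' @param max_sift cap on sifting iterations per mode (termination
#'   guarantee).
#' @param max_imf cap on extracted modes.
#' @return A `memd_config` list.
#' @export
memd_config <- function(n_channels = 4, n_directions = 2 * n_channels,
                        stop_vector = c(0.075, 0.75, 0.075),
                        noise_intensity = 1, seed = 1,
                        max_sift = 100, max_imf = 30) {
  stopifnot(n_channels >= 2, n_directions >= 2,
            length(stop_vector) == 3, all(stop_vector > 0),
            noise_intensity > 0, max_sift >= 1)
  structure(list(n_channels = as.integer(n_channels),
                 n_directions = as.integer(n_directions),
                 stop_vector = stop_vector,
                 noise_intensity = noise_intensity, seed = seed,
                 max_sift = as.integer(max_sift),
                 max_imf = as.integer(max_imf)),
            class = "memd_config")
}

# Low-discrepancy direction set: Hammersley points in the unit cube
# mapped to the (p-1)-sphere via the inverse-normal transform, so the
# directions spread quasi-uniformly over the whole sphere.
hammersley_directions <- function(k, p) {
  radical_inverse <- function(i, base) {
    f <- 1 / base; r <- 0
    while (i > 0) {
      r <- r + f * (i %% base)
      i <- i %/% base
      f <- f / base
    }
    r
  }
  primes <- c(2, 3, 5, 7, 11, 13, 17, 19, 23, 29, 31, 37)
  u <- matrix(0, k, p)
  u[, 1] <- (seq_len(k) - 0.5) / k
  for (j in 2:p)
    u[, j] <- vapply(seq_len(k), radical_inverse, 0.0,
                     base = primes[j - 1])
  z <- stats::qnorm(pmin(pmax(u, 1e-12), 1 - 1e-12))
  z / sqrt(rowSums(z^2))
}

# strict local maxima / minima index sets
extrema_idx <- function(x) {
  n <- length(x)
  if (n < 3) return(list(max = integer(0), min = integer(0)))
  mid <- x[2:(n - 1)]
  list(max = which(mid > x[1:(n - 2)] & mid > x[3:n]) + 1L,
       min = which(mid < x[1:(n - 2)] & mid < x[3:n]) + 1L)
}

# Cubic-spline envelope of multichannel data through the samples at
# `idx`, with up to two extrema mirrored beyond each end to tame
# boundary swings. Returns an n x p matrix, or NULL if idx is too small.
envelope_through <- function(X, idx, n) {
  if (length(idx) < 3) return(NULL)
  k <- min(2L, length(idx))
  tl <- 2 - rev(idx[seq_len(k)])        # mirror about t = 1
  tr <- 2 * n - rev(rev(idx)[seq_len(k)])  # mirror about t = n
  tt <- c(tl, idx, tr)
  rows <- c(rev(idx[seq_len(k)]), idx, rev(rev(idx)[seq_len(k)]))
  apply(X[rows, , drop = FALSE], 2, function(v)
    stats::spline(tt, v, xout = seq_len(n), method = "fmm")$y)
}

# One multivariate envelope-mean pass: project onto each direction,
# interpolate the multichannel signal at the projection's maxima and
# minima, and average the (max+min)/2 envelopes over directions.
# Returns the mean envelope, the mean envelope amplitude, and how many
# directions still carried enough extrema.
envelope_mean <- function(X, dirs) {
  n <- nrow(X); p <- ncol(X); K <- nrow(dirs)
  m <- matrix(0, n, p)
  amp <- numeric(n)
  used <- 0L
  for (j in seq_len(K)) {
    q <- as.numeric(X %*% dirs[j, ])
    ex <- extrema_idx(q)
    e_max <- envelope_through(X, ex$max, n)
    e_min <- envelope_through(X, ex$min, n)
    if (is.null(e_max) || is.null(e_min)) next
    m <- m + (e_max + e_min) / 2
    amp <- amp + sqrt(rowSums((e_max - e_min)^2)) / 2
    used <- used + 1L
  }
  if (used == 0) return(NULL)
  list(mean = m / used, amp = amp / used, used = used)
}

#' Multivariate empirical mode decomposition
#'
#' Joint sifting of an n-by-p multichannel series: the signal is
#' projected onto quasi-uniform hypersphere directions, envelopes are
#' interpolated through the projection extrema, and their average is
#' subtracted until the three-parameter stop criterion is met. All
#' channels receive the same number of aligned intrinsic mode
#' functions; summing a channel's modes plus its residue reconstructs
#' the channel exactly (telescoping identity of sifting).
#'
#' @param x numeric matrix, one column per channel (>= 2 columns, >= 4
#'   rows).
#' @param n_directions projection count (default twice the channel
#'   count).
#' @param stop_vector,max_sift,max_imf see [memd_config()].
#' @return List of one `imf_set` per channel: `imfs` (list of series,
#'   index 1 = highest frequency), `residue`, `channel_role`.
#' @export
memd <- function(x, n_directions = 2 * ncol(x),
                 stop_vector = c(0.075, 0.75, 0.075),
                 max_sift = 100, max_imf = 30) {
  x <- as.matrix(x)
  n <- nrow(x); p <- ncol(x)
  if (p < 2) stop("need >= 2 channels", call. = FALSE)
  if (n < 4) stop("need >= 4 samples", call. = FALSE)
  dirs <- hammersley_directions(n_directions, p)
  sd_ <- stop_vector[1]; sd2 <- stop_vector[2]; tol <- stop_vector[3]

  R <- x
  imfs <- list()
  while (length(imfs) < max_imf) {
    env <- envelope_mean(R, dirs)
    if (is.null(env)) break          # residue carries too few oscillations
    h <- R
    for (it in seq_len(max_sift)) {
      if (it > 1) {
        env <- envelope_mean(h, dirs)
        if (is.null(env)) break
      }
      sx <- sqrt(rowSums(env$mean^2)) / pmax(env$amp, .Machine$double.eps)
      if (mean(sx > sd_) <= tol && !any(sx > sd2)) break
      h <- h - env$mean
    }
    imfs[[length(imfs) + 1L]] <- h
    R <- R - h
  }

  lapply(seq_len(p), function(ch) {
    structure(list(
      imfs = lapply(imfs, function(m) m[, ch]),
      residue = R[, ch],
      channel_role = if (ch == 1) "signal" else "noise"),
      class = "imf_set")
  })
}

#' @export
print.imf_set <- function(x, ...) {
  cat("<imf_set>", length(x$imfs), "IMFs, residue length",
      length(x$residue), sprintf("(%s channel)\n", x$channel_role))
  invisible(x)
}

#' Noise-assisted MEMD of a single-channel EEG
#'
#' Stacks the signal with `n_channels - 1` independent white-noise
#' channels (SD equal to `noise_intensity` times the signal SD), runs
#' the multivariate decomposition, and returns the signal channel's
#' modes. The noise channels stabilise mode alignment and mitigate mode
#' mixing; they are discarded. Deterministic under a fixed
#' `config$seed`.
#'
#' @param x numeric series (uV), length >= 4.
#' @param config a [memd_config()].
#' @return The signal channel's `imf_set`.
#' @export
#' @examples
#' x <- simulate_state_epoch("OPERATIVE", n_samples = 640, seed = 4)
#' s <- na_memd(x, memd_config(seed = 7))
#' length(s$imfs)
na_memd <- function(x, config = memd_config()) {
  stopifnot(inherits(config, "memd_config"))
  if (length(x) < 4) stop("signal too short (need >= 4 samples)",
                          call. = FALSE)
  s <- stats::sd(x)
  noise_sd <- config$noise_intensity * if (s > 0) s else 1
  noise <- with_seed(config$seed, matrix(
    rnorm(length(x) * (config$n_channels - 1), sd = noise_sd),
    ncol = config$n_channels - 1))
  out <- memd(cbind(x, noise), n_directions = config$n_directions,
              stop_vector = config$stop_vector,
              max_sift = config$max_sift, max_imf = config$max_imf)
  out[[1]]
}

#' Select modes from a decomposition
#'
#' Returns the requested intrinsic mode functions in order. Modes 2 and
#' 3 are the package default for the EEG feature routes.
#'
#' @param imfset an `imf_set`.
#' @param indices mode indices (default `c(2, 3)`).
#' @return List of numeric series, one per requested index.
#' @export
select_imfs <- function(imfset, indices = c(2, 3)) {
  stopifnot(inherits(imfset, "imf_set"))
  avail <- length(imfset$imfs)
  if (any(indices < 1) || any(indices > avail))
    stop(sprintf("requested IMF(s) %s but only %d available",
                 paste(indices[indices > avail | indices < 1],
                       collapse = ", "), avail), call. = FALSE)
  imfset$imfs[indices]
}
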