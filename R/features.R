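#' Feature-extraction parameters
#'
#' Parameters for the handcrafted feature set. Defaults follow the study
#' protocol: a 1 uV threshold wherever a threshold is needed (zero
#' crossings, peak counting), a 4th-order autoregressive fit, sample
#' entropy with template length `m = 2` and tolerance `r = 0.2` times
#' the series SD, Higuchi fractal dimension over `k = 1..10`, and DFA
#' boxes log-spaced between 4 and N/4 with order-1 detrending.
#'
#' @param threshold amplitude threshold in microvolts.
#' @param ar_order autoregressive model order.
#' @param sampen_m sample-entropy template length.
#' @param sampen_r sample-entropy tolerance as a fraction of the SD.
#' @param higuchi_k maximum Higuchi delay.
#' @param dfa_box_range length-2 integer vector `(min, max)` of DFA box
#'   sizes; `NA` max means N/4 at call time.
#' @param sampen_cap_policy how to handle undefined sample entropy (no
#'   extending template matches): `"cap"` substitutes `log(B) + log(2)`
#'   with a warning; `"error"` raises.
#' @return A `feature_params` list.
#' @export
feature_params <- function(threshold = 1, ar_order = 4, sampen_m = 2,
                           sampen_r = 0.2, higuchi_k = 10,
                           dfa_box_range = c(4, NA),
                           sampen_cap_policy = c("cap", "error")) {
  stopifnot(threshold > 0, ar_order >= 1, sampen_m >= 1,
            sampen_r > 0, sampen_r <= 1, higuchi_k >= 2)
  structure(list(threshold = threshold, ar_order = as.integer(ar_order),
                 sampen_m = as.integer(sampen_m), sampen_r = sampen_r,
                 higuchi_k = as.integer(higuchi_k),
                 dfa_box_range = dfa_box_range,
                 sampen_cap_policy = match.arg(sampen_cap_policy)),
            class = "feature_params")
}

#' @rdname feature_params
#' @export
feature_names <- function() {
  c("MAV", "WL", "ZC", "RMS", "AR1", "AR2", "AR3", "AR4",
    "NPEAKS", "SSI", "VAR", "MAXCEPS", "MDF",
    "SAMPEN", "MFL", "HFD", "DFA")
}

#' Time-domain (linear) features
#'
#' Mean absolute value, waveform length, thresholded zero crossings,
#' root mean square, the four coefficients of an order-4 Burg
#' autoregressive fit, thresholded peak count, simple squared integral
#' and sample variance.
#'
#' @param x numeric series (microvolts).
#' @param params a [feature_params()].
#' @return Named numeric vector of 11 values.
#' @export
linear_features <- function(x, params = feature_params()) {
  n <- length(x)
  if (n < params$ar_order + 1)
    stop("series too short for linear features (need > ar_order samples)",
         call. = FALSE)
  thr <- params$threshold
  dx <- diff(x)
  sign_change <- x[-n] * x[-1] < 0
  above <- abs(x[-n]) > thr & abs(x[-1]) > thr
  zc <- sum(sign_change & above)
  if (n >= 3) {
    mid <- x[2:(n - 1)]
    peaks <- sum(mid > x[1:(n - 2)] & mid > x[3:n] & mid > thr)
  } else peaks <- 0L
  ar <- tryCatch(
    stats::ar.burg(x, aic = FALSE, order.max = params$ar_order,
                   demean = TRUE)$ar,
    error = function(e) stop("AR fit failed: ", conditionMessage(e),
                             call. = FALSE))
  ar <- c(ar, rep(0, params$ar_order))[seq_len(params$ar_order)]
  c(MAV = mean(abs(x)), WL = sum(abs(dx)), ZC = zc,
    RMS = sqrt(mean(x^2)),
    stats::setNames(ar, paste0("AR", seq_len(params$ar_order))),
    NPEAKS = peaks, SSI = sum(x^2), VAR = stats::var(x))
}

#' Frequency features: maximum cepstrum coefficient and median frequency
#'
#' `MAXCEPS` is the maximum of the real cepstrum excluding the zeroth
#' quefrency (a trivial energy proxy). `MDF` is the frequency that
#' splits the periodogram power into equal halves.
#'
#' @param x numeric series.
#' @param fs sampling rate in Hz.
#' @return Named numeric vector `(MAXCEPS, MDF)`.
#' @export
frequency_features <- function(x, fs = 128) {
  n <- length(x)
  if (n < 8) stop("series too short for frequency features", call. = FALSE)
  X <- fft(x)
  mag <- Mod(X)
  if (max(mag) == 0)
    stop("all-zero series: cepstrum undefined", call. = FALSE)
  mag[mag == 0] <- .Machine$double.eps * max(mag)
  ceps <- Re(fft(log(mag), inverse = TRUE)) / n
  maxceps <- max(ceps[-1])
  nf <- n %/% 2 + 1
  pwr <- mag[seq_len(nf)]^2
  freqs <- (seq_len(nf) - 1) * fs / n
  cum <- cumsum(pwr)
  mdf <- freqs[which(cum >= cum[nf] / 2)[1]]
  c(MAXCEPS = maxceps, MDF = mdf)
}

#' Nonlinear features: SampEn, MFL, HFD and DFA
#'
#' Sample entropy uses Chebyshev distance, template length `m`,
#' tolerance `r` times the series SD, and excludes self-matches.
#' Maximum fractal length is `log10` of the RMS first-difference energy.
#' Higuchi fractal dimension is the log-log slope of mean curve length
#' against delay over `k = 1..higuchi_k`. DFA integrates the centred
#' series, removes an order-1 trend per box, and reports the slope of
#' `log F(s)` against `log s`.
#'
#' @inheritParams linear_features
#' @return Named numeric vector `(SAMPEN, MFL, HFD, DFA)`.
#' @export
nonlinear_features <- function(x, params = feature_params()) {
  if (length(x) < 100)
    stop("series too short for nonlinear features (need >= 100 samples)",
         call. = FALSE)
  c(SAMPEN = sample_entropy(x, params$sampen_m, params$sampen_r,
                            params$sampen_cap_policy),
    MFL = log10(sqrt(sum(diff(x)^2))),
    HFD = higuchi_fd(x, params$higuchi_k),
    DFA = dfa_exponent(x, params$dfa_box_range))
}

#' Sample entropy
#'
#' @param x numeric series.
#' @param m template length.
#' @param r tolerance as a fraction of `sd(x)`.
#' @param cap_policy see [feature_params()].
#' @return `-log(A/B)` where `B` counts length-`m` template matches and
#'   `A` those that still match at length `m + 1`.
#' @export
sample_entropy <- function(x, m = 2, r = 0.2, cap_policy = "cap") {
  s <- stats::sd(x)
  if (s == 0) {
    # constant series: every template matches and extends
    return(0)
  }
  cnt <- sampen_counts(as.numeric(x), as.integer(m), r * s)
  A <- cnt[1]; B <- cnt[2]
  if (A > 0 && B > 0) return(-log(A / B))
  if (cap_policy == "error")
    stop("sample entropy undefined: no extending template matches",
         call. = FALSE)
  cap <- log(max(B, 1)) + log(2)
  warning(sprintf("sample entropy undefined (A=%g, B=%g); capped at %.3f",
                  A, B, cap), call. = FALSE)
  cap
}

#' Higuchi fractal dimension
#'
#' @param x numeric series.
#' @param kmax maximum delay.
#' @return Estimated fractal dimension in `[1, 2]` for typical signals.
#' @export
higuchi_fd <- function(x, kmax = 10) {
  n <- length(x)
  lk <- numeric(kmax)
  for (k in seq_len(kmax)) {
    lm <- numeric(k)
    for (m in seq_len(k)) {
      idx <- seq(m, n, by = k)
      ni <- length(idx) - 1
      if (ni < 1) { lm[m] <- NA; next }
      lm[m] <- sum(abs(diff(x[idx]))) * (n - 1) / (ni * k) / k
    }
    lk[k] <- mean(lm, na.rm = TRUE)
  }
  keep <- is.finite(lk) & lk > 0
  fit <- stats::lm.fit(cbind(1, log(1 / seq_len(kmax)[keep])),
                       log(lk[keep]))
  unname(fit$coefficients[2])
}

#' Detrended fluctuation analysis exponent
#'
#' @param x numeric series.
#' @param box_range `(min, max)` box sizes; `NA` max means `N/4`.
#' @param n_scales number of log-spaced box sizes.
#' @return Scaling exponent alpha (0.5 for white noise, 1.5 for its
#'   cumulative sum).
#' @export
dfa_exponent <- function(x, box_range = c(4, NA), n_scales = 15) {
  n <- length(x)
  smin <- max(4, box_range[1])
  smax <- if (is.na(box_range[2])) n %/% 4 else box_range[2]
  if (smax <= smin) stop("DFA box range degenerate", call. = FALSE)
  scales <- unique(round(exp(seq(log(smin), log(smax),
                                 length.out = n_scales))))
  y <- cumsum(x - mean(x))
  fluct <- vapply(scales, function(s) dfa_fluctuation(y, s), 0.0)
  keep <- is.finite(fluct) & fluct > 0
  fit <- stats::lm.fit(cbind(1, log(scales[keep])), log(fluct[keep]))
  unname(fit$coefficients[2])
}

# RMS residual of per-box linear detrending at one box size (profile y).
dfa_fluctuation <- function(y, s) {
  nb <- length(y) %/% s
  if (nb < 1) return(NA_real_)
  m <- matrix(y[seq_len(nb * s)], nrow = s)
  t <- seq_len(s)
  tc <- t - mean(t)
  stt <- sum(tc^2)
  cm <- colMeans(m)
  slope <- as.numeric(crossprod(tc, m)) / stt
  resid <- m - rep(cm, each = s) - outer(tc, slope)
  sqrt(mean(resid^2))
}

#' Full handcrafted feature vector for one window
#'
#' Concatenates the linear, frequency and nonlinear features into the
#' fixed 17-value named vector used throughout the pipeline.
#'
#' @param x numeric series (microvolts).
#' @param fs sampling rate in Hz.
#' @param params a [feature_params()].
#' @return Named numeric vector of length 17 in [feature_names()] order.
#' @export
extract_features <- function(x, fs = 128, params = feature_params()) {
  out <- c(linear_features(x, params), frequency_features(x, fs),
           nonlinear_features(x, params))
  out[feature_names()]
}

#' Feature matrix over a set of windows
#'
#' @param windows a `dataset_split`, a list of labelled windows, or a
#'   list of numeric series.
#' @param fs sampling rate in Hz.
#' @param params a [feature_params()].
#' @param transform optional function applied to each window's samples
#'   before feature extraction, returning one series or a list of
#'   series; multiple series have their feature vectors concatenated
#'   (used by the decomposition routes).
#' @return A `feature_matrix`: list with `x` (numeric matrix, one row
#'   per window), `labels` (or `NULL`), and `params`.
#' @export
feature_matrix <- function(windows, fs = 128, params = feature_params(),
                           transform = NULL) {
  if (inherits(windows, "dataset_split")) windows <- windows$windows
  if (length(windows) == 0) stop("no windows supplied", call. = FALSE)
  labelled <- is.list(windows[[1]]) && !is.null(windows[[1]]$samples)
  labels <- if (labelled) vapply(windows, `[[`, "", "label") else NULL
  rows <- lapply(seq_along(windows), function(i) {
    x <- if (labelled) windows[[i]]$samples else windows[[i]]
    parts <- if (is.null(transform)) list(x) else transform(x)
    if (!is.list(parts)) parts <- list(parts)
    tryCatch(
      unlist(lapply(seq_along(parts), function(j) {
        v <- extract_features(parts[[j]], fs, params)
        if (length(parts) > 1) names(v) <- paste0(names(v), "_", j)
        v
      })),
      error = function(e) stop("window ", i, ": ", conditionMessage(e),
                               call. = FALSE))
  })
  x <- do.call(rbind, rows)
  structure(list(x = x, labels = labels, params = params,
                 col_means = colMeans(x),
                 col_sds = apply(x, 2, stats::sd)),
            class = "feature_matrix")
}
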