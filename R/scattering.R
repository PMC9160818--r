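#' Wavelet scattering configuration
#'
#' Two-layer scattering transform settings. Defaults follow the study
#' protocol: Gabor (complex Morlet-like) wavelets, a 1 s invariance
#' scale, 8 wavelets per octave in the first filter bank and 1 per
#' octave in the second.
#'
#' @param invariance_scale low-pass averaging scale in seconds.
#' @param Q1,Q2 wavelets per octave in layers 1 and 2.
#' @param wavelet filter family; only `"gabor"` is supported.
#' @return A `scattering_config` list (two layers, fixed).
#' @export
scattering_config <- function(invariance_scale = 1, Q1 = 8, Q2 = 1,
                              wavelet = "gabor") {
  if (!identical(wavelet, "gabor"))
    stop("unsupported wavelet: ", wavelet, call. = FALSE)
  stopifnot(invariance_scale > 0, Q1 >= 1, Q2 >= 1)
  structure(list(invariance_scale = invariance_scale,
                 Q1 = as.integer(Q1), Q2 = as.integer(Q2),
                 n_layers = 2L, wavelet = wavelet),
            class = "scattering_config")
}

# one Gabor band-pass bank: analytic Gaussian bumps at geometrically
# spaced centre frequencies, tiling (f_min, f_max] with Q per octave
gabor_bank <- function(n, fs, Q, f_min, f_max = 0.4 * fs) {
  freqs <- (seq_len(n) - 1) / n * fs      # unwrapped bin frequencies
  centers <- c()
  fc <- f_max
  while (fc >= f_min) {
    centers <- c(centers, fc)
    fc <- fc * 2^(-1 / Q)
  }
  spacing_ratio <- 1 - 2^(-1 / Q)
  lapply(centers, function(fc) {
    sigma <- fc * spacing_ratio           # adjacent bumps cross near e^-1/2
    list(fc = fc, hat = exp(-(freqs - fc)^2 / (2 * sigma^2)))
  })
}

#' Build the scattering filter bank
#'
#' Constructs the low-pass averaging filter at the invariance scale and
#' both Gabor band-pass banks on the FFT grid of an `n_samples` signal,
#' normalised so the Littlewood-Paley sum
#' `|phi|^2 + (1/2) sum_j (|psi_j(f)|^2 + |psi_j(-f)|^2)` is bounded by
#' 1 (the transform is then non-expansive).
#'
#' @param config a [scattering_config()].
#' @param fs sampling rate in Hz.
#' @param n_samples signal length the bank will be applied to.
#' @return A `scattering_bank`: `phi_hat`, `bank1`, `bank2`, and the
#'   grid metadata.
#' @export
build_filterbank <- function(config, fs, n_samples) {
  stopifnot(inherits(config, "scattering_config"))
  n <- as.integer(n_samples)
  t_samp <- config$invariance_scale * fs
  if (n < t_samp)
    stop("signal shorter than the invariance window (need >= ",
         ceiling(t_samp), " samples)", call. = FALSE)
  freqs <- (seq_len(n) - 1) / n * fs
  folded <- pmin(freqs, fs - freqs)
  sigma_t <- config$invariance_scale / 4          # seconds
  sigma_f <- 1 / (2 * pi * sigma_t)
  phi_hat <- exp(-folded^2 / (2 * sigma_f^2))

  f_min <- 1 / config$invariance_scale
  bank1 <- gabor_bank(n, fs, config$Q1, f_min)
  bank2 <- gabor_bank(n, fs, config$Q2, f_min)

  lp <- function(bank) {
    a <- numeric(n)
    for (flt in bank) {
      h2 <- flt$hat^2
      a <- a + 0.5 * (h2 + h2[c(1, n:2)])         # + mirrored spectrum
    }
    a
  }
  for (nm in c("bank1", "bank2")) {
    bank <- get(nm)
    a_psi <- lp(bank)
    head <- phi_hat^2
    c_norm <- max(a_psi / pmax(1 - head, 1e-6))
    bank <- lapply(bank, function(flt) {
      flt$hat <- flt$hat / sqrt(c_norm); flt
    })
    assign(nm, bank)
  }

  structure(list(phi_hat = phi_hat, bank1 = bank1, bank2 = bank2,
                 fs = fs, n = n, config = config,
                 subsample_step = max(1L, 2^floor(log2(t_samp)))),
            class = "scattering_bank")
}

#' Littlewood-Paley sum of a filter bank
#'
#' @param bank a `scattering_bank`.
#' @param layer which band-pass bank to include (1 or 2).
#' @return Numeric vector over FFT bins (should be <= 1 everywhere).
#' @export
littlewood_paley <- function(bank, layer = 1) {
  n <- bank$n
  a <- bank$phi_hat^2
  for (flt in bank[[paste0("bank", layer)]]) {
    h2 <- flt$hat^2
    a <- a + 0.5 * (h2 + h2[c(1, n:2)])
  }
  a
}

#' Wavelet scattering transform of one window
#'
#' Zero order: the signal averaged by the invariance-scale low-pass.
#' First order: wavelet modulus followed by the same averaging, one path
#' per first-bank filter. Second order: the first-order modulus is
#' re-analysed by the second bank along frequency-decreasing paths
#' (`fc2 < fc1`) and averaged. Coefficients are critically subsampled at
#' the invariance scale unless `subsample = FALSE`.
#'
#' @param x numeric series (uV).
#' @param config a [scattering_config()].
#' @param fs sampling rate in Hz.
#' @param subsample subsample outputs by the invariance step.
#' @param n_layers scattering depth (2 by default; 3 available for
#'   energy-decay diagnostics).
#' @param bank optional pre-built [build_filterbank()] result.
#' @return A `scatter_matrix`: `S0` (series), `S1` (named list by
#'   path), `S2` (named list by path `j1.j2`), optionally `S3`, plus
#'   the configuration.
#' @export
scatter <- function(x, config = scattering_config(), fs = 128,
                    subsample = TRUE, n_layers = 2, bank = NULL) {
  n <- length(x)
  if (is.null(bank)) bank <- build_filterbank(config, fs, n)
  if (bank$n != n) stop("filter bank built for different length",
                        call. = FALSE)
  step <- if (subsample) bank$subsample_step else 1L
  keep <- seq(1L, n, by = step)
  lowpass <- function(v_hat) Re(fft(v_hat * bank$phi_hat,
                                    inverse = TRUE))[keep] / n
  bandmod <- function(v_hat, flt) Mod(fft(v_hat * flt$hat,
                                          inverse = TRUE)) / n

  xh <- fft(x)
  S0 <- lowpass(xh)
  S1 <- list(); S2 <- list(); S3 <- list()
  for (j1 in seq_along(bank$bank1)) {
    f1 <- bank$bank1[[j1]]
    u1 <- bandmod(xh, f1)
    u1h <- fft(u1)
    S1[[sprintf("%02d", j1)]] <- lowpass(u1h)
    for (j2 in seq_along(bank$bank2)) {
      f2 <- bank$bank2[[j2]]
      if (f2$fc >= f1$fc) next
      u2 <- bandmod(u1h, f2)
      u2h <- fft(u2)
      S2[[sprintf("%02d.%02d", j1, j2)]] <- lowpass(u2h)
      if (n_layers >= 3) {
        for (j3 in seq_along(bank$bank2)) {
          f3 <- bank$bank2[[j3]]
          if (f3$fc >= f2$fc) next
          u3 <- bandmod(u2h, f3)
          S3[[sprintf("%02d.%02d.%02d", j1, j2, j3)]] <- lowpass(fft(u3))
        }
      }
    }
  }
  out <- list(S0 = S0, S1 = S1, S2 = S2, config = config, fs = fs,
              subsample_step = step)
  if (n_layers >= 3) out$S3 <- S3
  structure(out, class = "scatter_matrix")
}

#' @export
print.scatter_matrix <- function(x, ...) {
  cat("<scatter_matrix>", length(x$S1), "order-1 paths,",
      length(x$S2), "order-2 paths, output length", length(x$S0), "\n")
  invisible(x)
}

#' Fixed-length scattering feature vector
#'
#' Time-averages every coefficient path and concatenates the averages
#' in lexicographic path order (order, j1, j2), giving a dimension that
#' depends only on the configuration and sampling rate.
#'
#' @param matrix a `scatter_matrix` from [scatter()].
#' @return Named numeric vector (`S0`, `S1_<j1>`, `S2_<j1>.<j2>`).
#' @export
scatter_features <- function(matrix) {
  stopifnot(inherits(matrix, "scatter_matrix"))
  s1 <- vapply(matrix$S1, mean, 0.0)
  s2 <- vapply(matrix$S2, mean, 0.0)
  c(S0 = mean(matrix$S0),
    stats::setNames(s1, paste0("S1_", names(s1))),
    stats::setNames(s2, paste0("S2_", names(s2))))
}

# total energy per order, used by the energy-decay diagnostic
scatter_energy <- function(matrix) {
  e <- function(v) sum(v^2)
  out <- c(S0 = e(matrix$S0),
           S1 = sum(vapply(matrix$S1, e, 0.0)),
           S2 = sum(vapply(matrix$S2, e, 0.0)))
  if (!is.null(matrix$S3)) out <- c(out, S3 = sum(vapply(matrix$S3, e, 0.0)))
  out
}
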