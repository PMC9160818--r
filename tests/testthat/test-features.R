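test_that("time-domain features match hand arithmetic", {
  p <- feature_params()
  v <- linear_features(c(1, -2, 3), feature_params(ar_order = 2))
  expect_equal(unname(v["MAV"]), 2)
  expect_equal(unname(v["WL"]), 8)
  expect_equal(unname(v["SSI"]), 14)
  expect_equal(unname(v["RMS"]), sqrt(14 / 3))
  expect_equal(unname(v["VAR"]), stats::var(c(1, -2, 3)))
  zc <- linear_features(c(5, -5, 6, -4), feature_params(ar_order = 2))
  expect_equal(unname(zc["ZC"]), 3)
  # sub-threshold wiggles do not count as crossings
  zc2 <- linear_features(c(0.5, -0.5, 0.3, -0.4, 5, -6),
                         feature_params(ar_order = 2))
  expect_equal(unname(zc2["ZC"]), 1)
  expect_error(linear_features(c(1, 2), p), "too short")
})

test_that("AR(4) coefficients are recovered from a known process", {
  truth <- c(0.5, -0.3, 0.2, -0.1)
  x <- with_seed_test(81, as.numeric(
    stats::arima.sim(list(ar = truth), n = 5000)))
  est <- linear_features(x, feature_params())[c("AR1", "AR2", "AR3", "AR4")]
  expect_true(all(abs(est - truth) < 0.05))
})

test_that("median frequency matches the cumulative-periodogram oracle", {
  fs <- 128
  t <- (0:4999) / fs
  tone <- sin(2 * pi * 10 * t)
  mdf <- frequency_features(tone, fs)[["MDF"]]
  expect_lt(abs(mdf - 10), fs / 5000 + 1e-9)       # within one bin
  wn <- with_seed_test(82, stats::rnorm(5000))
  mdf_wn <- frequency_features(wn, fs)[["MDF"]]
  expect_lt(abs(mdf_wn - fs / 4), 0.1 * fs / 4)
  expect_equal(mdf_wn, median_freq_oracle(wn, fs))
  # power-ratio definition: amplitude scaling leaves MDF unchanged
  expect_equal(frequency_features(2 * wn, fs)[["MDF"]], mdf_wn)
  expect_error(frequency_features(rep(0, 100), fs), "all-zero")
})

test_that("maximum cepstrum coefficient excludes the zeroth quefrency", {
  x <- with_seed_test(83, stats::rnorm(512))
  mc <- frequency_features(x, 128)[["MAXCEPS"]]
  n <- length(x)
  ceps <- Re(stats::fft(log(Mod(stats::fft(x))),
                        inverse = TRUE)) / n
  expect_equal(mc, max(ceps[-1]))
})

test_that("sample entropy agrees with the brute-force template oracle", {
  set.seed(84)
  for (rep in 1:8) {
    x <- stats::rnorm(150)
    r_abs <- 0.2 * stats::sd(x)
    cnt <- sampen_oracle(x, 2, r_abs)
    expect_equal(sample_entropy(x, 2, 0.2), -log(cnt["A"] / cnt["B"]),
                 ignore_attr = TRUE)
  }
  # strictly periodic series: every length-2 match extends
  per <- rep(c(1, 2, 3), 50)
  expect_equal(sample_entropy(per, 2, 0.2), 0)
})

test_that("adding noise to a periodic signal does not reduce SampEn", {
  t <- 1:600
  clean <- sin(2 * pi * t / 30)
  noisy <- clean + with_seed_test(85, stats::rnorm(600, sd = 0.3))
  expect_gte(sample_entropy(noisy), sample_entropy(clean))
})

test_that("DFA matches known scaling laws and the brute-force oracle", {
  wn <- with_seed_test(86, stats::rnorm(5000))
  expect_lt(abs(dfa_exponent(wn) - 0.5), 0.1)
  expect_lt(abs(dfa_exponent(cumsum(wn)) - 1.5), 0.15)
  for (s in c(8, 32, 100)) {
    expect_equal(anesdepth:::dfa_fluctuation(cumsum(wn - mean(wn)), s),
                 dfa_fluct_oracle(wn, s), tolerance = 1e-10)
  }
})

test_that("Higuchi dimension is 1 on a straight line", {
  expect_lt(abs(higuchi_fd(seq_len(2000)) - 1), 0.05)
  # oracle check: curve lengths of a line scale exactly as 1/k
  n <- 500
  x <- seq_len(n)
  lk <- vapply(1:10, function(k) {
    mean(vapply(1:k, function(m) {
      idx <- seq(m, n, by = k)
      sum(abs(diff(x[idx]))) * (n - 1) / ((length(idx) - 1) * k) / k
    }, 0.0))
  }, 0.0)
  slope <- coef(stats::lm(log(lk) ~ log(1 / (1:10))))[2]
  expect_equal(unname(slope), 1, tolerance = 1e-6)
})

test_that("the full vector has 17 named features in fixed order", {
  x <- simulate_state_epoch("OPERATIVE", n_samples = 1280, seed = 87)
  v <- extract_features(x)
  expect_identical(names(v), feature_names())
  expect_length(v, 17)
  expect_true(all(is.finite(v)))
  expect_error(nonlinear_features(stats::rnorm(50)), ">= 100")
})

test_that("feature matrices have stable shape and rows", {
  fm <- fixture_features()
  expect_identical(dim(fm$x), c(16L, 17L))
  expect_identical(colnames(fm$x), feature_names())
  split <- fixture_split()
  sel <- lsdl_select_optimal(split)
  fm2 <- t(vapply(split$windows, function(w)
    lsdl_features(w$samples, sel), numeric(34)))
  expect_identical(dim(fm2), c(16L, 34L))
  # identical windows give identical rows
  w <- split$windows[[1]]
  fm3 <- feature_matrix(list(w, w))
  expect_identical(fm3$x[1, ], fm3$x[2, ])
})

test_that("features scale as documented under amplitude scaling", {
  x <- simulate_state_epoch("SEMI_AWAKE", n_samples = 2000, seed = 88)
  a <- 2.5
  v1 <- extract_features(x)
  v2 <- extract_features(a * x)
  linear <- c("MAV", "WL", "RMS")
  expect_equal(v2[linear], a * v1[linear], tolerance = 1e-8)
  expect_equal(v2[c("SSI", "VAR")], a^2 * v1[c("SSI", "VAR")],
               tolerance = 1e-8)
  invariant <- c("MDF", "SAMPEN", "HFD", "DFA")
  expect_equal(v2[invariant], v1[invariant], tolerance = 1e-6)
  expect_equal(unname(v2["MFL"]), unname(v1["MFL"] + log10(a)),
               tolerance = 1e-8)
})
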