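# Shared fixtures, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixtures)) assign(name, expr, envir = .fixtures)
  get(name, envir = .fixtures)
}

# one full-protocol synthetic subject: 160 s per state -> 16 windows
fixture_split <- function() {
  cached("split", {
    rec <- simulate_session(c("AWAKE", "SEMI_AWAKE", "OPERATIVE",
                              "VERY_LOW"),
                            durations = 160, seed = 101,
                            subject_id = "fix1")
    extract_class_windows(rec)
  })
}

fixture_features <- function() {
  cached("features", feature_matrix(fixture_split()))
}

# small two-class windows whose discriminative content sits in rare
# high-amplitude spikes on a shared low-amplitude noise floor
spiky_windows <- function(n_per_class = 6, n = 1200, seed = 5) {
  mk <- function(label, i) {
    x <- with_seed_test(seed + i, {
      base <- rnorm(n, sd = 0.5)
      spike_at <- seq(4, n, by = 4)[1:300]
      mag <- runif(300, 6.5, 8) + rnorm(300, sd = 0.1)
      sgn <- if (label == "A") rep(1, 300) else rep(c(1, -1), 150)
      base[spike_at] <- sgn * mag
      base
    })
    list(samples = x, label = label, subject_id = "spiky", window_index = i)
  }
  c(lapply(seq_len(n_per_class), function(i) mk("A", i)),
    lapply(seq_len(n_per_class), function(i) mk("B", i + 100)))
}

with_seed_test <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

# independent periodogram median frequency (oracle, direct summation)
median_freq_oracle <- function(x, fs) {
  n <- length(x)
  nf <- n %/% 2 + 1
  p <- Mod(fft(x))[seq_len(nf)]^2
  f <- (seq_len(nf) - 1) * fs / n
  f[which(cumsum(p) >= sum(p) / 2)[1]]
}

# brute-force sample-entropy template counts (oracle)
sampen_oracle <- function(x, m, r_abs) {
  n <- length(x)
  nt <- n - m
  A <- 0; B <- 0
  for (i in 1:(nt - 1)) {
    for (j in (i + 1):nt) {
      if (max(abs(x[i:(i + m - 1)] - x[j:(j + m - 1)])) <= r_abs) {
        B <- B + 1
        if (max(abs(x[i:(i + m)] - x[j:(j + m)])) <= r_abs) A <- A + 1
      }
    }
  }
  c(A = A, B = B)
}

# brute-force DFA fluctuation at one box size, via lm() per box
dfa_fluct_oracle <- function(x, s) {
  y <- cumsum(x - mean(x))
  nb <- length(y) %/% s
  res <- unlist(lapply(seq_len(nb), function(b) {
    seg <- y[((b - 1) * s + 1):(b * s)]
    stats::residuals(stats::lm(seg ~ seq_len(s)))
  }))
  sqrt(mean(res^2))
}
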