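test_that("threshold recurrences hold exactly", {
  sch <- threshold_schedule(100, 3)
  expect_equal(sch$upper, c(50, 75, 87.5))
  expect_equal(sch$lower, c(50, 25, 12.5))
  sch1 <- threshold_schedule(80, 1)
  expect_equal(sch1$upper, 40)
  expect_equal(sch1$lower, 40)
  expect_error(threshold_schedule(-1, 3))
  expect_error(threshold_schedule(10, 0))
})

test_that("schedules match a brute-force recurrence for random amplitudes", {
  set.seed(42)
  for (mx in stats::runif(25, 0.01, 500)) {
    n <- 6
    sch <- threshold_schedule(mx, n)
    up <- lo <- numeric(n)
    up[1] <- lo[1] <- 0.5 * mx
    for (k in 2:n) {
      up[k] <- (mx + up[k - 1]) / 2
      lo[k] <- lo[k - 1] / 2
    }
    expect_equal(sch$upper, up, tolerance = 0)
    expect_equal(sch$lower, lo, tolerance = 0)
    # fixed points: upper -> max, lower -> 0, monotonically
    expect_true(all(diff(sch$upper) > 0) && all(sch$upper < mx))
    expect_true(all(diff(sch$lower) < 0) && all(sch$lower > 0))
  }
})

test_that("amplitude bands select the right subsequences", {
  r <- lsdl_decompose(c(10, -60, 30, 80),
                      schedule = threshold_schedule(80, 2))
  expect_equal(r$upper_regions[[1]], c(-60, 80))
  # lower threshold above max|s| keeps the whole signal
  x <- c(1, -2, 3)
  r2 <- lsdl_decompose(x, schedule = threshold_schedule(100, 1))
  expect_equal(r2$lower_regions[[1]], x)
  expect_error(lsdl_decompose(numeric(0)), "empty")
})

test_that("region sample counts shrink with iteration", {
  set.seed(7)
  for (rep in 1:5) {
    x <- stats::rnorm(500) * stats::runif(1, 0.5, 50)
    r <- lsdl_decompose(x, n_iter = 5)
    nu <- lengths(r$upper_regions)
    nl <- lengths(r$lower_regions)
    # oracle: brute-force membership counts
    sch <- r$schedule
    expect_equal(nu, vapply(sch$upper, function(t) sum(abs(x) >= t), 0L))
    expect_equal(nl, vapply(sch$lower, function(t) sum(abs(x) <= t), 0L))
    expect_true(all(diff(nu) <= 0))
    expect_true(all(diff(nl) <= 0))
  }
})

test_that("iteration-1 regions jointly cover every sample", {
  set.seed(8)
  x <- stats::rnorm(1000) * 20
  r <- lsdl_decompose(x, n_iter = 4)
  covered <- abs(x) >= r$schedule$upper[1] | abs(x) <= r$schedule$lower[1]
  expect_true(all(covered))
  expect_equal(length(r$upper_regions[[1]]) + length(r$lower_regions[[1]])
               - sum(abs(x) == r$schedule$upper[1]), length(x))
})

test_that("selection favours the band holding the discriminative content", {
  wins <- spiky_windows()
  sel <- suppressWarnings(lsdl_select_optimal(wins, n_iter = 4, fs = 128))
  # classes differ only in their high-amplitude spikes, so the chosen
  # upper band must out-score every spike-free low band
  expect_gt(sel$upper_scores[sel$selected_upper],
            max(sel$lower_scores, na.rm = TRUE))
  # exhaustive-score oracle: the selected index is the argmax
  expect_equal(sel$selected_upper,
               which.max(ifelse(is.na(sel$upper_scores), -Inf,
                                sel$upper_scores)))
  expect_length(sel$upper_scores, 4)
  expect_length(sel$lower_scores, 4)
})

test_that("identical windows tie and resolve to iteration 1", {
  x <- 10 * sin(2 * pi * (1:2000) * 5 / 128) +
    sin(2 * pi * (1:2000) * 31 / 128)
  wins <- list(list(samples = x, label = "A"),
               list(samples = x, label = "A"),
               list(samples = x, label = "B"),
               list(samples = x, label = "B"))
  sel <- suppressWarnings(lsdl_select_optimal(wins, n_iter = 3, fs = 128))
  eligible_up <- which(!is.na(sel$upper_scores))
  expect_true(all(abs(sel$upper_scores[eligible_up]) < 1e-9))
  expect_equal(sel$selected_upper, eligible_up[1])
  expect_equal(sel$selected_lower, which(!is.na(sel$lower_scores))[1])
})

test_that("selection is stable under common rescaling of all windows", {
  wins <- spiky_windows()
  wins_scaled <- lapply(wins, function(w) {
    w$samples <- w$samples * 3.7; w
  })
  s1 <- suppressWarnings(lsdl_select_optimal(wins, n_iter = 4))
  s2 <- suppressWarnings(lsdl_select_optimal(wins_scaled, n_iter = 4))
  expect_equal(s1$selected_upper, s2$selected_upper)
  expect_equal(s1$selected_lower, s2$selected_lower)
})

test_that("per-window features double the base dimension deterministically", {
  split <- fixture_split()
  sel <- lsdl_select_optimal(split)
  v1 <- lsdl_features(split$windows[[1]]$samples, sel)
  v2 <- lsdl_features(split$windows[[1]]$samples, sel)
  expect_length(v1, 2 * length(feature_names()))
  expect_identical(v1, v2)
  # decomposition strips most samples of a peaky signal before features
  wins <- spiky_windows()
  r <- lsdl_decompose(wins[[1]]$samples, n_iter = 4)
  kept <- length(r$upper_regions[[1]])
  expect_lt(kept, length(wins[[1]]$samples) / 2)
})
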