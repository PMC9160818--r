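#' LSDL threshold schedule
#'
#' Iterated amplitude thresholds for the linear series decomposition
#' learner. Both families start at half the absolute signal maximum;
#' upper thresholds then halve the gap to the maximum each iteration,
#' while lower thresholds halve toward zero:
#' `T_upper_k = (max_abs + T_upper_{k-1}) / 2`, `T_lower_k = T_lower_{k-1} / 2`.
#'
#' @param max_abs maximum absolute amplitude of the signal (uV).
#' @param n_iter number of iterations (default 4).
#' @return A `threshold_schedule` with `upper`, `lower`, `max_abs`.
#' @export
#' @examples
#' threshold_schedule(100, 3)
threshold_schedule <- function(max_abs, n_iter = 4) {
  stopifnot_scalar_pos(max_abs, "max_abs")
  if (!is.numeric(n_iter) || n_iter < 1)
    stop("`n_iter` must be a positive count", call. = FALSE)
  n_iter <- as.integer(n_iter)
  upper <- lower <- numeric(n_iter)
  upper[1] <- lower[1] <- 0.5 * max_abs
  if (n_iter > 1) {
    for (k in 2:n_iter) {
      upper[k] <- (max_abs + upper[k - 1]) / 2
      lower[k] <- lower[k - 1] / 2
    }
  }
  structure(list(upper = upper, lower = lower, max_abs = max_abs,
                 n_iter = n_iter),
            class = "threshold_schedule")
}

# One amplitude band as a time-ordered subsequence. When the dyadic
# threshold leaves fewer than `min_len` member samples, the band is
# padded with the next samples in amplitude rank (largest |s| first for
# the upper family, smallest first for the lower) so the handcrafted
# features stay computable; `min_len = 0` disables padding.
band_region <- function(x, thr, family, min_len = 0, candidate = NULL) {
  a <- abs(x)
  if (is.null(candidate)) candidate <- rep(TRUE, length(x))
  keep <- candidate & if (family == "upper") a >= thr else a <= thr
  if (sum(keep) >= min_len || min_len <= 0) return(x[keep])
  pool <- which(candidate)
  ord <- pool[order(a[pool], decreasing = (family == "upper"))]
  x[sort(ord[seq_len(min(min_len, length(ord)))])]
}

# local extrema (strict) of a series; used by the optional peak filter
local_extrema_mask <- function(x) {
  n <- length(x)
  if (n < 3) return(rep(TRUE, n))
  mid <- x[2:(n - 1)]
  up <- mid > x[1:(n - 2)] & mid > x[3:n]
  dn <- mid < x[1:(n - 2)] & mid < x[3:n]
  c(TRUE, up | dn, TRUE)
}

#' Amplitude-band decomposition of a signal
#'
#' For each threshold iteration, extracts the subsequence of samples
#' (time gaps closed up, original order and raw values preserved) whose
#' rectified amplitude lies at or above the upper threshold, and the
#' subsequence at or below the lower threshold. With `peaks = TRUE`,
#' membership is first restricted to local extrema of `|x|`.
#'
#' @param x numeric signal (uV).
#' @param schedule a [threshold_schedule()]; by default built from
#'   `max(abs(x))` with `n_iter` iterations.
#' @param n_iter iterations when `schedule` is NULL.
#' @param peaks restrict candidate samples to local extrema of the
#'   rectified signal (off by default).
#' @return An `lsdl_regions` object: lists `upper_regions` and
#'   `lower_regions` of candidate subsequences plus the schedule.
#' @export
lsdl_decompose <- function(x, schedule = NULL, n_iter = 4, peaks = FALSE) {
  if (length(x) == 0) stop("empty signal", call. = FALSE)
  if (is.null(schedule)) {
    mx <- max(abs(x))
    if (mx == 0) stop("all-zero signal has no amplitude bands", call. = FALSE)
    schedule <- threshold_schedule(mx, n_iter)
  }
  stopifnot(inherits(schedule, "threshold_schedule"))
  a <- abs(x)
  cand <- if (peaks) local_extrema_mask(a) else rep(TRUE, length(x))
  upper <- lapply(schedule$upper, function(t) x[cand & a >= t])
  lower <- lapply(schedule$lower, function(t) x[cand & a <= t])
  structure(list(upper_regions = upper, lower_regions = lower,
                 schedule = schedule, peaks = peaks),
            class = "lsdl_regions")
}

#' Fisher class-separability score
#'
#' Default LSDL performance index: mean over features of the ratio of
#' between-class variance of class means to mean within-class variance.
#' Scale-invariant per feature, classifier-free, and cheap.
#'
#' @param feats numeric feature matrix (rows = windows).
#' @param labels class labels aligned with rows.
#' @return A single non-negative score (higher = more separable).
#' @export
fisher_score <- function(feats, labels) {
  labels <- as.character(labels)
  classes <- unique(labels)
  if (length(classes) < 2) stop("need >= 2 classes", call. = FALSE)
  per_feature <- apply(feats, 2, function(col) {
    means <- tapply(col, labels, mean)
    wvar <- tapply(col, labels, stats::var)
    wbar <- mean(wvar, na.rm = TRUE)
    bvar <- stats::var(means)
    if (!is.finite(wbar) || wbar <= 0) {
      if (is.finite(bvar) && bvar > 0) Inf else 0
    } else bvar / wbar
  })
  per_feature[!is.finite(per_feature)] <- max(
    per_feature[is.finite(per_feature)], 1) * 10
  mean(per_feature)
}

#' Select the optimal LSDL regions by performance index
#'
#' Decomposes every window at each threshold iteration, extracts the
#' handcrafted features of each candidate region, scores each iteration
#' with the performance index, and selects one upper and one lower
#' iteration. Ties (and the all-identical degenerate case) resolve to
#' the smallest iteration index. Candidate bands shorter than the
#' 100-sample feature floor are padded by amplitude rank (see
#' [lsdl_features()]) so every iteration stays scoreable on bursty
#' signals whose extreme peaks leave high thresholds nearly empty.
#'
#' @param windows a `dataset_split` or list of labelled windows with at
#'   least two classes.
#' @param n_iter threshold iterations (default 4).
#' @param fs sampling rate (Hz) for the frequency features.
#' @param params a [feature_params()].
#' @param scorer performance-index function `f(feats, labels)`; default
#'   [fisher_score()].
#' @param sense `"max"` (default) or `"min"`: whether larger or smaller
#'   scores are better.
#' @param peaks passed to [lsdl_decompose()].
#' @return An `lsdl_selection`: `upper_scores`, `lower_scores`,
#'   `selected_upper`, `selected_lower`, plus the configuration.
#' @export
lsdl_select_optimal <- function(windows, n_iter = 4, fs = 128,
                                params = feature_params(),
                                scorer = fisher_score,
                                sense = c("max", "min"), peaks = FALSE) {
  sense <- match.arg(sense)
  if (inherits(windows, "dataset_split")) windows <- windows$windows
  labels <- vapply(windows, `[[`, "", "label")
  if (length(unique(labels)) < 2)
    stop("need windows from >= 2 classes", call. = FALSE)

  if (any(vapply(windows, function(w) length(w$samples), 0L) < 100))
    stop("windows shorter than 100 samples cannot be scored", call. = FALSE)
  schedules <- lapply(windows, function(w)
    threshold_schedule(max(abs(w$samples)), n_iter))
  candidates <- lapply(windows, function(w)
    if (peaks) local_extrema_mask(abs(w$samples)) else NULL)

  score_family <- function(family) {
    vapply(seq_len(n_iter), function(k) {
      regs <- lapply(seq_along(windows), function(i)
        band_region(windows[[i]]$samples,
                    schedules[[i]][[if (family == "upper_regions")
                      "upper" else "lower"]][k],
                    if (family == "upper_regions") "upper" else "lower",
                    min_len = 100, candidate = candidates[[i]]))
      feats <- do.call(rbind, lapply(regs, extract_features, fs = fs,
                                     params = params))
      s <- scorer(feats, labels)
      if (!is.finite(s))
        stop("performance index non-finite at ", family, " iteration ", k,
             call. = FALSE)
      s
    }, 0.0)
  }
  upper_scores <- score_family("upper_regions")
  lower_scores <- score_family("lower_regions")

  pick <- function(scores) {
    if (all(is.na(scores)))
      stop("no eligible iteration: all candidate regions too short",
           call. = FALSE)
    s <- if (sense == "max") scores else -scores
    # ties and near-ties (1e-12 relative) resolve to the earliest iteration
    best <- max(s, na.rm = TRUE)
    tol <- 1e-12 * max(1, abs(best))
    which(!is.na(s) & s >= best - tol)[1]
  }
  structure(list(upper_scores = upper_scores, lower_scores = lower_scores,
                 selected_upper = pick(upper_scores),
                 selected_lower = pick(lower_scores),
                 n_iter = n_iter, sense = sense, peaks = peaks),
            class = "lsdl_selection")
}

#' @export
print.lsdl_selection <- function(x, ...) {
  cat("<lsdl_selection> upper:", round(x$upper_scores, 4),
      "-> iteration", x$selected_upper, "\n")
  cat("                 lower:", round(x$lower_scores, 4),
      "-> iteration", x$selected_lower, "\n")
  invisible(x)
}

#' Handcrafted features on the two selected LSDL regions
#'
#' Decomposes one window with its own amplitude schedule, keeps the
#' selected upper and lower regions, and concatenates their feature
#' vectors (twice the base feature dimension). A selected band with
#' fewer than 100 member samples (possible on bursty windows whose
#' single extreme peak pushes the upper thresholds out of reach) is,
#' under the default `"pad"` policy, extended with the next samples in
#' amplitude rank until the feature floor is met; `"error"` rejects
#' such windows instead.
#'
#' @param x numeric window (uV).
#' @param selection an `lsdl_selection` from [lsdl_select_optimal()].
#' @param fs sampling rate in Hz.
#' @param params a [feature_params()].
#' @param short_region policy for under-populated selected bands.
#' @return Named numeric vector of length `2 * 17`, suffixes `_up`,
#'   `_lo`.
#' @export
lsdl_features <- function(x, selection, fs = 128,
                          params = feature_params(),
                          short_region = c("pad", "error")) {
  stopifnot(inherits(selection, "lsdl_selection"))
  short_region <- match.arg(short_region)
  regs <- lsdl_selected_regions(x, selection,
                                min_len = if (short_region == "pad")
                                  100 else 0)
  if (length(regs$up) < 100 || length(regs$lo) < 100)
    stop("selected LSDL region too short for feature extraction (",
         length(regs$up), " upper / ", length(regs$lo),
         " lower samples)", call. = FALSE)
  fu <- extract_features(regs$up, fs, params)
  fl <- extract_features(regs$lo, fs, params)
  names(fu) <- paste0(names(fu), "_up")
  names(fl) <- paste0(names(fl), "_lo")
  c(fu, fl)
}

# the two selected bands of one window, optionally padded to min_len
lsdl_selected_regions <- function(x, selection, min_len = 100) {
  sch <- threshold_schedule(max(abs(x)), selection$n_iter)
  cand <- if (selection$peaks) local_extrema_mask(abs(x)) else NULL
  list(up = band_region(x, sch$upper[selection$selected_upper], "upper",
                        min_len = min_len, candidate = cand),
       lo = band_region(x, sch$lower[selection$selected_lower], "lower",
                        min_len = min_len, candidate = cand))
}
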