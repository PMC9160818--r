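#' Method route definitions
#'
#' The four signal-processing routes compared by the benchmark:
#' `RAW` (windowed signal straight into the handcrafted features),
#' `NAMEMD` (noise-assisted multivariate EMD, features on modes 2 and
#' 3), `LSDL` (amplitude-band decomposition, features on the selected
#' upper and lower regions), and `DWS` (two-layer wavelet scattering
#' coefficients as the feature vector). Each feeds the pooled
#' covariance discriminant with 10-fold cross-validation.
#'
#' @return Character vector of route names.
#' @export
route_names <- function() c("NAMEMD", "RAW", "LSDL", "DWS")

timed <- function(expr) {
  t0 <- proc.time()[["elapsed"]]
  value <- force(expr)
  list(value = value, elapsed = proc.time()[["elapsed"]] - t0)
}

#' Run one processing route on a windowed dataset
#'
#' Executes decompose, then feature extraction, then stratified k-fold
#' cross-validated discriminant classification, recording wall-clock
#' time per stage and the mean per-window sample count entering feature
#' extraction.
#'
#' @param route one of [route_names()].
#' @param split a `dataset_split` from [extract_class_windows()].
#' @param seed master seed; the noise channels and fold assignment use
#'   child seeds derived from it.
#' @param fs sampling rate in Hz.
#' @param k cross-validation folds.
#' @param params a [feature_params()] (handcrafted routes).
#' @param memd_cfg a [memd_config()] template for the NAMEMD route.
#' @param scat_cfg a [scattering_config()] for the DWS route.
#' @param imf_indices modes used by the NAMEMD route.
#' @param n_iter LSDL threshold iterations.
#' @param lambda discriminant shrinkage.
#' @return A `route_result`: `route`, `accuracy` (%), `cv`, `timing`
#'   (decomposition_s, n_samples_pre_feature, feature_s, predict_s,
#'   total_s), `feature_dim`, `n_windows`.
#' @export
run_route <- function(route, split, seed = 1, fs = 128, k = 10,
                      params = feature_params(),
                      memd_cfg = memd_config(),
                      scat_cfg = scattering_config(),
                      imf_indices = c(2, 3), n_iter = 4, lambda = 1e-3) {
  route <- match.arg(route, route_names())
  stopifnot(inherits(split, "dataset_split"))
  windows <- split$windows
  labels <- window_labels(split)
  wlen <- length(windows[[1]]$samples)

  run <- function() switch(route,
    RAW = {
      fm <- timed(feature_matrix(split, fs = fs, params = params))
      list(decomp_s = 0, n_pre = wlen, feat = fm)
    },
    NAMEMD = {
      dec <- timed(lapply(seq_along(windows), function(i) {
        cfg <- memd_cfg
        cfg$seed <- child_seed(seed, 100L + i)
        # modes beyond the highest requested index are never consumed;
        # capping them leaves the retained modes bit-identical
        cfg$max_imf <- min(cfg$max_imf, max(imf_indices))
        select_imfs(na_memd(windows[[i]]$samples, cfg), imf_indices)
      }))
      n_pre <- mean(vapply(dec$value, function(l)
        sum(lengths(l)), 0.0))
      fm <- timed(feature_matrix(dec$value, fs = fs, params = params,
                                 transform = identity))
      fm$value$labels <- labels
      list(decomp_s = dec$elapsed, n_pre = n_pre, feat = fm)
    },
    LSDL = {
      sel <- timed(lsdl_select_optimal(split, n_iter = n_iter, fs = fs,
                                       params = params))
      regions <- lapply(windows, function(w) {
        r <- lsdl_selected_regions(w$samples, sel$value)
        list(r$up, r$lo)
      })
      n_pre <- mean(vapply(regions, function(l) sum(lengths(l)), 0.0))
      fm <- timed(feature_matrix(regions, fs = fs, params = params,
                                 transform = identity))
      fm$value$labels <- labels
      list(decomp_s = sel$elapsed, n_pre = n_pre, feat = fm,
           selection = sel$value)
    },
    DWS = {
      bank <- build_filterbank(scat_cfg, fs, wlen)
      fm <- timed({
        rows <- lapply(windows, function(w)
          scatter_features(scatter(w$samples, scat_cfg, fs, bank = bank)))
        structure(list(x = do.call(rbind, rows), labels = labels,
                       params = scat_cfg),
                  class = "feature_matrix")
      })
      list(decomp_s = 0, n_pre = wlen, feat = fm)
    })

  stage <- tryCatch(run(), error = function(e)
    stop(route, " route: ", conditionMessage(e), call. = FALSE))
  fm <- stage$feat$value
  cv <- kfold_cv(fm, labels, k = k, seed = child_seed(seed, 7L),
                 lambda = lambda)
  model <- fit_lda(fm$x, labels, lambda = lambda)
  pt <- timed(predict(model, fm$x[1, ]))

  structure(list(
    route = route, accuracy = cv$accuracy, cv = cv,
    selection = stage$selection,
    timing = list(decomposition_s = stage$decomp_s,
                  n_samples_pre_feature = stage$n_pre,
                  feature_s = stage$feat$elapsed,
                  predict_s = pt$elapsed,
                  total_s = stage$decomp_s + stage$feat$elapsed +
                    pt$elapsed),
    feature_dim = ncol(fm$x), n_windows = length(windows)),
    class = "route_result")
}

#' Benchmark all routes over a set of subjects
#'
#' Runs every route on every subject's windowed data (patient-specific
#' models, as in the study design), then summarises mean and SD
#' accuracy per route, counts how often each route is (jointly) best
#' across subjects, and averages the per-stage timing.
#'
#' @param subjects list of `eeg_record`s.
#' @param routes routes to compare (default all four).
#' @param k cross-validation folds.
#' @param seed master seed; per-subject child seeds derive from it.
#' @param samples_per_class,window_size passed to
#'   [extract_class_windows()].
#' @param fs sampling rate in Hz.
#' @param ... further arguments to [run_route()].
#' @return A `benchmark_report`: `per_subject` (accuracy matrix,
#'   subjects x routes), `mean_sd`, `rank_counts`, `timing`.
#' @export
run_benchmark <- function(subjects, routes = route_names(), k = 10,
                          seed = 1, samples_per_class = 20000,
                          window_size = 5000, fs = 128, ...) {
  if (length(subjects) < 1) stop("need >= 1 subject", call. = FALSE)
  ids <- vapply(subjects, `[[`, "", "subject_id")
  acc <- matrix(NA_real_, length(subjects), length(routes),
                dimnames = list(ids, routes))
  timing_acc <- list()
  for (si in seq_along(subjects)) {
    split <- extract_class_windows(subjects[[si]], samples_per_class,
                                   window_size)
    for (r in routes) {
      res <- run_route(r, split, seed = child_seed(seed, si), fs = fs,
                       k = k, ...)
      acc[si, r] <- res$accuracy
      timing_acc[[r]] <- rbind(timing_acc[[r]],
                               unlist(res$timing))
    }
  }
  mean_sd <- data.frame(
    route = routes,
    mean = colMeans(acc),
    sd = apply(acc, 2, function(v) if (length(v) > 1) stats::sd(v) else 0),
    row.names = NULL)
  # joint-best convention: every route tied at a subject's maximum scores
  rank_counts <- stats::setNames(integer(length(routes)), routes)
  for (si in seq_len(nrow(acc))) {
    best <- max(acc[si, ])
    winners <- routes[acc[si, ] >= best - 1e-9]
    rank_counts[winners] <- rank_counts[winners] + 1L
  }
  timing <- lapply(timing_acc, function(m)
    as.list(colMeans(m)))
  structure(list(per_subject = acc, mean_sd = mean_sd,
                 rank_counts = rank_counts, timing = timing,
                 k = k, seed = seed),
            class = "benchmark_report")
}

#' @export
print.benchmark_report <- function(x, ...) {
  cat("<benchmark_report>", nrow(x$per_subject), "subject(s)\n")
  for (i in seq_len(nrow(x$mean_sd)))
    cat(sprintf("  %-7s %.2f +/- %.2f %%  (best %d time(s))\n",
                x$mean_sd$route[i], x$mean_sd$mean[i], x$mean_sd$sd[i],
                x$rank_counts[[x$mean_sd$route[i]]]))
  invisible(x)
}
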