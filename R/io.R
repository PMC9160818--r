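#' Bin a BIS-like value into a consciousness class
#'
#' Maps values on `[0, 100]` to the four depth-of-anaesthesia classes
#' using half-open bins `[0,40)`, `[40,60)`, `[60,80)`, `[80,100]`.
#' The mapping is total and piecewise constant; 100 belongs to AWAKE.
#'
#' @param bis numeric vector of index values in `[0, 100]`.
#' @return Character vector of state labels.
#' @export
#' @examples
#' bin_bis(c(90, 40, 0, 100))
bin_bis <- function(bis) {
  if (!is.numeric(bis) || any(!is.finite(bis)))
    stop("`bis` must be finite numeric", call. = FALSE)
  if (any(bis < 0 | bis > 100))
    stop("BIS values must lie in [0, 100]", call. = FALSE)
  st <- doa_states()
  out <- character(length(bis))
  out[bis >= 80] <- "AWAKE"
  out[bis >= 60 & bis < 80] <- "SEMI_AWAKE"
  out[bis >= 40 & bis < 60] <- "OPERATIVE"
  out[bis < 40] <- "VERY_LOW"
  out
}

#' Cut per-class EEG into fixed-length labelled windows
#'
#' Labels every sample of the record by binning its aligned BIS value
#' (each BIS value labels the preceding 5 s of signal), takes the first
#' `samples_per_class` samples of each requested class in temporal
#' order, and cuts them into consecutive non-overlapping windows of
#' `window_size` samples. Defaults follow the study protocol: 20,000
#' samples per class split into four 5000-sample repetitions.
#'
#' @param record an `eeg_record` from [simulate_session()] or
#'   [read_record()].
#' @param samples_per_class samples retained per class (default 20000).
#' @param window_size window length in samples (default 5000); must
#'   divide `samples_per_class`.
#' @param states classes to extract; defaults to all four.
#' @return A `dataset_split`: list with `windows` (each a list with
#'   `samples`, `label`, `subject_id`, `window_index`) and
#'   `per_class_counts`.
#' @export
extract_class_windows <- function(record, samples_per_class = 20000,
                                  window_size = 5000,
                                  states = doa_state_labels()) {
  stopifnot(inherits(record, "eeg_record"))
  stopifnot_scalar_pos(samples_per_class, "samples_per_class")
  stopifnot_scalar_pos(window_size, "window_size")
  if (samples_per_class %% window_size != 0)
    stop("`window_size` must divide `samples_per_class`", call. = FALSE)
  states <- vapply(states, function(s) match.arg(s, doa_state_labels()), "")

  block <- as.integer(5 * record$fs)
  n_lab <- length(record$bis_trace) * block
  labels <- rep(bin_bis(record$bis_trace), each = block)
  sig <- record$signal[seq_len(n_lab)]

  shortfall <- character(0)
  windows <- list()
  counts <- stats::setNames(integer(length(states)), states)
  for (s in states) {
    idx <- which(labels == s)
    if (length(idx) < samples_per_class) {
      shortfall <- c(shortfall, sprintf(
        "%s: %d of %d samples available", s, length(idx), samples_per_class))
      next
    }
    seg <- sig[idx[seq_len(samples_per_class)]]
    n_win <- as.integer(samples_per_class %/% window_size)
    for (w in seq_len(n_win)) {
      samples <- seg[((w - 1) * window_size + 1):(w * window_size)]
      windows[[length(windows) + 1L]] <- list(
        samples = samples, label = s,
        subject_id = record$subject_id, window_index = w)
    }
    counts[s] <- n_win
  }
  if (length(shortfall) > 0)
    stop("insufficient samples for state(s): ",
         paste(shortfall, collapse = "; "), call. = FALSE)
  structure(list(windows = windows, per_class_counts = counts),
            class = "dataset_split")
}

#' @export
print.dataset_split <- function(x, ...) {
  cat("<dataset_split>", length(x$windows), "windows;",
      paste(names(x$per_class_counts), x$per_class_counts,
            sep = "=", collapse = " "), "\n")
  invisible(x)
}

window_labels <- function(split) {
  vapply(split$windows, `[[`, "", "label")
}

#' Write / read an EEG record as CSV
#'
#' `write_record()` writes two files: `<path>` with columns
#' `time_s, eeg_uv` and a companion `<path minus .csv>.bis.csv` with
#' columns `time_s, bis`. `read_record()` reads them back; signal values
#' round-trip to better than 1e-6 uV.
#'
#' @param record an `eeg_record`.
#' @param path CSV path for the signal file (companion BIS path derived
#'   from it).
#' @param fs sampling rate used to re-derive timing on read (taken from
#'   the time column spacing; `fs` is a fallback when the file has a
#'   single row).
#' @return `read_record()` returns an `eeg_record`; `write_record()`
#'   returns `path` invisibly.
#' @export
write_record <- function(record, path) {
  stopifnot(inherits(record, "eeg_record"))
  t <- (seq_along(record$signal) - 1) / record$fs
  data.table::fwrite(data.table::data.table(time_s = t,
                                            eeg_uv = record$signal), path)
  bis_path <- bis_companion_path(path)
  tb <- seq_along(record$bis_trace) * 5
  data.table::fwrite(data.table::data.table(time_s = tb,
                                            bis = record$bis_trace), bis_path)
  invisible(path)
}

#' @rdname write_record
#' @param subject_id identifier attached to the record on read.
#' @export
read_record <- function(path, subject_id = basename(path), fs = 128) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  dt <- tryCatch(suppressWarnings(data.table::fread(path)),
                 error = function(e) stop("parse error in ", path, ": ",
                                          conditionMessage(e), call. = FALSE))
  if (nrow(dt) == 0 || ncol(dt) < 2)
    stop("parse error in ", path, ": expected columns time_s, eeg_uv",
         call. = FALSE)
  tcol <- as.numeric(dt[[1]]); sig <- as.numeric(dt[[2]])
  if (any(!is.finite(tcol)) || any(!is.finite(sig)))
    stop("parse error in ", path, ": non-numeric values", call. = FALSE)
  if (nrow(dt) >= 2) {
    dtm <- diff(tcol)
    if (any(dtm <= 0))
      stop("parse error in ", path, ": time column not strictly increasing (row ",
           which(dtm <= 0)[1] + 1, ")", call. = FALSE)
    fs <- 1 / stats::median(dtm)
  }
  bis_path <- bis_companion_path(path)
  bis <- numeric(0)
  if (file.exists(bis_path)) {
    db <- data.table::fread(bis_path)
    if (nrow(db) == 0 || ncol(db) < 2)
      stop("parse error in ", bis_path, ": expected columns time_s, bis",
           call. = FALSE)
    tb <- as.numeric(db[[1]])
    if (length(tb) >= 2 && any(diff(tb) <= 0))
      stop("parse error in ", bis_path,
           ": time column not strictly increasing (row ",
           which(diff(tb) <= 0)[1] + 1, ")", call. = FALSE)
    bis <- as.numeric(db[[2]])
  }
  structure(list(signal = sig, fs = fs, bis_trace = bis,
                 subject_id = subject_id, seed = NA_integer_,
                 state_spans = NULL),
            class = "eeg_record")
}

bis_companion_path <- function(path) {
  sub("\\.csv$", ".bis.csv", path)
}
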