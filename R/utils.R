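# internal helpers shared across modules

#' @useDynLib anesdepth, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats var sd rnorm runif fft ar.burg spline splinefun
#'   quantile median lm.fit
NULL

# Evaluate `expr` under a fixed RNG seed and restore the caller's RNG state,
# so every generator is a pure function of its arguments.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("`seed` must be a single finite number", call. = FALSE)
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic child-seed chain: keeps derived seeds in (0, 2^31 - 1).
child_seed <- function(seed, index) {
  m <- 2147483647
  s <- (abs(as.double(seed)) %% m)
  as.integer(((s * 48271) %% m + 7919 * (as.double(index) %% m)) %% m + 1)
}

stopifnot_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stop(sprintf("`%s` must be a single positive number", name), call. = FALSE)
  invisible(x)
}
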