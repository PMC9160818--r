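#' Fit a pooled-covariance linear discriminant model
#'
#' Standardises features with training-set means and SDs, computes per
#' class mean vectors and the pooled within-class covariance, and
#' stores the linear discriminant
#' `D_c(x) = mu_c' S^-1 x - (1/2) mu_c' S^-1 mu_c (+ log prior)`.
#' With few instances and many features the pooled covariance is
#' singular, so it is shrunk toward its diagonal,
#' `S <- (1 - lambda) S + lambda diag(S)`, before inversion; see the
#' methods vignette for why this matters at 16 windows by 17+ features.
#'
#' @param x numeric feature matrix or a `feature_matrix`.
#' @param labels class labels (ignored when `x` carries them).
#' @param lambda diagonal shrinkage weight in `[0, 1]`.
#' @param priors named per-class priors; default uniform (the windowing
#'   protocol is class-balanced).
#' @return An `lda_model`.
#' @export
fit_lda <- function(x, labels = NULL, lambda = 1e-3, priors = NULL) {
  if (inherits(x, "feature_matrix")) {
    if (is.null(labels)) labels <- x$labels
    x <- x$x
  }
  x <- as.matrix(x)
  labels <- as.character(labels)
  if (length(labels) != nrow(x))
    stop("labels do not match rows", call. = FALSE)
  classes <- sort(unique(labels))
  if (length(classes) < 2) stop("need >= 2 classes", call. = FALSE)
  counts <- table(labels)
  if (any(counts < 2))
    stop("class(es) with < 2 instances: ",
         paste(names(counts)[counts < 2], collapse = ", "), call. = FALSE)
  if (lambda < 0 || lambda > 1) stop("`lambda` must be in [0, 1]",
                                     call. = FALSE)

  mu <- colMeans(x)
  sdev <- apply(x, 2, stats::sd)
  sdev[sdev == 0] <- 1                 # constant columns carry no signal
  z <- scale(x, center = mu, scale = sdev)

  means <- do.call(rbind, lapply(classes, function(c)
    colMeans(z[labels == c, , drop = FALSE])))
  rownames(means) <- classes
  pooled <- matrix(0, ncol(z), ncol(z))
  for (c in classes) {
    zc <- z[labels == c, , drop = FALSE]
    pooled <- pooled + crossprod(scale(zc, scale = FALSE))
  }
  pooled <- pooled / (nrow(z) - length(classes))
  d <- diag(pooled)
  d[d <= 0] <- mean(d[d > 0])
  shrunk <- (1 - lambda) * pooled + lambda * diag(d, ncol(z))
  inv <- tryCatch(solve(shrunk), error = function(e) {
    warning("pooled covariance near-singular even after shrinkage; ",
            "adding ridge", call. = FALSE)
    solve(shrunk + diag(1e-6 * mean(d), ncol(z)))
  })

  if (is.null(priors)) priors <- stats::setNames(
    rep(1 / length(classes), length(classes)), classes)
  structure(list(classes = classes, class_means = means,
                 pooled_cov = shrunk, inv_cov = inv,
                 priors = priors[classes], lambda = lambda,
                 standardization = list(center = mu, scale = sdev)),
            class = "lda_model")
}

#' @export
print.lda_model <- function(x, ...) {
  cat("<lda_model>", length(x$classes), "classes,",
      ncol(x$class_means), "features, shrinkage lambda =", x$lambda, "\n")
  invisible(x)
}

#' Predict classes with a fitted discriminant model
#'
#' Evaluates each class's linear discriminant score on the (internally
#' standardised) input and returns the argmax class; exact ties resolve
#' to the earlier class in the model's class order.
#'
#' @param object an `lda_model`.
#' @param newdata numeric vector (one instance) or matrix (rows =
#'   instances).
#' @param ... unused.
#' @return Character vector of predicted class labels.
#' @export
predict.lda_model <- function(object, newdata, ...) {
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1)
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != ncol(object$class_means))
    stop(sprintf("feature dimension mismatch: model has %d, data has %d",
                 ncol(object$class_means), ncol(newdata)), call. = FALSE)
  z <- scale(newdata, center = object$standardization$center,
             scale = object$standardization$scale)
  scores <- vapply(seq_along(object$classes), function(ci) {
    m <- object$class_means[ci, ]
    a <- object$inv_cov %*% m
    as.numeric(z %*% a) - 0.5 * sum(m * a) + log(object$priors[ci])
  }, numeric(nrow(z)))
  if (is.null(dim(scores))) scores <- matrix(scores, nrow = 1)
  object$classes[apply(scores, 1, which.max)]
}

#' Stratified k-fold cross-validated accuracy
#'
#' Shuffles instances under the seed, assigns folds stratified by class
#' where possible (fold sizes differ by at most one), and for each fold
#' fits the discriminant (including the standardisation) on the
#' training folds only, predicting the held-out instances. Accuracy is
#' total correct over total held-out predictions, in percent.
#'
#' @param x feature matrix or `feature_matrix`.
#' @param labels class labels.
#' @param k number of folds (default 10).
#' @param seed integer fold-assignment seed.
#' @param lambda shrinkage passed to [fit_lda()].
#' @return A `cv_result`: `accuracy` (%), `per_fold_accuracy`,
#'   `fold_assignments`, `predictions`, `k`, `seed`.
#' @export
kfold_cv <- function(x, labels = NULL, k = 10, seed = 1, lambda = 1e-3) {
  if (inherits(x, "feature_matrix")) {
    if (is.null(labels)) labels <- x$labels
    x <- x$x
  }
  x <- as.matrix(x)
  labels <- as.character(labels)
  n <- nrow(x)
  if (k > n) stop("k exceeds the number of instances", call. = FALSE)
  folds <- integer(n)
  with_seed(seed, {
    # stratified round-robin over a shuffled within-class order, with a
    # rotating fold offset so small classes spread across folds
    offset <- 0L
    for (c in unique(labels)) {
      idx <- sample(which(labels == c))
      folds[idx] <- ((seq_along(idx) - 1L + offset) %% k) + 1L
      offset <- offset + length(idx)
    }
  })
  preds <- character(n)
  per_fold <- numeric(k)
  for (f in seq_len(k)) {
    test <- folds == f
    if (!any(test)) { per_fold[f] <- NA; next }
    model <- fit_lda(x[!test, , drop = FALSE], labels[!test],
                     lambda = lambda)
    preds[test] <- predict(model, x[test, , drop = FALSE])
    per_fold[f] <- mean(preds[test] == labels[test]) * 100
  }
  structure(list(accuracy = mean(preds == labels) * 100,
                 per_fold_accuracy = per_fold,
                 fold_assignments = folds, predictions = preds,
                 k = as.integer(k), seed = seed),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %d-fold accuracy: %.1f%%\n", x$k, x$accuracy))
  invisible(x)
}
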