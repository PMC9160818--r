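test_that("class means and reproducibility of the fit", {
  x <- matrix(c(0, 0.1, 2, 2.1), ncol = 1)
  lab <- c("a", "a", "b", "b")
  m <- fit_lda(x, lab)
  # class means are stored standardised; undo to compare with arithmetic
  raw_means <- m$class_means[, 1] * m$standardization$scale[1] +
    m$standardization$center[1]
  expect_equal(unname(raw_means), c(0.05, 2.05), tolerance = 1e-9)
  expect_identical(fit_lda(x, lab), fit_lda(x, lab))
  expect_error(fit_lda(x, c("a", "b", "b", "b")), "a")
})

test_that("duplicated columns are handled by shrinkage", {
  set.seed(91)
  base <- matrix(stats::rnorm(40), ncol = 2)
  x <- cbind(base, base[, 1])
  lab <- rep(c("a", "b"), each = 10)
  x[lab == "b", ] <- x[lab == "b", ] + 2
  m <- fit_lda(x, lab)
  expect_true(all(is.finite(m$inv_cov)))
  expect_identical(predict(m, x[1, ]), "a")
})

test_that("prediction follows the linear discriminant rule", {
  # symmetric clusters with means exactly (0,0) and (2,0)
  base <- rbind(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))
  x <- rbind(base, sweep(base, 2, c(2, 0), `+`))
  lab <- rep(c("c1", "c2"), each = 4)
  m <- fit_lda(x, lab)
  expect_identical(predict(m, c(2, 0)), "c2")
  expect_identical(predict(m, c(0, 0)), "c1")
  # exact tie resolves to the first class in order
  expect_identical(predict(m, c(1, 0)), "c1")
  expect_error(predict(m, c(1, 2, 3)), "dimension mismatch")
})

test_that("decisions agree with an explicit shared-covariance Bayes rule", {
  set.seed(92)
  p <- 4
  mu1 <- rep(0, p); mu2 <- c(1.5, -1, 0.5, 0); mu3 <- c(-1, 1, 1, -0.5)
  A <- matrix(stats::rnorm(p * p), p)
  S <- crossprod(A) / p + diag(p)
  ch <- chol(S)
  draw <- function(mu, n) sweep(matrix(stats::rnorm(n * p), n) %*% ch,
                                2, mu, `+`)
  xtr <- rbind(draw(mu1, 60), draw(mu2, 60), draw(mu3, 60))
  lab <- rep(c("g1", "g2", "g3"), each = 60)
  model <- fit_lda(xtr, lab, lambda = 0)
  xte <- rbind(draw(mu1, 170), draw(mu2, 170), draw(mu3, 160))
  got <- predict(model, xte)

  # oracle: evaluate the shared-covariance Gaussian density per class,
  # with moments estimated the same way, and take the argmax
  zc <- scale(xtr, center = model$standardization$center,
              scale = model$standardization$scale)
  zt <- scale(xte, center = model$standardization$center,
              scale = model$standardization$scale)
  means <- t(vapply(sort(unique(lab)), function(cl)
    colMeans(zc[lab == cl, , drop = FALSE]), numeric(p)))
  pooled <- Reduce(`+`, lapply(sort(unique(lab)), function(cl)
    crossprod(scale(zc[lab == cl, , drop = FALSE], scale = FALSE)))) /
    (nrow(zc) - 3)
  Sin <- solve(pooled)
  loglik <- vapply(1:3, function(ci) {
    d <- sweep(zt, 2, means[ci, ])
    -0.5 * rowSums((d %*% Sin) * d)
  }, numeric(nrow(zt)))
  bayes <- sort(unique(lab))[apply(loglik, 1, which.max)]
  expect_gte(mean(got == bayes), 0.99)
})

test_that("cross-validation separates separable clusters and not noise", {
  set.seed(93)
  x <- rbind(matrix(stats::rnorm(100), ncol = 2),
             matrix(stats::rnorm(100, mean = 10), ncol = 2))
  lab <- rep(c("lo", "hi"), each = 50)
  cv <- kfold_cv(x, lab, k = 10, seed = 1)
  expect_equal(cv$accuracy, 100)
  # fold sizes differ by at most one
  expect_lte(diff(range(table(cv$fold_assignments))), 1)
  # chance level on permuted labels of 4 balanced classes
  x4 <- matrix(stats::rnorm(800), ncol = 2)
  lab4 <- with_seed_test(94, sample(rep(c("a", "b", "c", "d"), 100)))
  cv4 <- kfold_cv(x4, lab4, k = 10, seed = 2)
  expect_gt(cv4$accuracy, 10)
  expect_lt(cv4$accuracy, 40)
  expect_error(kfold_cv(x[1:5, ], lab[1:5], k = 10), "k exceeds")
})

test_that("the same seed reproduces folds and accuracy exactly", {
  fm <- fixture_features()
  cv1 <- kfold_cv(fm, seed = 7)
  cv2 <- kfold_cv(fm, seed = 7)
  expect_identical(cv1, cv2)
})

test_that("decisions are invariant under consistent affine transforms", {
  set.seed(95)
  x <- rbind(matrix(stats::rnorm(80), ncol = 4),
             sweep(matrix(stats::rnorm(80), ncol = 4), 2,
                   c(3, -2, 1, 0), `+`))
  lab <- rep(c("a", "b"), each = 20)
  xt <- matrix(stats::rnorm(200), ncol = 4)
  m1 <- fit_lda(x, lab)
  p1 <- predict(m1, xt)
  scale_v <- c(2, 0.5, 10, 1)
  shift <- c(100, -5, 0, 3)
  x2 <- sweep(sweep(x, 2, scale_v, `*`), 2, shift, `+`)
  xt2 <- sweep(sweep(xt, 2, scale_v, `*`), 2, shift, `+`)
  m2 <- fit_lda(x2, lab)
  expect_identical(predict(m2, xt2), p1)
})
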