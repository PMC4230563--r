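test_that("N = 2 model matches the closed form", {
  set.seed(51)
  X1 <- rnorm(30); X2 <- rnorm(30)
  pdm <- build_pdm(rbind(X1, X2), k = 1)
  expect_equal(pdm$mean, (X1 + X2) / 2)
  expect_equal(pdm$eigenvalues[1], sum((X2 - X1)^2) / 2) # 1/(N-1) convention
  d <- (X2 - X1) / sqrt(sum((X2 - X1)^2))
  expect_equal(abs(sum(pdm$eigenvectors[, 1] * d)), 1, tolerance = 1e-10)
})

test_that("collinear shapes give exactly one nonzero eigenvalue", {
  base <- rnorm(60); d <- rnorm(60)
  shapes <- rbind(base - d, base, base + d)
  pdm <- build_pdm(shapes, k = 2)
  expect_equal(pdm$eigenvalues[1], sum(d^2), tolerance = 1e-8)
  expect_lt(pdm$eigenvalues[2] / pdm$eigenvalues[1], 1e-10)
  expect_equal(variance_spectrum(pdm)$percent[1], 100, tolerance = 1e-6)
})

test_that("Gram-trick eigenpairs equal the dense covariance decomposition", {
  set.seed(53)
  N <- 10; m <- 200
  X <- matrix(rnorm(N * 3 * m), N)
  pdm <- build_pdm(X, k = N - 1)
  A <- sweep(X, 2, colMeans(X))
  D <- crossprod(A) / (N - 1)
  ed <- eigen(D, symmetric = TRUE)
  expect_equal(pdm$eigenvalues, ed$values[seq_len(N - 1)], tolerance = 1e-8)
  for (q in seq_len(N - 1)) {
    # eigen equation residual and direction agreement up to sign
    expect_lt(max(abs(D %*% pdm$eigenvectors[, q] -
                        pdm$eigenvalues[q] * pdm$eigenvectors[, q])),
              1e-8 * pdm$eigenvalues[1])
    expect_equal(abs(sum(pdm$eigenvectors[, q] * ed$vectors[, q])), 1,
                 tolerance = 1e-8)
  }
  expect_equal(crossprod(pdm$eigenvectors), diag(N - 1), tolerance = 1e-10)
})

test_that("projection and reconstruction are mutually consistent", {
  set.seed(55)
  X <- matrix(rnorm(8 * 90), 8)
  pdm <- build_pdm(X, k = 7)
  # mean projects to zero; a pure mode projects to its amplitude
  expect_equal(pdm_project(pdm, pdm$mean), rep(0, 7))
  expect_equal(pdm_project(pdm, pdm$mean + 2 * pdm$eigenvectors[, 1]),
               c(2, rep(0, 6)), tolerance = 1e-10)
  expect_equal(pdm_reconstruct(pdm, rep(0, 7)), pdm$mean)
  # training shapes are in the span with k = N-1
  for (i in c(1, 5, 8)) {
    expect_equal(pdm_reconstruct(pdm, pdm_project(pdm, X[i, ])), X[i, ],
                 tolerance = 1e-8)
  }
  # variance of training coefficients equals the eigenvalues
  b <- pdm_project(pdm, X)
  expect_equal(apply(b, 2, var), pdm$eigenvalues, tolerance = 1e-8)
})

test_that("the model is order-invariant after sign canonicalisation", {
  set.seed(57)
  X <- matrix(rnorm(7 * 120), 7)
  p1 <- build_pdm(X, k = 3)
  p2 <- build_pdm(X[sample(7), ], k = 3)
  expect_equal(p1$mean, p2$mean)
  expect_equal(p1$eigenvalues, p2$eigenvalues, tolerance = 1e-10)
  expect_equal(p1$eigenvectors, p2$eigenvectors, tolerance = 1e-8)
})

test_that("variance-threshold mode selection and input validation work", {
  set.seed(59)
  lam <- c(10, 5, 1, 0.1, 0.05)
  V <- qr.Q(qr(matrix(rnorm(60 * 5), 60)))
  B <- matrix(rnorm(40 * 5), 40) %*% diag(sqrt(lam))
  X <- B %*% t(V)
  pdm <- build_pdm(X, k = 0.90)
  spec <- variance_spectrum(pdm)
  expect_gte(spec$cumulative[pdm$k], 90)
  expect_true(pdm$k == 1 || spec$cumulative[pdm$k - 1] < 90)
  expect_equal(spec$cumulative[length(spec$cumulative)], 100, tolerance = 1e-8)

  expect_error(build_pdm(X[1, , drop = FALSE]), "at least N = 2")
  expect_error(build_pdm(list(rnorm(9), rnorm(12))), "mismatched")
})
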