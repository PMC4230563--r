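test_that("single-component fit is the closed-form MLE", {
  set.seed(61)
  x <- rnorm(500, 4, 2)
  g <- fit_em(x, 1)
  expect_equal(g$means, mean(x))
  expect_equal(g$variances, var(x) * 499 / 500) # 1/n convention
  expect_equal(g$weights, 1)
})

test_that("EM recovers a well-separated two-component mixture", {
  set.seed(63)
  x <- c(rnorm(1000, -3, 0.5), rnorm(1000, 3, 0.5))
  g <- fit_em(x, 2, seed = 1)
  expect_lt(max(abs(g$means - c(-3, 3))), 0.1)
  expect_lt(max(abs(g$weights - 0.5)), 0.05)
  expect_lt(max(abs(sqrt(g$variances) - 0.5)), 0.1)
  # log-likelihood trace is nondecreasing
  tr <- attr(g, "trace")
  expect_true(all(diff(tr) >= -1e-8))
})

test_that("EM fit agrees with an independent mixture implementation", {
  skip_if_not_installed("mclust")
  suppressPackageStartupMessages(library(mclust))
  set.seed(65)
  x <- c(rnorm(700, -2, 0.7), rnorm(300, 2.5, 0.5))
  g <- fit_em(x, 2, seed = 1)
  mc <- mclust::Mclust(x, G = 2, modelNames = "V", verbose = FALSE)
  o <- order(mc$parameters$mean)
  expect_equal(g$means, mc$parameters$mean[o], tolerance = 0.05,
               ignore_attr = TRUE)
  expect_equal(g$weights, mc$parameters$pro[o], tolerance = 0.03)
  expect_equal(attr(g, "loglik"), mc$loglik, tolerance = 1e-3)
})

test_that("BIC selects one component for unimodal, two for bimodal data", {
  hits1 <- 0L
  for (s in 1:5) {
    x <- draw_mode_coefficients(1000, 2, bimodal = FALSE, seed = 100 + s)
    if (select_components(x, r_max = 3, seed = s)$r == 1L) hits1 <- hits1 + 1L
  }
  expect_gte(hits1, 4L) # r = 1 wins with probability > 0.9

  x2 <- draw_mode_coefficients(1000, 8, bimodal = TRUE, seed = 9)
  sel <- select_components(x2, r_max = 3, seed = 1)
  expect_equal(sel$r, 2L)
  diag <- attr(sel, "diagnostics")
  expect_equal(diag$r, 1:3)
  expect_equal(diag$bic[2], min(diag$bic))
})

test_that("sample-size preconditions are enforced", {
  expect_error(fit_em(rnorm(3), 2), "at least 2r")
  # candidates with too few samples are skipped by the selector
  sel <- select_components(rnorm(5), r_max = 3)
  expect_lte(sel$r, 2L)
  expect_error(fit_em(rep(1, 10), 1), "zero-variance")
})

test_that("mixture CDF inversion is exact to 1e-10", {
  # single Gaussian median
  g1 <- gmm1d(1, 3, 4)
  expect_equal(mixture_quantile(g1, 0.5), 3, tolerance = 1e-9)
  expect_equal(mixture_quantile(g1, stats::pnorm(1)), 5, tolerance = 1e-8)
  # symmetric mixture median is zero
  g2 <- gmm1d(c(0.5, 0.5), c(-4, 4), c(1.5, 1.5))
  expect_equal(mixture_quantile(g2, 0.5), 0, tolerance = 1e-9)
  expect_error(mixture_quantile(g2, 1), "inside")

  set.seed(67)
  for (rep in 1:10) {
    r <- sample(1:3, 1)
    w <- runif(r); w <- w / sum(w)
    g <- gmm1d(w, rnorm(r, 0, 5), runif(r, 0.2, 4))
    u <- runif(20, 0.001, 0.999)
    W <- mixture_quantile(g, u)
    expect_lt(max(abs(mixture_cdf(g, W) - u)), 1e-10)
  }
})

test_that("inversion sampling reproduces the fitted distribution", {
  set.seed(69)
  x <- c(rnorm(800, -2, 0.8), rnorm(1200, 3, 1.2))
  cm <- fit_coefficient_models(cbind(x), r_max = 3, seed = 2)
  W <- sample_coefficients(cm, 1e4, seed = 5)
  expect_identical(W, sample_coefficients(cm, 1e4, seed = 5)) # seeded determinism
  g <- cm$mixtures[[1]]
  # one-sample KS statistic against the mixture CDF
  emp <- ecdf(W[, 1])
  xs <- sort(W[, 1])
  ks <- max(abs(emp(xs) - mixture_cdf(g, xs)),
            abs(emp(xs) - 1 / 1e4 - mixture_cdf(g, xs)))
  expect_lt(ks, 0.02)
  # moments match the mixture identities within 5%
  mo <- gmm_moments(g)
  expect_lt(abs(var(W[, 1]) - mo["variance"]) / mo["variance"], 0.05)
  expect_lt(abs(mean(W[, 1]) - mo["mean"]), 3 * sqrt(mo["variance"] / 1e4) + 0.05)
})
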