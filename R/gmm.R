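#' 1-D Gaussian mixtures for mode coefficients
#'
#' The density of each retained mode coefficient is modelled as
#' `p(b) = sum_l w_l N(b; mu_l, S_l)` with weights summing to one and
#' positive variances. New coefficients are drawn by inverting the mixture
#' CDF.
#'
#' @param weights,means,variances component parameters (equal lengths).
#' @return an object of class `gmm1d`.
#' @export
gmm1d <- function(weights, means, variances) {
  stopifnot(length(weights) == length(means), length(means) == length(variances))
  if (abs(sum(weights) - 1) > 1e-12) stop("weights must sum to 1")
  if (any(variances <= 0)) stop("variances must be positive")
  o <- order(means)
  structure(list(weights = weights[o], means = means[o], variances = variances[o],
                 r = length(weights)),
            class = "gmm1d")
}

#' @export
print.gmm1d <- function(x, ...) {
  cat(sprintf("gmm1d with %d component(s):\n", x$r))
  for (l in seq_len(x$r)) {
    cat(sprintf("  w = %.3f, mu = %.4g, sd = %.4g\n",
                x$weights[l], x$means[l], sqrt(x$variances[l])))
  }
  invisible(x)
}

gmm_log_density <- function(gmm, x) {
  lp <- vapply(seq_len(gmm$r), function(l) {
    log(gmm$weights[l]) + stats::dnorm(x, gmm$means[l], sqrt(gmm$variances[l]), log = TRUE)
  }, numeric(length(x)))
  if (length(x) == 1L) lp <- matrix(lp, 1L)
  mx <- apply(lp, 1L, max)
  mx + log(rowSums(exp(lp - mx)))
}

#' Moments of a 1-D Gaussian mixture
#'
#' Mean `sum w_l mu_l` and variance
#' `sum w_l (S_l + mu_l^2) - (sum w_l mu_l)^2`.
#'
#' @param gmm a [gmm1d()].
#' @return named vector `c(mean, variance)`.
#' @export
gmm_moments <- function(gmm) {
  mu <- sum(gmm$weights * gmm$means)
  v <- sum(gmm$weights * (gmm$variances + gmm$means^2)) - mu^2
  c(mean = mu, variance = v)
}

#' Fit a 1-D Gaussian mixture by EM
#'
#' Maximum-likelihood fit with the expectation-maximisation algorithm.
#' For `r = 1` the closed-form MLE (sample mean, 1/n variance) is the EM
#' fixed point and is returned directly. Otherwise EM is run from a
#' quantile-split initialisation plus `restarts` randomly perturbed
#' restarts, keeping the best log-likelihood. The log-likelihood is
#' nondecreasing over iterations; a component whose variance falls below
#' the floor (`1e-8` x sample variance) triggers a restart.
#'
#' @param samples numeric coefficient values (`n >= 2r`).
#' @param r number of components.
#' @param seed integer seed for the restart perturbations.
#' @param max_iter,tol EM stopping rule: stop when the log-likelihood
#'   improves by less than `tol` or after `max_iter` iterations.
#' @param restarts number of perturbed restarts beyond the deterministic
#'   initialisation.
#' @return a [gmm1d()] with attributes `loglik` (final value), `trace`
#'   (per-iteration log-likelihoods of the winning run) and `n`.
#' @export
fit_em <- function(samples, r, seed = 1L, max_iter = 500L, tol = 1e-8,
                   restarts = 5L) {
  x <- as.numeric(samples)
  n <- length(x)
  if (r < 1L) stop("r must be >= 1")
  if (n < 2L * r) stop(sprintf("need at least 2r = %d samples, got %d", 2L * r, n))
  sv <- stats::var(x) * (n - 1) / n
  if (sv <= 0) {
    if (r > 1L) stop("all samples identical: only r = 1 with zero variance is degenerate")
    stop("zero-variance samples violate the variance floor")
  }
  floor_var <- 1e-8 * sv
  if (r == 1L) {
    g <- gmm1d(1, mean(x), sv)
    attr(g, "loglik") <- sum(gmm_log_density(g, x))
    attr(g, "trace") <- attr(g, "loglik")
    attr(g, "n") <- n
    return(g)
  }

  run_em <- function(mu0, var0, w0) {
    w <- w0; mu <- mu0; s2 <- pmax(var0, floor_var)
    ll_trace <- numeric(0)
    ll_old <- -Inf
    for (it in seq_len(max_iter)) {
      lp <- vapply(seq_len(r), function(l) {
        log(w[l]) + stats::dnorm(x, mu[l], sqrt(s2[l]), log = TRUE)
      }, numeric(n))
      mx <- apply(lp, 1L, max)
      ll <- sum(mx + log(rowSums(exp(lp - mx))))
      ll_trace <- c(ll_trace, ll)
      resp <- exp(lp - mx - log(rowSums(exp(lp - mx))))
      nk <- colSums(resp)
      if (any(nk < 1e-10)) return(NULL) # collapsed component
      w <- nk / n
      mu <- colSums(resp * x) / nk
      s2 <- colSums(resp * outer(x, mu, `-`)^2) / nk
      if (any(s2 < floor_var)) return(NULL) # variance collapse -> restart
      if (is.finite(ll_old) && ll - ll_old < tol) break
      ll_old <- ll
    }
    list(w = w, mu = mu, s2 = s2, ll = ll_trace[length(ll_trace)], trace = ll_trace)
  }

  qs <- stats::quantile(x, probs = (seq_len(r) - 0.5) / r, names = FALSE)
  grp <- integer(n); grp[order(x)] <- ceiling(seq_len(n) * r / n)
  mu0 <- vapply(seq_len(r), function(l) mean(x[grp == l]), numeric(1))
  var0 <- vapply(seq_len(r), function(l) {
    xl <- x[grp == l]
    if (length(xl) > 1L) stats::var(xl) else sv / r
  }, numeric(1))
  mu0[!is.finite(mu0)] <- qs[!is.finite(mu0)]
  var0[!is.finite(var0) | var0 <= 0] <- sv / r

  best <- NULL
  old_seed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(as.integer(seed) %% .Machine$integer.max)
  inits <- c(list(list(mu = mu0, var = var0)),
             lapply(seq_len(restarts), function(i) {
               list(mu = mu0 + stats::rnorm(r, 0, sqrt(sv) / 2),
                    var = var0 * stats::runif(r, 0.5, 2))
             }))
  for (ini in inits) {
    res <- run_em(ini$mu, ini$var, rep(1 / r, r))
    if (!is.null(res) && (is.null(best) || res$ll > best$ll)) best <- res
  }
  if (is.null(best)) {
    stop("EM failed: all runs collapsed a component; try smaller r")
  }
  g <- gmm1d(best$w, best$mu, best$s2)
  attr(g, "loglik") <- best$ll
  attr(g, "trace") <- best$trace
  attr(g, "n") <- n
  g
}

#' Choose the number of mixture components by BIC
#'
#' Fits `r = 1..r_max` by [fit_em()] (skipping any `r` with fewer than `2r`
#' samples) and returns the mixture minimising
#' `BIC = -2 logL + (3r - 1) log n`.
#'
#' @inheritParams fit_em
#' @param r_max largest component count to try (default 3).
#' @return the winning [gmm1d()], with attribute `diagnostics`: a data
#'   frame of `r`, `loglik` and `bic` for every candidate fitted.
#' @export
select_components <- function(samples, r_max = 3L, seed = 1L, ...) {
  n <- length(samples)
  fits <- list(); rows <- list()
  for (r in seq_len(r_max)) {
    if (n < 2L * r) next
    g <- tryCatch(fit_em(samples, r, seed = seed, ...), error = function(e) NULL)
    if (is.null(g)) next
    ll <- attr(g, "loglik")
    bic <- -2 * ll + (3 * r - 1) * log(n)
    fits[[as.character(r)]] <- g
    rows[[as.character(r)]] <- data.frame(r = r, loglik = ll, bic = bic)
  }
  if (length(fits) == 0L) stop("no mixture could be fitted")
  diag <- do.call(rbind, rows)
  best <- fits[[which.min(diag$bic)]]
  attr(best, "diagnostics") <- diag
  best
}

#' Mixture CDF and its inverse
#'
#' `mixture_cdf` evaluates `F(x) = sum_l w_l Phi((x - mu_l)/sqrt(S_l))`;
#' `mixture_quantile` inverts it by bracketed bisection to machine
#' precision in `x`, so that `|F(F^-1(u)) - u| < 1e-10`.
#'
#' @param gmm a [gmm1d()].
#' @param x quantile values (vectorised).
#' @param u probabilities in (0, 1) (vectorised).
#' @return numeric vector.
#' @export
mixture_cdf <- function(gmm, x) {
  stopifnot(inherits(gmm, "gmm1d"))
  out <- 0
  for (l in seq_len(gmm$r)) {
    out <- out + gmm$weights[l] * stats::pnorm(x, gmm$means[l], sqrt(gmm$variances[l]))
  }
  out
}

#' @rdname mixture_cdf
#' @export
mixture_quantile <- function(gmm, u) {
  stopifnot(inherits(gmm, "gmm1d"))
  if (any(u <= 0 | u >= 1)) stop("u must lie strictly inside (0, 1)")
  sd_max <- sqrt(max(gmm$variances))
  lo <- rep(min(gmm$means) - 15 * sd_max, length(u))
  hi <- rep(max(gmm$means) + 15 * sd_max, length(u))
  # vectorised bisection: ~90 halvings take the bracket below 1e-20 relative
  for (it in 1:200) {
    mid <- 0.5 * (lo + hi)
    below <- mixture_cdf(gmm, mid) < u
    lo[below] <- mid[below]
    hi[!below] <- mid[!below]
    if (max(hi - lo) < 1e-14 * max(1, sd_max)) break
  }
  0.5 * (lo + hi)
}

#' Per-mode coefficient models
#'
#' Fits one Gaussian mixture per retained PCA mode to the training
#' coefficients, selecting the component count by BIC.
#'
#' @param b `N x k` matrix of training coefficients ([pdm_project()] of the
#'   training shapes).
#' @param r_max largest component count per mode.
#' @param seed integer seed.
#' @return an object of class `coefficient_model`: list of [gmm1d()] per
#'   mode, with `k` and the per-mode BIC diagnostics.
#' @export
fit_coefficient_models <- function(b, r_max = 3L, seed = 1L) {
  b <- as.matrix(b)
  mixtures <- lapply(seq_len(ncol(b)), function(q) {
    select_components(b[, q], r_max = r_max, seed = seed + q)
  })
  structure(list(mixtures = mixtures, k = ncol(b)),
            class = "coefficient_model")
}

#' @export
print.coefficient_model <- function(x, ...) {
  rs <- vapply(x$mixtures, `[[`, 0L, "r")
  cat(sprintf("coefficient_model: %d modes; components per mode: %s\n",
              x$k, paste(rs, collapse = ", ")))
  invisible(x)
}

#' Draw new mode coefficients by inversion sampling
#'
#' For each mode q, draws i.i.d. uniforms u on (0, 1) and maps them through
#' the fitted mixture's inverse CDF, `W = F^-1(u)`. Reproducible given the
#' seed.
#'
#' @param model a [fit_coefficient_models()] result.
#' @param n_samples number of coefficient rows to draw.
#' @param seed integer seed.
#' @return an `n_samples x k` matrix `W`.
#' @export
sample_coefficients <- function(model, n_samples, seed = 1L) {
  stopifnot(inherits(model, "coefficient_model"))
  old_seed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(as.integer(seed) %% .Machine$integer.max)
  U <- matrix(stats::runif(n_samples * model$k), n_samples, model$k)
  W <- matrix(NA_real_, n_samples, model$k)
  for (q in seq_len(model$k)) {
    W[, q] <- mixture_quantile(model$mixtures[[q]], U[, q])
  }
  W
}
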