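#' Build a point-distribution model by PCA of corresponded shape vectors
#'
#' Each training shape is a 3m-element vector stacking the (x, y, z) of its
#' m corresponded surface points. The model is the mean shape plus the
#' leading eigenvectors of the sample covariance
#' `D = 1/(N-1) sum_i (X_i - Xbar)(X_i - Xbar)^T`. Because 3m >> N, the
#' eigenpairs are computed from the N x N Gram matrix (dual PCA) without
#' ever materialising D; the equivalence with the dense decomposition is a
#' tested property, not an assumption. Eigenvector signs are canonicalised
#' so the largest-magnitude component of each mode is positive, making the
#' model reproducible across linear-algebra backends and shape orderings.
#'
#' @param shapes an `N x 3m` matrix (rows are shape vectors) or a list of
#'   equal-length vectors / `m x 3` point matrices.
#' @param k number of modes to retain; alternatively a fraction in (0, 1)
#'   interpreted as the cumulative variance threshold (default 0.90).
#' @return an object of class `pdm`: list with `mean` (3m), `eigenvectors`
#'   (3m x k, orthonormal columns), `eigenvalues` (all N-1 nonnegative
#'   values, descending), `k`, `N_train`, `m`.
#' @export
build_pdm <- function(shapes, k = 0.90) {
  X <- shapes_to_matrix(shapes)
  N <- nrow(X)
  if (N < 2L) stop("need at least N = 2 training shapes")
  if (ncol(X) %% 3L != 0L) stop("shape vectors must have length divisible by 3")
  mean_shape <- colMeans(X)
  A <- sweep(X, 2L, mean_shape) # N x 3m, centred
  G <- tcrossprod(A) / (N - 1)  # N x N Gram matrix
  eg <- eigen(G, symmetric = TRUE)
  lam <- pmax(eg$values, 0)
  r <- min(N - 1L, sum(lam > max(lam[1], .Machine$double.eps) * 1e-12))
  lam_keep <- lam[seq_len(max(r, 1L))]
  P <- crossprod(A, eg$vectors[, seq_len(max(r, 1L)), drop = FALSE])
  P <- sweep(P, 2L, sqrt((N - 1) * pmax(lam_keep, .Machine$double.eps)), `/`)
  # sign canonicalisation: largest-|.| component positive
  for (q in seq_len(ncol(P))) {
    j <- which.max(abs(P[, q]))
    if (P[j, q] < 0) P[, q] <- -P[, q]
  }
  lam_all <- lam[seq_len(N - 1L)]
  if (length(k) != 1L || k <= 0) stop("k must be a positive count or a fraction")
  kk <- if (k < 1) {
    cf <- cumsum(lam_all) / sum(lam_all)
    max(1L, which(cf >= k)[1L])
  } else {
    as.integer(min(k, ncol(P)))
  }
  kk <- min(kk, ncol(P))
  structure(list(mean = mean_shape,
                 eigenvectors = P[, seq_len(kk), drop = FALSE],
                 eigenvalues = lam_all,
                 k = kk, N_train = N, m = ncol(X) %/% 3L),
            class = "pdm")
}

shapes_to_matrix <- function(shapes) {
  if (is.matrix(shapes)) return(shapes)
  rows <- lapply(shapes, function(s) {
    if (is.matrix(s)) as.vector(t(s)) else as.numeric(s)
  })
  len <- vapply(rows, length, 0L)
  if (length(unique(len)) != 1L) stop("shape vectors have mismatched lengths")
  do.call(rbind, rows)
}

#' @export
print.pdm <- function(x, ...) {
  spec <- variance_spectrum(x)
  cat(sprintf("pdm: N = %d shapes, m = %d points, k = %d modes (%.1f%% of variance)\n",
              x$N_train, x$m, x$k, spec$cumulative[x$k]))
  invisible(x)
}

#' Project a shape onto the model's modes
#'
#' Returns the coefficient vector `b = P^T (X - Xbar)`.
#'
#' @param pdm a [build_pdm()] model.
#' @param X a 3m shape vector (or `m x 3` matrix, or an `n x 3m` matrix of
#'   several shapes, one per row).
#' @return a length-k coefficient vector (or `n x k` matrix).
#' @export
pdm_project <- function(pdm, X) {
  stopifnot(inherits(pdm, "pdm"))
  if (is.matrix(X) && ncol(X) == 3L) X <- as.vector(t(X))
  if (is.matrix(X)) {
    if (ncol(X) != 3L * pdm$m) stop("shape length mismatch")
    return(sweep(X, 2L, pdm$mean) %*% pdm$eigenvectors)
  }
  if (length(X) != 3L * pdm$m) stop("shape length mismatch")
  drop(crossprod(pdm$eigenvectors, X - pdm$mean))
}

#' Reconstruct a shape from mode coefficients
#'
#' `X = Xbar + P b`; missing trailing coefficients are taken as zero.
#'
#' @param pdm a [build_pdm()] model.
#' @param b coefficient vector of length <= k (or an `n x k` matrix).
#' @return a 3m shape vector (or `n x 3m` matrix).
#' @export
pdm_reconstruct <- function(pdm, b) {
  stopifnot(inherits(pdm, "pdm"))
  if (is.matrix(b)) {
    if (ncol(b) > pdm$k) stop("more coefficients than retained modes")
    P <- pdm$eigenvectors[, seq_len(ncol(b)), drop = FALSE]
    return(sweep(b %*% t(P), 2L, pdm$mean, `+`))
  }
  if (length(b) > pdm$k) stop("more coefficients than retained modes")
  P <- pdm$eigenvectors[, seq_along(b), drop = FALSE]
  pdm$mean + drop(P %*% b)
}

#' Relative eigenvalue spectrum
#'
#' Eigenvalues normalised so they sum to 100%, with cumulative sums — the
#' scree of the model's deformation modes.
#'
#' @param pdm a [build_pdm()] model.
#' @return list with `percent` and `cumulative` (both length N-1, in %).
#' @export
variance_spectrum <- function(pdm) {
  stopifnot(inherits(pdm, "pdm"))
  tot <- sum(pdm$eigenvalues)
  pct <- if (tot > 0) 100 * pdm$eigenvalues / tot else rep(0, length(pdm$eigenvalues))
  list(percent = pct, cumulative = cumsum(pct))
}
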