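#' Matching configuration
#'
#' Parameters of the substep deformation that drives the reference NURBS
#' surface onto a target training surface. The deformation is split into
#' `n_substeps` intermediate targets (a relatively small step per substep
#' avoids local minima), and within each substep the control points are
#' warped iteratively until the surface stops moving.
#'
#' @param n_substeps number of intermediate deformation targets (>= 1).
#' @param max_iters maximum warp iterations per substep.
#' @param tol convergence threshold (mm) on the maximum surface-point
#'   displacement per iteration.
#' @param damping step fraction in (0, 1] applied to each control update.
#' @param lambda Tikhonov ridge factor, scaled by the mean diagonal of the
#'   collocation normal matrix.
#' @return an object of class `match_config`.
#' @export
match_config <- function(n_substeps = 10L, max_iters = 50L, tol = 1e-3,
                         damping = 0.8, lambda = 1e-6) {
  stopifnot(n_substeps >= 1L, tol > 0, damping > 0, damping <= 1, lambda >= 0)
  structure(list(n_substeps = as.integer(n_substeps),
                 max_iters = as.integer(max_iters),
                 tol = tol, damping = damping, lambda = lambda),
            class = "match_config")
}

#' Intermediate deformation targets
#'
#' Splits the move from the reference point set `X1` to the corresponded
#' target set `X2` into `n` equal substeps: set `j` is
#' `X1 + (X2 - X1) * j / n`, so the final set equals `X2` exactly.
#'
#' @param X1,X2 `m x 3` point matrices in correspondence order.
#' @param n number of substeps (>= 1).
#' @return a list of `n` point matrices.
#' @export
intermediate_targets <- function(X1, X2, n) {
  X1 <- as.matrix(X1); X2 <- as.matrix(X2)
  if (!all(dim(X1) == dim(X2))) stop("X1 and X2 must have identical dimensions")
  stopifnot(n >= 1L)
  lapply(seq_len(n), function(j) X1 + (X2 - X1) * (j / n))
}

# Collocation operator of a surface on a grid, with pole-cap control rows
# tied to single free points so deformation cannot open the poles.
# Returns B (m x K), the expand map back to the control array, and the
# reduced control matrix accessor.
collocation_operator <- function(surface, grid) {
  d <- dim(surface$control_points)
  n_u <- d[1]; n_v <- d[2]
  Bu <- surface_basis_u(surface, grid$u)
  Bv <- surface_basis_v(surface, grid$v)
  Bfull <- kronecker(Bv, Bu) # row (b-1)*m_u + a ; col (j-1)*n_u + i
  group <- matrix(0L, n_u, n_v)
  nxt <- 0L
  if (surface$caps[1]) { nxt <- nxt + 1L; group[, 1L] <- nxt }
  for (j in seq_len(n_v)) {
    if (surface$caps[1] && j == 1L) next
    if (surface$caps[2] && j == n_v) next
    for (i in seq_len(n_u)) { nxt <- nxt + 1L; group[i, j] <- nxt }
  }
  if (surface$caps[2]) { nxt <- nxt + 1L; group[, n_v] <- nxt }
  K <- nxt
  gvec <- as.vector(group)
  B <- matrix(0, nrow(Bfull), K)
  for (g in unique(gvec)) {
    cols <- which(gvec == g)
    B[, g] <- if (length(cols) == 1L) Bfull[, cols] else rowSums(Bfull[, cols, drop = FALSE])
  }
  list(B = B, group = gvec, K = K, n_u = n_u, n_v = n_v)
}

reduce_controls <- function(surface, op) {
  # representative control value per group (cap rows are identical by
  # construction; enforce by averaging)
  cp <- surface$control_points
  out <- matrix(NA_real_, op$K, 3L)
  for (d in 1:3) {
    out[, d] <- as.vector(rowsum(as.vector(cp[, , d]), op$group) /
                            tabulate(op$group, op$K))
  }
  out
}

expand_controls <- function(Cred, op) {
  cp <- array(NA_real_, c(op$n_u, op$n_v, 3L))
  for (d in 1:3) cp[, , d] <- matrix(Cred[op$group, d], op$n_u, op$n_v)
  cp
}

#' One control-point warp step
#'
#' Updates the surface control points by the damped, ridge-regularised
#' least-squares solution of the collocation system `B dC = dX`, where `B`
#' holds the basis values at the grid parameters and `dX` the current
#' displacements of the resampled surface points towards `target_points`.
#' Periodic wrap and collapsed pole rows are preserved by construction.
#'
#' @param surface a [nurbs_surface()].
#' @param grid the shared [param_grid()]; the number of grid points must be
#'   at least the number of free control points.
#' @param target_points `m x 3` matrix, index-aligned with the grid.
#' @param damping step fraction in (0, 1].
#' @param lambda trace-scaled ridge factor; with `lambda = 0` a
#'   rank-deficient system is an error suggesting a denser grid or ridge.
#' @return the updated [nurbs_surface()].
#' @export
warp_step <- function(surface, grid, target_points, damping = 1, lambda = 1e-6) {
  op <- collocation_operator(surface, grid)
  fac <- warp_factorization(op, lambda)
  warp_step_internal(surface, op, fac, target_points, damping)$surface
}

warp_factorization <- function(op, lambda) {
  G <- crossprod(op$B)
  if (nrow(op$B) < op$K) {
    stop(sprintf("grid has %d points but %d free control points; use a denser grid",
                 nrow(op$B), op$K))
  }
  scale <- mean(diag(G))
  if (lambda > 0) G <- G + diag(lambda * scale, op$K)
  ch <- tryCatch(chol(G), error = function(e) NULL)
  if (is.null(ch)) {
    stop("rank-deficient collocation system: increase the grid resolution or use lambda > 0")
  }
  ch
}

warp_step_internal <- function(surface, op, fac, target_points, damping) {
  Cred <- reduce_controls(surface, op)
  X <- op$B %*% Cred
  dX <- target_points - X
  dC <- backsolve(fac, forwardsolve(t(fac), crossprod(op$B, dX)))
  Cred2 <- Cred + damping * dC
  surface$control_points <- expand_controls(Cred2, op)
  move <- op$B %*% (damping * dC)
  list(surface = surface,
       step_max = sqrt(max(rowSums(move^2))),
       resid = sqrt(rowSums((target_points - (X + move))^2)))
}

#' Match the reference NURBS surface to a target via substep deformation
#'
#' Deforms the reference surface towards the corresponded target points in
#' `cfg$n_substeps` intermediate stages; within each stage the control
#' points are warped (see [warp_step()]) until the surface moves less than
#' `cfg$tol` mm per iteration. The deformed surface keeps the reference's
#' degrees and knot vectors exactly — only the control points move — so
#' every matched training shape shares one NURBS topology.
#'
#' @param reference the reference [nurbs_surface()].
#' @param grid the shared [param_grid()].
#' @param correspondence a [correspond()] result whose `reference_points`
#'   are `resample_points(reference, grid)`.
#' @param cfg a [match_config()].
#' @return an object of class `match_result`: list with `surface` (the
#'   deformed [nurbs_surface()]), `trace` (per-substep data frame of RMS
#'   and max residuals in mm and iteration counts) and `converged`.
#'   Non-convergence sets `converged = FALSE`; it never throws.
#' @export
match_surfaces <- function(reference, grid, correspondence, cfg = match_config()) {
  stopifnot(inherits(reference, "nurbs_surface"), inherits(grid, "param_grid"),
            inherits(correspondence, "correspondence_map"),
            inherits(cfg, "match_config"))
  X1 <- resample_points(reference, grid)
  X2 <- correspondence$target_points
  if (nrow(X2) != nrow(X1)) {
    stop("correspondence size does not match the resampling grid")
  }
  targets <- intermediate_targets(X1, X2, cfg$n_substeps)
  op <- collocation_operator(reference, grid)
  fac <- warp_factorization(op, cfg$lambda)

  surf <- reference
  converged <- TRUE
  rows <- vector("list", cfg$n_substeps)
  for (j in seq_len(cfg$n_substeps)) {
    tj <- targets[[j]]
    it <- 0L
    last_rms <- Inf
    repeat {
      it <- it + 1L
      st <- warp_step_internal(surf, op, fac, tj, cfg$damping)
      rms <- sqrt(mean(st$resid^2))
      if (rms <= last_rms + 1e-12) {
        surf <- st$surface
        last_rms <- rms
      } else {
        break # numerical stagnation: keep the best surface
      }
      if (st$step_max < cfg$tol || it >= cfg$max_iters) break
    }
    if (it >= cfg$max_iters && st$step_max >= cfg$tol) converged <- FALSE
    rows[[j]] <- data.frame(substep = j, iters = it,
                            rms = last_rms, max = max(st$resid))
  }
  structure(list(surface = surf, trace = do.call(rbind, rows),
                 converged = converged),
            class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  n <- nrow(x$trace)
  cat(sprintf("match_result: %d substeps, final RMS %.4g mm (max %.4g), %s\n",
              n, x$trace$rms[n], x$trace$max[n],
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}
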