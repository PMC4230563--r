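#' B-spline basis functions
#'
#' Evaluates all basis functions of the given degree and knot vector at a
#' parameter value, by the Cox-de Boor recursion in its numerically stable
#' triangular form. Values are non-negative and sum to one (partition of
#' unity) everywhere in the knot domain.
#'
#' @param degree spline degree (>= 1).
#' @param knots nondecreasing knot vector of length `n + degree + 1`.
#' @param u parameter value inside `[knots[degree + 1], knots[n + 1]]`.
#' @return a length-`n` vector of basis values (at most `degree + 1` nonzero).
#' @examples
#' basis_functions(2, c(0, 0, 0, 1, 1, 1), 0.5) # Bernstein: 0.25 0.5 0.25
#' @export
basis_functions <- function(degree, knots, u) {
  n <- length(knots) - degree - 1L
  if (u < knots[degree + 1L] - 1e-12 || u > knots[n + 1L] + 1e-12) {
    stop(sprintf("parameter u = %g outside knot domain [%g, %g]",
                 u, knots[degree + 1L], knots[n + 1L]))
  }
  s <- find_span(degree, knots, u)
  loc <- basis_local(degree, knots, s, u)
  out <- numeric(n)
  out[(s - degree):s] <- loc
  out
}

find_span <- function(degree, knots, u) {
  n <- length(knots) - degree - 1L
  if (u >= knots[n + 1L]) return(n)
  s <- findInterval(u, knots)
  min(max(s, degree + 1L), n)
}

basis_local <- function(degree, knots, span, u) {
  N <- numeric(degree + 1L); N[1L] <- 1
  left <- right <- numeric(degree)
  for (j in seq_len(degree)) {
    left[j] <- u - knots[span + 1L - j]
    right[j] <- knots[span + j] - u
    saved <- 0
    for (r in seq_len(j)) {
      temp <- N[r] / (right[r] + left[j - r + 1L])
      N[r] <- saved + right[r] * temp
      saved <- left[j - r + 1L] * temp
    }
    N[j + 1L] <- saved
  }
  N
}

# collocation matrix: one row of basis values per parameter; when wrap_n is
# given the basis indices are folded modulo wrap_n (periodic splines)
basis_matrix <- function(degree, knots, u, wrap_n = NULL) {
  n <- length(knots) - degree - 1L
  ncol_out <- if (is.null(wrap_n)) n else wrap_n
  B <- matrix(0, length(u), ncol_out)
  for (a in seq_along(u)) {
    s <- find_span(degree, knots, u[a])
    loc <- basis_local(degree, knots, s, u[a])
    idx <- (s - degree):s
    if (!is.null(wrap_n)) idx <- (idx - 1L) %% wrap_n + 1L
    for (k in seq_along(idx)) B[a, idx[k]] <- B[a, idx[k]] + loc[k]
  }
  B
}

periodic_knots <- function(n_ctrl, degree) {
  ((0:(n_ctrl + 2L * degree)) - degree) / n_ctrl
}

#' NURBS / B-spline tensor-product surfaces
#'
#' A `nurbs_surface` stores degrees, knot vectors, an `n_u x n_v` grid of
#' 3D control points and positive weights. The u direction may be periodic
#' (closed around the organ's axial contours), in which case `n_u` distinct
#' control columns are stored and the basis wraps modulo `n_u`; v is
#' clamped (superior-inferior). With all weights 1 (the default) the
#' surface is a non-rational B-spline.
#'
#' @param degree_u,degree_v spline degrees.
#' @param knots_u,knots_v knot vectors (for a periodic u, the uniform
#'   extended vector over domain `[0, 1]`).
#' @param control_points numeric array `dim = c(n_u, n_v, 3)` (mm).
#' @param weights positive `n_u x n_v` matrix; default all 1.
#' @param periodic_u is the u direction closed?
#' @param caps logical length 2: are the first/last control rows collapsed
#'   pole caps (kept collapsed during deformation)?
#' @param name organ label.
#' @return an object of class `nurbs_surface`.
#' @export
nurbs_surface <- function(degree_u, degree_v, knots_u, knots_v, control_points,
                          weights = NULL, periodic_u = FALSE,
                          caps = c(FALSE, FALSE), name = "organ") {
  d <- dim(control_points)
  if (length(d) != 3L || d[3] != 3L) stop("control_points must be n_u x n_v x 3")
  if (is.null(weights)) weights <- matrix(1, d[1], d[2])
  if (any(weights <= 0)) stop("weights must be positive")
  n_basis_u <- length(knots_u) - degree_u - 1L
  expect_u <- if (periodic_u) d[1] + degree_u else d[1]
  if (n_basis_u != expect_u) stop("knots_u length inconsistent with control grid")
  if (length(knots_v) - degree_v - 1L != d[2]) {
    stop("knots_v length inconsistent with control grid")
  }
  if (is.unsorted(knots_u) || is.unsorted(knots_v)) stop("knot vectors must be nondecreasing")
  structure(list(degree_u = degree_u, degree_v = degree_v,
                 knots_u = knots_u, knots_v = knots_v,
                 control_points = control_points, weights = weights,
                 periodic_u = periodic_u, caps = caps, name = name),
            class = "nurbs_surface")
}

#' @export
print.nurbs_surface <- function(x, ...) {
  d <- dim(x$control_points)
  cat(sprintf("nurbs_surface '%s': degree %dx%d, control net %dx%d%s%s\n",
              x$name, x$degree_u, x$degree_v, d[1], d[2],
              if (x$periodic_u) ", periodic u" else "",
              if (any(x$caps)) ", capped poles" else ""))
  invisible(x)
}

surface_basis_u <- function(surface, u) {
  if (surface$periodic_u) {
    basis_matrix(surface$degree_u, surface$knots_u, u %% 1,
                 wrap_n = dim(surface$control_points)[1])
  } else {
    basis_matrix(surface$degree_u, surface$knots_u, u)
  }
}

surface_basis_v <- function(surface, v) {
  basis_matrix(surface$degree_v, surface$knots_v, v)
}

#' Evaluate a NURBS surface
#'
#' Rational tensor-product evaluation
#' `S(u, v) = sum_ij N_i(u) M_j(v) w_ij C_ij / sum_ij N_i(u) M_j(v) w_ij`.
#' `u` and `v` are paired (recycled to a common length).
#'
#' @param surface a [nurbs_surface()].
#' @param u,v parameter values; for a periodic u any real is accepted
#'   (wrapped into `[0, 1)`).
#' @return a `length(u) x 3` matrix of points (mm).
#' @export
evaluate_surface <- function(surface, u, v) {
  k <- max(length(u), length(v))
  u <- rep_len(u, k); v <- rep_len(v, k)
  Bu <- surface_basis_u(surface, u)
  Bv <- surface_basis_v(surface, v)
  W <- surface$weights
  den <- rowSums((Bu %*% W) * Bv)
  out <- matrix(NA_real_, k, 3L)
  for (d in 1:3) {
    out[, d] <- rowSums((Bu %*% (W * surface$control_points[, , d])) * Bv) / den
  }
  out
}

# full-grid evaluation: returns list of m_u x m_v coordinate matrices
evaluate_surface_grid <- function(surface, u, v) {
  Bu <- surface_basis_u(surface, u)
  Bv <- surface_basis_v(surface, v)
  W <- surface$weights
  den <- Bu %*% W %*% t(Bv)
  lapply(1:3, function(d) (Bu %*% (W * surface$control_points[, , d]) %*% t(Bv)) / den)
}

#' Surface normal by central differences
#'
#' Unit normal of the surface at `(u, v)`, from finite-difference tangents
#' (one-sided at the clamped v ends). Near the degenerate pole caps the u
#' tangent vanishes; a zero vector is returned there and callers fall back
#' to plain closest-point correspondence.
#'
#' @inheritParams evaluate_surface
#' @param h finite-difference step.
#' @return `length(u) x 3` matrix of unit normals (rows may be zero at poles).
#' @export
surface_normals <- function(surface, u, v, h = 1e-5) {
  k <- max(length(u), length(v))
  u <- rep_len(u, k); v <- rep_len(v, k)
  du <- (evaluate_surface(surface, u + h, v) -
         evaluate_surface(surface, u - h, v)) / (2 * h)
  vlo <- pmax(v - h, 0); vhi <- pmin(v + h, 1)
  dv <- (evaluate_surface(surface, u, vhi) -
         evaluate_surface(surface, u, vlo)) / (vhi - vlo)
  n <- cbind(du[, 2] * dv[, 3] - du[, 3] * dv[, 2],
             du[, 3] * dv[, 1] - du[, 1] * dv[, 3],
             du[, 1] * dv[, 2] - du[, 2] * dv[, 1])
  len <- sqrt(rowSums(n^2))
  ok <- len > 1e-8 * max(len)
  n[ok, ] <- n[ok, , drop = FALSE] / len[ok]
  n[!ok, ] <- 0
  n
}

# ---- contour resampling and lofting ---------------------------------------

# rotate/orient a closed polygon: counterclockwise, starting at max-x vertex
orient_polygon <- function(p) {
  if (polygon_area(p) < 0) p <- p[rev(seq_len(nrow(p))), , drop = FALSE]
  start <- which.max(p[, 1])
  if (start > 1L) p <- p[c(start:nrow(p), 1L:(start - 1L)), , drop = FALSE]
  p
}

# arc-length uniform resampling of a closed polygon to n points
resample_polygon <- function(p, n) {
  p <- orient_polygon(p)
  q <- rbind(p, p[1L, ])
  seg <- sqrt(rowSums(diff(q)^2))
  cum <- c(0, cumsum(seg))
  total <- cum[length(cum)]
  if (total <= 0) return(matrix(rep(p[1L, ], each = n), n, 2L))
  s <- total * (seq_len(n) - 1L) / n
  i <- findInterval(s, cum, rightmost.closed = TRUE)
  i[i >= nrow(q)] <- nrow(q) - 1L
  frac <- (s - cum[i]) / pmax(seg[i], .Machine$double.eps)
  q[i, , drop = FALSE] + frac * (q[i + 1L, , drop = FALSE] - q[i, , drop = FALSE])
}

#' Loft a NURBS surface through a stack of closed contours
#'
#' Builds an interpolating tensor-product B-spline surface through an
#' axial contour stack, periodic (closed) around the contours and clamped
#' along the superior-inferior axis. Each contour is first oriented
#' counterclockwise, seeded at its maximum-x point and resampled uniformly
#' by arc length to `n_u` points; the surface interpolates every resampled
#' contour point. With `cap_ends = TRUE` the stack is extended by one
#' degenerate contour at each end, collapsed to the apex centroid of the
#' extreme contour, so the surface closes at the poles.
#'
#' @param stack a [contour_stack()].
#' @param degree_u,degree_v spline degrees (cubic by default).
#' @param n_u number of resampled points (and control columns) per contour.
#' @param cap_ends close the surface with degenerate pole rows.
#' @param cap_extent axial distance (mm) from the extreme slice to its apex;
#'   default half the median slice spacing.
#' @return a [nurbs_surface()] with attributes `u_params` and `v_params`
#'   giving the parameters at which the resampled contour points are
#'   interpolated.
#' @export
loft_contours <- function(stack, degree_u = 3L, degree_v = 3L, n_u = 36L,
                          cap_ends = TRUE, cap_extent = NULL) {
  stack <- validate_contours(stack, check_simple = FALSE)
  zs <- vapply(stack$slices, `[[`, 0, "z")
  K0 <- length(zs)
  rings <- lapply(stack$slices, function(s) resample_polygon(s$points, n_u))
  pts3 <- mapply(function(r, z) cbind(r, z), rings, zs, SIMPLIFY = FALSE)

  if (cap_ends) {
    dz <- if (K0 > 1L) stats::median(diff(zs)) else 2
    ext_lo <- if (is.null(cap_extent)) cap_extrapolation(pts3, zs, lower = TRUE, dz) else cap_extent
    ext_hi <- if (is.null(cap_extent)) cap_extrapolation(pts3, zs, lower = FALSE, dz) else cap_extent
    lo <- colMeans(pts3[[1L]]); hi <- colMeans(pts3[[K0]])
    lo[3] <- zs[1] - ext_lo; hi[3] <- zs[K0] + ext_hi
    pts3 <- c(list(matrix(lo, n_u, 3L, byrow = TRUE)), pts3,
              list(matrix(hi, n_u, 3L, byrow = TRUE)))
    zs <- c(lo[3], zs, hi[3])
  }
  K <- length(pts3)
  if (K < degree_v + 1L) {
    stop(sprintf("need at least %d contours (after capping) for degree %d loft, got %d",
                 degree_v + 1L, degree_v, K))
  }
  if (n_u <= degree_u + 1L) stop("n_u must exceed degree_u + 1")

  # periodic interpolation around each contour
  u_params <- (seq_len(n_u) - 1L) / n_u
  ku <- periodic_knots(n_u, degree_u)
  Bu <- basis_matrix(degree_u, ku, u_params, wrap_n = n_u)
  Bu_lu <- lu_factor(Bu)
  R <- lapply(pts3, function(q) lu_solve(Bu_lu, q)) # each n_u x 3

  # clamped interpolation across slices, parameterised by chord length
  # averaged over the u columns (reduces to z spacing for straight stacks,
  # and keeps the interpolant regular at the degenerate pole rows)
  chords <- vapply(seq_len(K - 1L), function(k2) {
    mean(sqrt(rowSums((pts3[[k2 + 1L]] - pts3[[k2]])^2)))
  }, numeric(1))
  v_params <- c(0, cumsum(chords)) / sum(chords)
  kv <- averaged_knots(v_params, degree_v)
  Bv <- basis_matrix(degree_v, kv, v_params)
  cp <- array(NA_real_, c(n_u, K, 3L))
  for (d in 1:3) {
    Rd <- t(vapply(R, function(r) r[, d], numeric(n_u))) # K x n_u
    cp[, , d] <- t(solve(Bv, Rd))
  }
  surf <- nurbs_surface(degree_u, degree_v, ku, kv, cp,
                        periodic_u = TRUE, caps = c(cap_ends, cap_ends),
                        name = stack$organ)
  attr(surf, "u_params") <- u_params
  attr(surf, "v_params") <- v_params
  surf
}

# Apex placement for the pole caps: extrapolate the squared mean ring
# radius in z to zero with a quadratic through the three extreme slices
# (exact for quadric caps, i.e. spheres and ellipsoids); fall back to a
# linear fit with two slices. The extent from the extreme slice is clamped
# to [0.1, 3] slice spacings for robustness against noisy contours.
cap_extrapolation <- function(pts3, zs, lower, dz) {
  K <- length(zs)
  take <- if (lower) seq_len(min(3L, K)) else seq(K, by = -1L, length.out = min(3L, K))
  r2 <- vapply(pts3[take], function(p) {
    c2 <- colMeans(p[, 1:2, drop = FALSE])
    mean((p[, 1] - c2[1])^2 + (p[, 2] - c2[2])^2)
  }, numeric(1))
  z <- zs[take]
  z_edge <- zs[if (lower) 1L else K]
  ext <- NA_real_
  if (length(z) >= 3L) {
    co <- tryCatch(solve(cbind(1, z, z^2), r2), error = function(e) NULL)
    if (!is.null(co) && abs(co[3]) > 1e-12) {
      disc <- co[2]^2 - 4 * co[3] * co[1]
      if (disc >= 0) {
        roots <- (-co[2] + c(-1, 1) * sqrt(disc)) / (2 * co[3])
        cand <- if (lower) roots[roots < z_edge + 1e-9] else roots[roots > z_edge - 1e-9]
        if (length(cand) > 0L) ext <- min(abs(cand - z_edge))
      }
    }
  }
  if (!is.finite(ext) && length(z) >= 2L) {
    i2 <- 1:2
    b <- (r2[i2[2]] - r2[i2[1]]) / (z[i2[2]] - z[i2[1]])
    if ((lower && b > 1e-12) || (!lower && b < -1e-12)) {
      z0 <- z[1] - r2[1] / b
      ext <- abs(z0 - z_edge)
    }
  }
  if (!is.finite(ext)) ext <- dz / 2
  min(max(ext, 0.1 * dz), 3 * dz)
}

# interpolation knot vector by parameter averaging (clamped)
averaged_knots <- function(params, degree) {
  n <- length(params)
  inner <- if (n - degree - 1L >= 1L) {
    vapply(seq_len(n - degree - 1L), function(j) mean(params[(j + 1L):(j + degree)]),
           numeric(1))
  } else numeric(0)
  c(rep(params[1], degree + 1L), inner, rep(params[n], degree + 1L))
}

lu_factor <- function(A) list(qr = qr(A))
lu_solve <- function(f, b) qr.solve(f$qr, b)

# ---- parameter grids and resampling ---------------------------------------

#' Resampling parameter grids
#'
#' A fixed ordered grid of `(u, v)` parameter pairs shared by all surfaces
#' of one organ, so that resampled point sets are in dense correspondence.
#' u is sampled uniformly on `[0, 1)` (periodic direction) and v uniformly
#' on `[0, 1]` including the pole caps. Ordering is row-major over v with u
#' varying fastest: point index `(a, b)` maps to row `(b - 1) * m_u + a`.
#'
#' @param m_u,m_v grid resolution (default 50 x 50 = 2500 points).
#' @return an object of class `param_grid` with elements `u`, `v`, `uv`
#'   (the full ordered pair list), `m_u`, `m_v`.
#' @export
param_grid <- function(m_u = 50L, m_v = 50L) {
  u <- (seq_len(m_u) - 1L) / m_u
  v <- seq(0, 1, length.out = m_v)
  structure(list(u = u, v = v,
                 uv = cbind(u = rep(u, times = m_v), v = rep(v, each = m_u)),
                 m_u = as.integer(m_u), m_v = as.integer(m_v)),
            class = "param_grid")
}

#' Resample surface points from a NURBS surface
#'
#' Evaluates the surface on a shared [param_grid()], producing the ordered
#' point set used for correspondence and the PCA shape vectors
#' ("controlled precision" digitisation of the organ shape).
#'
#' @param surface a [nurbs_surface()].
#' @param grid a [param_grid()].
#' @return an `(m_u * m_v) x 3` matrix of surface points, with attribute
#'   `grid`.
#' @export
resample_points <- function(surface, grid) {
  stopifnot(inherits(surface, "nurbs_surface"), inherits(grid, "param_grid"))
  co <- evaluate_surface_grid(surface, grid$u, grid$v)
  pts <- cbind(as.vector(co[[1]]), as.vector(co[[2]]), as.vector(co[[3]]))
  attr(pts, "grid") <- grid
  pts
}
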