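# Shared fixtures, built in code at test time.

# smallest closed triangulation
tetra_mesh <- function() {
  triangle_mesh(
    rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
    rbind(c(1, 3, 2), c(1, 2, 4), c(2, 3, 4), c(1, 4, 3)),
    name = "tetra"
  )
}

# unit cube, 12 triangles
cube_mesh <- function() {
  v <- as.matrix(expand.grid(x = 0:1, y = 0:1, z = 0:1))
  f <- rbind(
    c(1, 3, 2), c(2, 3, 4),   # z = 0
    c(5, 6, 7), c(6, 8, 7),   # z = 1
    c(1, 2, 5), c(2, 6, 5),   # y = 0
    c(3, 7, 4), c(4, 7, 8),   # y = 1
    c(1, 5, 3), c(3, 5, 7),   # x = 0
    c(2, 4, 6), c(4, 8, 6)    # x = 1
  )
  triangle_mesh(v, f, "cube")
}

# analytic circle-contour stack for a sphere of given radius
sphere_contours <- function(radius = 25, spacing = 2.5, n_pts = 120) {
  zs <- seq(-radius + spacing, radius - spacing, by = spacing)
  th <- 2 * pi * (seq_len(n_pts) - 1L) / n_pts
  slices <- lapply(zs, function(z) {
    r <- sqrt(radius^2 - z^2)
    list(z = z, points = cbind(r * cos(th), r * sin(th)))
  })
  contour_stack(slices, organ = "sphere", slice_thickness = spacing)
}

# independent scalar closest-point-on-triangle oracle: candidate set of
# the unconstrained plane foot (if inside), the three clamped edge
# projections and the three vertices
closest_point_triangle_oracle <- function(p, a, b, c3) {
  cands <- list(a, b, c3)
  seg <- function(x, y) {
    t <- sum((p - x) * (y - x)) / sum((y - x)^2)
    x + min(1, max(0, t)) * (y - x)
  }
  cands <- c(cands, list(seg(a, b), seg(b, c3), seg(c3, a)))
  n <- pracma_cross(b - a, c3 - a)
  if (sum(n^2) > 0) {
    q <- p - sum((p - a) * n) / sum(n^2) * n
    # barycentric feasibility
    M <- cbind(b - a, c3 - a)
    st <- tryCatch(solve(crossprod(M), crossprod(M, q - a)), error = function(e) NULL)
    if (!is.null(st) && st[1] >= 0 && st[2] >= 0 && sum(st) <= 1) {
      cands <- c(cands, list(q))
    }
  }
  d2 <- vapply(cands, function(x) sum((p - x)^2), numeric(1))
  list(point = cands[[which.min(d2)]], distance = sqrt(min(d2)))
}

pracma_cross <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3], u[1] * v[2] - u[2] * v[1])
}

closest_point_mesh_oracle <- function(p, mesh) {
  best <- list(distance = Inf)
  for (t in seq_len(nrow(mesh$faces))) {
    r <- closest_point_triangle_oracle(p,
                                       mesh$vertices[mesh$faces[t, 1], ],
                                       mesh$vertices[mesh$faces[t, 2], ],
                                       mesh$vertices[mesh$faces[t, 3], ])
    if (r$distance < best$distance) best <- r
  }
  best
}

# direct recursive Cox-de Boor definition (independent of the package's
# triangular-scheme implementation)
coxdeboor_recursive <- function(i, p, knots, u) {
  if (p == 0) {
    return(as.numeric(u >= knots[i] & (u < knots[i + 1] ||
      (u == knots[i + 1] && knots[i + 1] == max(knots)))))
  }
  d1 <- knots[i + p] - knots[i]
  d2 <- knots[i + p + 1] - knots[i + 1]
  t1 <- if (d1 > 0) (u - knots[i]) / d1 * coxdeboor_recursive(i, p - 1, knots, u) else 0
  t2 <- if (d2 > 0) (knots[i + p + 1] - u) / d2 * coxdeboor_recursive(i + 1, p - 1, knots, u) else 0
  t1 + t2
}

# principal angles (degrees) between the column spans of two matrices
principal_angles <- function(A, B) {
  sv <- svd(crossprod(qr.Q(qr(A)), qr.Q(qr(B))))$d
  acos(pmin(1, sv)) * 180 / pi
}

# restrict shape-vector rows to grid points with v inside [lo, hi]
interior_rows <- function(grid, lo = 0.1, hi = 0.9) {
  pts <- which(grid$uv[, "v"] >= lo & grid$uv[, "v"] <= hi)
  as.vector(rbind(3L * (pts - 1L) + 1L, 3L * (pts - 1L) + 2L, 3L * (pts - 1L) + 3L))
}
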