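#' Closest point on a triangle mesh
#'
#' Exact closest-point search over all faces, edges and vertices of the
#' mesh: for every triangle the minimiser of the Euclidean distance from
#' the query point is computed in closed form (the seven Voronoi regions of
#' a triangle), and the global minimum is kept. Ties are broken towards the
#' lowest face index, so the result is deterministic.
#'
#' @param p a 3-vector query point (mm).
#' @param mesh a [triangle_mesh()].
#' @return a list with `point` (the foot point), `distance` (mm), `face`
#'   (index of the winning triangle) and `element` (`"face"`, `"edge"` or
#'   `"vertex"` depending on where in the triangle the minimiser lies).
#' @export
closest_point_on_mesh <- function(p, mesh) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  if (nrow(mesh$faces) == 0L) stop("empty mesh")
  r <- closest_points_on_mesh(matrix(p, 1L, 3L), mesh)
  list(point = r$points[1L, ], distance = r$distance[1L],
       face = r$face[1L], element = r$element[1L])
}

# Vectorised over query points: for each triangle in face order, the
# closest point for all queries at once; strict improvement keeps the
# lowest-index face on ties.
closest_points_on_mesh <- function(P, mesh) {
  v <- mesh$vertices; f <- mesh$faces
  n <- nrow(P)
  best_d2 <- rep(Inf, n)
  best_pt <- matrix(NA_real_, n, 3L)
  best_face <- integer(n)
  best_reg <- integer(n) # 1,2,3 vertex a/b/c; 4,5,6 edge ab/ac/bc; 7 face
  dot <- function(X, Y) X[, 1] * Y[, 1] + X[, 2] * Y[, 2] + X[, 3] * Y[, 3]
  for (t in seq_len(nrow(f))) {
    a <- v[f[t, 1L], ]; b <- v[f[t, 2L], ]; c3 <- v[f[t, 3L], ]
    ab <- b - a; ac <- c3 - a
    ap <- sweep(P, 2L, a)
    d1 <- ap %*% ab; d2 <- ap %*% ac
    bp <- sweep(P, 2L, b)
    d3 <- bp %*% ab; d4 <- bp %*% ac
    cp <- sweep(P, 2L, c3)
    d5 <- cp %*% ab; d6 <- cp %*% ac
    vc <- d1 * d4 - d3 * d2
    vb <- d5 * d2 - d1 * d6
    va <- d3 * d6 - d5 * d4

    reg <- rep.int(7L, n)
    m1 <- d1 <= 0 & d2 <= 0
    m2 <- !m1 & d3 >= 0 & d4 <= d3
    m3 <- !m1 & !m2 & d6 >= 0 & d5 <= d6
    m4 <- !m1 & !m2 & !m3 & vc <= 0 & d1 >= 0 & d3 <= 0
    m5 <- !m1 & !m2 & !m3 & !m4 & vb <= 0 & d2 >= 0 & d6 <= 0
    m6 <- !m1 & !m2 & !m3 & !m4 & !m5 & va <= 0 & (d4 - d3) >= 0 & (d5 - d6) >= 0
    reg[m1] <- 1L; reg[m2] <- 2L; reg[m3] <- 3L
    reg[m4] <- 4L; reg[m5] <- 5L; reg[m6] <- 6L

    q <- matrix(0, n, 3L)
    if (any(m1)) q[m1, ] <- matrix(a, sum(m1), 3L, byrow = TRUE)
    if (any(m2)) q[m2, ] <- matrix(b, sum(m2), 3L, byrow = TRUE)
    if (any(m3)) q[m3, ] <- matrix(c3, sum(m3), 3L, byrow = TRUE)
    if (any(m4)) {
      s <- d1[m4] / (d1[m4] - d3[m4])
      q[m4, ] <- matrix(a, sum(m4), 3L, byrow = TRUE) + s %o% ab
    }
    if (any(m5)) {
      s <- d2[m5] / (d2[m5] - d6[m5])
      q[m5, ] <- matrix(a, sum(m5), 3L, byrow = TRUE) + s %o% ac
    }
    if (any(m6)) {
      s <- (d4[m6] - d3[m6]) / ((d4[m6] - d3[m6]) + (d5[m6] - d6[m6]))
      q[m6, ] <- matrix(b, sum(m6), 3L, byrow = TRUE) + s %o% (c3 - b)
    }
    mf <- reg == 7L
    if (any(mf)) {
      den <- 1 / (va[mf] + vb[mf] + vc[mf])
      vv <- vb[mf] * den; ww <- vc[mf] * den
      q[mf, ] <- matrix(a, sum(mf), 3L, byrow = TRUE) + vv %o% ab + ww %o% ac
    }
    d2q <- rowSums((P - q)^2)
    upd <- d2q < best_d2
    if (any(upd)) {
      best_d2[upd] <- d2q[upd]
      best_pt[upd, ] <- q[upd, , drop = FALSE]
      best_face[upd] <- t
      best_reg[upd] <- reg[upd]
    }
  }
  element <- c("vertex", "vertex", "vertex", "edge", "edge", "edge", "face")[best_reg]
  list(points = best_pt, distance = sqrt(best_d2), face = best_face,
       element = element, region = best_reg)
}

# Moller-Trumbore line/triangle intersection for one origin+direction
# against a set of triangles; returns signed parameters t (NA if miss)
line_triangle_t <- function(orig, dir, A, B, C) {
  e1 <- B - A; e2 <- C - A
  pv <- cbind(dir[2] * e2[, 3] - dir[3] * e2[, 2],
              dir[3] * e2[, 1] - dir[1] * e2[, 3],
              dir[1] * e2[, 2] - dir[2] * e2[, 1])
  det <- rowSums(e1 * pv)
  tv <- sweep(A, 2L, orig, `-`) * -1
  uu <- rowSums(tv * pv) / det
  qv <- cbind(tv[, 2] * e1[, 3] - tv[, 3] * e1[, 2],
              tv[, 3] * e1[, 1] - tv[, 1] * e1[, 3],
              tv[, 1] * e1[, 2] - tv[, 2] * e1[, 1])
  vv <- (qv[, 1] * dir[1] + qv[, 2] * dir[2] + qv[, 3] * dir[3]) / det
  tt <- rowSums(e2 * qv) / det
  eps <- 1e-9
  miss <- abs(det) < 1e-14 | uu < -eps | vv < -eps | (uu + vv) > 1 + eps
  tt[miss] <- NA_real_
  tt
}

#' Dense correspondence between a reference point set and a target surface
#'
#' For every reference surface point the corresponding point on the target
#' mesh is found by a two-stage rule: (i) cast the line through the point
#' along the reference surface normal and intersect it with the target
#' surface patches near the point's closest-point foot; (ii) the target
#' point is the closest point on the target mesh to that intersection
#' (which lies on the mesh). If no intersection exists within the distance
#' cap — or the normal is degenerate, as at pole points — the plain
#' closest-point foot is used instead.
#'
#' @param reference either a [triangle_mesh()] (its vertices are the
#'   reference points, with angle-weighted vertex normals) or an `m x 3`
#'   point matrix, e.g. from [resample_points()].
#' @param target the aligned target [triangle_mesh()].
#' @param normals optional `m x 3` matrix of reference normals (required
#'   for the ray stage when `reference` is a point matrix; rows may be
#'   zero to force closest-point fallback).
#' @param rho neighbourhood radius around the foot point defining the
#'   "nearby" target patches; default 5 x mean target edge length.
#' @param cap maximum admissible ray travel; default half the target
#'   bounding-box diagonal. Also the alignment sanity bound: a
#'   reference/target centroid gap beyond it is an error.
#' @return an object of class `correspondence_map`: list with
#'   `reference_points`, `target_points` (both `m x 3`), `distance` (mm),
#'   `face`, `element`, `method` (`"ray"` or `"closest"` per point).
#' @export
correspond <- function(reference, target, normals = NULL, rho = NULL, cap = NULL) {
  stopifnot(inherits(target, "triangle_mesh"))
  if (inherits(reference, "triangle_mesh")) {
    P <- reference$vertices
    if (is.null(normals)) normals <- vertex_normals(reference)
  } else {
    P <- as.matrix(reference)
  }
  m <- nrow(P)
  bb <- apply(target$vertices, 2L, range)
  diag_len <- sqrt(sum((bb[2L, ] - bb[1L, ])^2))
  if (is.null(cap)) cap <- 0.5 * diag_len
  gap <- sqrt(sum((colMeans(P) - mesh_centroid(target))^2))
  if (gap > cap) {
    stop(sprintf("inputs look unaligned: centroid gap %.2f mm exceeds cap %.2f mm",
                 gap, cap))
  }
  if (is.null(rho)) rho <- 5 * mean_edge_length(target)

  cl <- closest_points_on_mesh(P, target)
  out_pts <- cl$points
  out_face <- cl$face
  out_elem <- cl$element
  method <- rep("closest", m)

  if (!is.null(normals)) {
    f <- target$faces; v <- target$vertices
    cent <- (v[f[, 1L], , drop = FALSE] + v[f[, 2L], , drop = FALSE] +
               v[f[, 3L], , drop = FALSE]) / 3
    A <- v[f[, 1L], , drop = FALSE]
    B <- v[f[, 2L], , drop = FALSE]
    C <- v[f[, 3L], , drop = FALSE]
    for (i in seq_len(m)) {
      nrm <- normals[i, ]
      nl <- sqrt(sum(nrm^2))
      if (nl < 1e-8) next
      nrm <- nrm / nl
      foot <- cl$points[i, ]
      near <- which(((cent[, 1] - foot[1])^2 + (cent[, 2] - foot[2])^2 +
                       (cent[, 3] - foot[3])^2) <= rho^2)
      if (length(near) == 0L) next
      tt <- line_triangle_t(P[i, ], nrm,
                            A[near, , drop = FALSE],
                            B[near, , drop = FALSE],
                            C[near, , drop = FALSE])
      ok <- which(!is.na(tt) & abs(tt) <= cap)
      if (length(ok) == 0L) next
      j <- ok[which.min(abs(tt[ok]))]
      hit <- P[i, ] + tt[j] * nrm
      out_pts[i, ] <- hit
      out_face[i] <- near[j]
      out_elem[i] <- "face"
      method[i] <- "ray"
    }
  }
  structure(list(reference_points = P, target_points = out_pts,
                 distance = sqrt(rowSums((P - out_pts)^2)),
                 face = out_face, element = out_elem, method = method),
            class = "correspondence_map")
}

#' @export
print.correspondence_map <- function(x, ...) {
  cat(sprintf("correspondence_map: %d pairs, distance %.3f +/- %.3f mm (max %.3f), %.1f%% ray hits\n",
              nrow(x$reference_points), mean(x$distance), stats::sd(x$distance),
              max(x$distance), 100 * mean(x$method == "ray")))
  invisible(x)
}
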