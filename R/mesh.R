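#' Triangle mesh objects
#'
#' A `triangle_mesh` is the package's container for a closed organ surface:
#' an `n x 3` matrix of vertex coordinates in millimetres and an `f x 3`
#' integer matrix of 1-based vertex indices, one row per triangle.
#'
#' @param vertices numeric matrix with 3 columns (x, y, z in mm).
#' @param faces integer matrix with 3 columns of vertex indices (1-based).
#' @param name organ label.
#' @return An object of class `triangle_mesh` with elements `vertices`,
#'   `faces` and `name`.
#' @examples
#' tet <- triangle_mesh(
#'   rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
#'   rbind(c(1, 3, 2), c(1, 2, 4), c(2, 3, 4), c(1, 4, 3))
#' )
#' validate_mesh(tet)
#' @export
triangle_mesh <- function(vertices, faces, name = "organ") {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L) stop("vertices must have 3 columns")
  if (nrow(faces) > 0L && ncol(faces) != 3L) stop("faces must have 3 columns")
  structure(list(vertices = vertices, faces = faces, name = as.character(name)),
            class = "triangle_mesh")
}

#' @export
print.triangle_mesh <- function(x, ...) {
  cat(sprintf("triangle_mesh '%s': %d vertices, %d faces\n",
              x$name, nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

face_areas <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  e1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  e2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cx <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
  cy <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]
  cz <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

#' Validate and repair a triangle mesh
#'
#' Checks index ranges, merges duplicate vertices (within `merge_tol` mm),
#' drops zero-area faces, and — when `closed = TRUE` — verifies that the
#' surface is closed and orientable (every edge shared by exactly two faces
#' with opposite orientation) and satisfies the genus-0 Euler relation
#' V - E + F = 2. Holes are never filled: an open surface is an error when a
#' closed one is required. Validation is idempotent.
#'
#' @param mesh a [triangle_mesh()].
#' @param closed require a closed orientable genus-0 surface (default `TRUE`).
#' @param merge_tol vertices closer than this (mm) are merged (default 1e-9).
#' @return The repaired `triangle_mesh`, invisibly carrying attribute
#'   `"validated" = TRUE`.
#' @export
validate_mesh <- function(mesh, closed = TRUE, merge_tol = 1e-9) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  v <- mesh$vertices; f <- mesh$faces
  if (nrow(v) == 0L || nrow(f) == 0L) stop("empty mesh: no vertices or faces")
  if (any(is.na(v)) || any(!is.finite(v))) stop("non-finite vertex coordinates")
  if (any(f < 1L) || any(f > nrow(v))) stop("face indices out of range")

  # merge duplicate vertices by quantised coordinate key
  key <- paste(round(v[, 1] / merge_tol), round(v[, 2] / merge_tol),
               round(v[, 3] / merge_tol))
  first <- match(key, key)
  if (any(first != seq_len(nrow(v)))) {
    keep <- which(first == seq_len(nrow(v)))
    remap <- match(first, keep)
    v <- v[keep, , drop = FALSE]
    f <- matrix(remap[f], ncol = 3L)
    storage.mode(f) <- "integer"
  }

  # drop faces with repeated indices or (numerically) zero area
  m2 <- triangle_mesh(v, f, mesh$name)
  degen <- f[, 1] == f[, 2] | f[, 2] == f[, 3] | f[, 1] == f[, 3]
  if (nrow(f) > 0L) degen <- degen | face_areas(m2) < (merge_tol^2)
  if (any(degen)) f <- f[!degen, , drop = FALSE]
  if (nrow(f) == 0L) stop("mesh has no non-degenerate faces")

  if (closed) {
    he <- rbind(f[, c(1L, 2L)], f[, c(2L, 3L)], f[, c(3L, 1L)])
    ekey <- paste(pmin(he[, 1], he[, 2]), pmax(he[, 1], he[, 2]))
    cnt <- table(ekey)
    bad <- cnt != 2L
    if (any(bad)) {
      stop(sprintf("surface not closed/manifold: %d edge(s) not shared by exactly 2 faces (e.g. %s)",
                   sum(bad), names(cnt)[bad][1]))
    }
    # orientability: each undirected edge must appear once in each direction
    dkey <- paste(he[, 1], he[, 2])
    if (anyDuplicated(dkey)) {
      stop("surface not consistently oriented: duplicated directed edge")
    }
    V <- length(unique(as.vector(f))); E <- length(cnt); FF <- nrow(f)
    if (V - E + FF != 2L) {
      stop(sprintf("Euler check failed: V-E+F = %d-%d+%d = %d (expected 2)",
                   V, E, FF, V - E + FF))
    }
  }
  out <- triangle_mesh(v, f, mesh$name)
  attr(out, "validated") <- TRUE
  out
}

#' Mesh centroid, volume and edge statistics
#'
#' `mesh_centroid` is the mean vertex position; `mesh_volume` the signed
#' volume of a closed oriented surface (positive for outward orientation);
#' `mean_edge_length` the average triangle edge length in mm.
#'
#' @param mesh a [triangle_mesh()].
#' @return numeric vector (centroid) or scalar.
#' @export
mesh_centroid <- function(mesh) colMeans(mesh$vertices)

#' @rdname mesh_centroid
#' @export
mesh_volume <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]; b <- v[f[, 2], , drop = FALSE]
  c3 <- v[f[, 3], , drop = FALSE]
  det3 <- a[, 1] * (b[, 2] * c3[, 3] - b[, 3] * c3[, 2]) -
          a[, 2] * (b[, 1] * c3[, 3] - b[, 3] * c3[, 1]) +
          a[, 3] * (b[, 1] * c3[, 2] - b[, 2] * c3[, 1])
  sum(det3) / 6
}

#' @rdname mesh_centroid
#' @export
mean_edge_length <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  d <- function(i, j) sqrt(rowSums((v[f[, i], , drop = FALSE] - v[f[, j], , drop = FALSE])^2))
  mean(c(d(1, 2), d(2, 3), d(3, 1)))
}

face_normals <- function(mesh, normalize = TRUE) {
  v <- mesh$vertices; f <- mesh$faces
  e1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  e2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  n <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
             e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
             e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  if (normalize) {
    len <- sqrt(rowSums(n^2)); len[len == 0] <- 1
    n <- n / len
  }
  n
}

#' Angle-weighted vertex normals
#'
#' Per-vertex outward normals computed as the angle-weighted average of the
#' incident face normals (the weight of a face at a vertex is the interior
#' triangle angle at that vertex), normalised to unit length.
#'
#' @param mesh a [triangle_mesh()].
#' @return an `n x 3` matrix of unit normals.
#' @export
vertex_normals <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  fn <- face_normals(mesh)
  nrm <- matrix(0, nrow(v), 3L)
  corner_angle <- function(a, b, c3) {
    u <- v[b, , drop = FALSE] - v[a, , drop = FALSE]
    w <- v[c3, , drop = FALSE] - v[a, , drop = FALSE]
    cu <- sqrt(rowSums(u^2)); cw <- sqrt(rowSums(w^2))
    ct <- rowSums(u * w) / pmax(cu * cw, .Machine$double.eps)
    acos(pmin(1, pmax(-1, ct)))
  }
  ang <- cbind(corner_angle(f[, 1], f[, 2], f[, 3]),
               corner_angle(f[, 2], f[, 3], f[, 1]),
               corner_angle(f[, 3], f[, 1], f[, 2]))
  for (k in 1:3) {
    agg <- rowsum(ang[, k] * fn, group = f[, k])
    ids <- as.integer(rownames(agg))
    nrm[ids, ] <- nrm[ids, ] + agg
  }
  len <- sqrt(rowSums(nrm^2)); len[len == 0] <- 1
  nrm / len
}

#' Build a closed UV-parameterised mesh from a radial-style surface function
#'
#' Samples `fun(theta, phi)` (theta around the z axis in `[0, 2pi)`, phi the
#' latitude in `(-pi/2, pi/2)`) on a regular grid, adds the two pole points
#' (`phi = -pi/2`, `+pi/2`), and triangulates with a fixed sphere-like
#' connectivity so that the result is closed, orientable and genus 0.
#'
#' @param fun function of vectors `(theta, phi)` returning an `n x 3` matrix.
#' @param n_theta number of samples around the axis.
#' @param n_phi number of latitude rows excluding the poles.
#' @param name organ label.
#' @return a closed [triangle_mesh()].
#' @export
uv_mesh <- function(fun, n_theta = 40L, n_phi = 24L, name = "organ") {
  th <- 2 * pi * (seq_len(n_theta) - 1L) / n_theta
  ph <- -pi / 2 + pi * seq_len(n_phi) / (n_phi + 1L)
  gr <- expand.grid(theta = th, phi = ph) # theta fastest
  v <- fun(gr$theta, gr$phi)
  south <- fun(0, -pi / 2); north <- fun(0, pi / 2)
  verts <- rbind(south, v, north)
  is <- 1L
  idx <- function(i, j) 1L + (j - 1L) * n_theta + (i - 1L) %% n_theta + 1L
  in_ <- nrow(verts)
  f <- list()
  # south fan (phi row 1), outward orientation for CCW theta
  for (i in seq_len(n_theta)) f[[length(f) + 1L]] <- c(is, idx(i + 1L, 1L), idx(i, 1L))
  for (j in seq_len(n_phi - 1L)) {
    for (i in seq_len(n_theta)) {
      a <- idx(i, j); b <- idx(i + 1L, j); c3 <- idx(i + 1L, j + 1L); d <- idx(i, j + 1L)
      f[[length(f) + 1L]] <- c(a, b, c3)
      f[[length(f) + 1L]] <- c(a, c3, d)
    }
  }
  for (i in seq_len(n_theta)) f[[length(f) + 1L]] <- c(in_, idx(i, n_phi), idx(i + 1L, n_phi))
  m <- triangle_mesh(verts, do.call(rbind, f), name)
  if (mesh_volume(m) < 0) m$faces <- m$faces[, c(1L, 3L, 2L)]
  m
}

#' A UV sphere mesh
#'
#' @param radius sphere radius (mm).
#' @param center 3-vector centre.
#' @param n_theta,n_phi grid resolution, see [uv_mesh()].
#' @return a closed [triangle_mesh()].
#' @export
sphere_mesh <- function(radius = 25, center = c(0, 0, 0), n_theta = 40L, n_phi = 24L) {
  uv_mesh(function(th, ph) {
    cbind(center[1] + radius * cos(ph) * cos(th),
          center[2] + radius * cos(ph) * sin(th),
          center[3] + radius * sin(ph))
  }, n_theta, n_phi, name = "sphere")
}
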