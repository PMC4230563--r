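#' Generate new organ shapes from a fitted model
#'
#' Draws a coefficient matrix `W` from the per-mode mixture densities by
#' inversion sampling and reconstructs one new shape per row as
#' `X_new = Xbar + P W`. Deterministic given the seed.
#'
#' @param pdm a [build_pdm()] model.
#' @param coeff_model a [fit_coefficient_models()] result with the same
#'   number of modes.
#' @param n number of new shapes.
#' @param seed integer seed.
#' @param W optional explicit `n x k` coefficient matrix; when supplied no
#'   sampling happens (used e.g. to reconstruct the mean with `W = 0`).
#' @return an object of class `generated_cohort`: list with `shapes`
#'   (`n x 3m` matrix), `W`, `seed`.
#' @export
generate_shapes <- function(pdm, coeff_model, n = NULL, seed = 1L, W = NULL) {
  stopifnot(inherits(pdm, "pdm"))
  if (is.null(W)) {
    stopifnot(inherits(coeff_model, "coefficient_model"))
    if (coeff_model$k != pdm$k) {
      stop(sprintf("mode count mismatch: pdm has k = %d, coefficient model k = %d",
                   pdm$k, coeff_model$k))
    }
    W <- sample_coefficients(coeff_model, n, seed)
  } else {
    W <- as.matrix(W)
    if (ncol(W) > pdm$k) stop("W has more columns than retained modes")
  }
  shapes <- pdm_reconstruct(pdm, W)
  structure(list(shapes = shapes, W = W, seed = seed),
            class = "generated_cohort")
}

#' @export
print.generated_cohort <- function(x, ...) {
  cat(sprintf("generated_cohort: %d shapes, %d modes\n",
              nrow(x$shapes), ncol(x$W)))
  invisible(x)
}

closed_grid_faces <- function(n_theta, n_phi) {
  # pole 1, then n_phi rows of n_theta, then pole 2 (same as uv_mesh)
  idx <- function(i, j) 1L + (j - 1L) * n_theta + (i - 1L) %% n_theta + 1L
  f <- vector("list", 2L * n_theta * n_phi)
  k <- 0L
  for (i in seq_len(n_theta)) {
    k <- k + 1L; f[[k]] <- c(1L, idx(i + 1L, 1L), idx(i, 1L))
  }
  for (j in seq_len(n_phi - 1L)) {
    for (i in seq_len(n_theta)) {
      a <- idx(i, j); b <- idx(i + 1L, j); c3 <- idx(i + 1L, j + 1L); d <- idx(i, j + 1L)
      k <- k + 1L; f[[k]] <- c(a, b, c3)
      k <- k + 1L; f[[k]] <- c(a, c3, d)
    }
  }
  last <- 1L + n_phi * n_theta + 1L
  for (i in seq_len(n_theta)) {
    k <- k + 1L; f[[k]] <- c(last, idx(i, n_phi), idx(i + 1L, n_phi))
  }
  do.call(rbind, f[seq_len(k)])
}

#' Convert a shape vector back into a closed triangle mesh
#'
#' Re-grids a 3m shape vector onto its `m_u x m_v` parameter grid and
#' triangulates it with the grid's fixed connectivity: the periodic u seam
#' is welded and the two pole rows (v = 0, 1), which hold `m_u` copies of
#' each apex, are collapsed to single vertices. The vertex count is
#' therefore `m_u * (m_v - 2) + 2` for every shape of a cohort.
#'
#' @param x a 3m shape vector (points ordered as in [resample_points()]).
#' @param grid the [param_grid()] the shapes were sampled on.
#' @param name organ label.
#' @return a closed [triangle_mesh()].
#' @export
shape_vector_to_mesh <- function(x, grid, name = "generated") {
  stopifnot(inherits(grid, "param_grid"))
  P <- matrix(x, ncol = 3L, byrow = TRUE)
  if (nrow(P) != grid$m_u * grid$m_v) stop("shape vector does not match grid size")
  m_u <- grid$m_u; m_v <- grid$m_v
  gp <- function(a, b) P[(b - 1L) * m_u + a, , drop = FALSE]
  pole1 <- gp(1L, 1L); pole2 <- gp(1L, m_v)
  interior <- P[m_u + seq_len(m_u * (m_v - 2L)), , drop = FALSE]
  verts <- rbind(pole1, interior, pole2)
  faces <- closed_grid_faces(m_u, m_v - 2L)
  m <- triangle_mesh(verts, faces, name)
  if (mesh_volume(m) < 0) m$faces <- m$faces[, c(1L, 3L, 2L)]
  m
}

#' Export a generated cohort as triangle meshes
#'
#' Applies [shape_vector_to_mesh()] to every generated shape. Instances
#' whose mesh fails closure validation or has non-positive volume are kept
#' but flagged, never dropped.
#'
#' @param cohort a [generate_shapes()] result.
#' @param grid the shared [param_grid()].
#' @param name_prefix label prefix for the meshes.
#' @return list with `meshes` and logical `flagged` per instance.
#' @export
cohort_to_meshes <- function(cohort, grid, name_prefix = "generated") {
  stopifnot(inherits(cohort, "generated_cohort"))
  n <- nrow(cohort$shapes)
  meshes <- vector("list", n)
  flagged <- logical(n)
  for (i in seq_len(n)) {
    m <- shape_vector_to_mesh(cohort$shapes[i, ], grid,
                              sprintf("%s_%03d", name_prefix, i))
    ok <- tryCatch({
      validate_mesh(m, closed = TRUE)
      mesh_volume(m) > 0
    }, error = function(e) FALSE)
    if (!ok) {
      flagged[i] <- TRUE
      warning(sprintf("instance %d flagged: degenerate or self-folding geometry", i))
    }
    meshes[[i]] <- m
  }
  list(meshes = meshes, flagged = flagged)
}
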