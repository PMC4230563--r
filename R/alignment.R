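#' Scaling + translation transforms
#'
#' The training surfaces are brought into the reference frame by affine
#' transforms restricted to per-axis scaling and translation (no rotation):
#' `x -> s * x + t` componentwise. The class is closed under composition and
#' inversion.
#'
#' @param scale length-3 positive scale factors `(s_x, s_y, s_z)`.
#' @param translation length-3 translation in mm.
#' @return an object of class `scale_translate`.
#' @export
scale_translate <- function(scale = c(1, 1, 1), translation = c(0, 0, 0)) {
  scale <- rep_len(as.numeric(scale), 3L)
  translation <- rep_len(as.numeric(translation), 3L)
  if (any(scale <= 0)) stop("scale factors must be positive")
  structure(list(scale = scale, translation = translation),
            class = "scale_translate")
}

#' @export
print.scale_translate <- function(x, ...) {
  cat(sprintf("scale_translate: s = (%.6g, %.6g, %.6g), t = (%.6g, %.6g, %.6g) mm\n",
              x$scale[1], x$scale[2], x$scale[3],
              x$translation[1], x$translation[2], x$translation[3]))
  invisible(x)
}

#' @rdname scale_translate
#' @param T,T2 `scale_translate` transforms.
#' @export
invert_transform <- function(T) {
  stopifnot(inherits(T, "scale_translate"))
  scale_translate(1 / T$scale, -T$translation / T$scale)
}

#' @rdname scale_translate
#' @export
compose_transforms <- function(T, T2) {
  # returns the transform equivalent to applying T2 first, then T
  stopifnot(inherits(T, "scale_translate"), inherits(T2, "scale_translate"))
  scale_translate(T$scale * T2$scale, T$scale * T2$translation + T$translation)
}

apply_to_points <- function(T, pts) {
  sweep(sweep(pts, 2L, T$scale, `*`), 2L, T$translation, `+`)
}

#' Estimate a moment-matching alignment between two surfaces
#'
#' Finds the scaling + translation transform that maps the target mesh into
#' the reference's frame by moment matching: after the transform, the
#' target's vertex centroid equals the reference's, and the per-axis vertex
#' standard deviations equal the reference's (or, with `isotropic = TRUE`,
#' a single factor matches the RMS radius about the centroid).
#'
#' @param target,reference [triangle_mesh()] objects.
#' @param isotropic use one common scale factor for all axes.
#' @return a [scale_translate()] transform `T` with `apply_alignment(T,
#'   target)` aligned to `reference`.
#' @export
estimate_alignment <- function(target, reference, isotropic = FALSE) {
  stopifnot(inherits(target, "triangle_mesh"), inherits(reference, "triangle_mesh"))
  if (nrow(target$vertices) == 0L || nrow(reference$vertices) == 0L) {
    stop("cannot align empty meshes")
  }
  ct <- colMeans(target$vertices); cr <- colMeans(reference$vertices)
  sdt <- apply(target$vertices, 2L, stats::sd)
  sdr <- apply(reference$vertices, 2L, stats::sd)
  if (any(sdt < 1e-12)) {
    stop("degenerate target: zero vertex variance along axis ",
         which(sdt < 1e-12)[1])
  }
  s <- if (isotropic) rep(sqrt(sum(sdr^2) / sum(sdt^2)), 3L) else sdr / sdt
  scale_translate(s, cr - s * ct)
}

#' Apply an alignment transform to a mesh
#'
#' Maps every vertex `x -> s * x + t`; connectivity is untouched.
#'
#' @param T a [scale_translate()].
#' @param mesh a [triangle_mesh()].
#' @return the transformed [triangle_mesh()].
#' @export
apply_alignment <- function(T, mesh) {
  stopifnot(inherits(T, "scale_translate"), inherits(mesh, "triangle_mesh"))
  triangle_mesh(apply_to_points(T, mesh$vertices), mesh$faces, mesh$name)
}
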