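#' Contour stacks: per-slice closed organ outlines
#'
#' A `contour_stack` mimics a planning-system contour export: an ordered
#' series of closed planar polygons, one per axial slice, each with its z
#' coordinate in mm. The on-disk representation is a documented JSON schema:
#' \preformatted{
#' {"organ": "bladder", "slice_thickness_mm": 2.5,
#'  "slices": [{"z": 0.0, "points": [[x, y], ...]}, ...]}
#' }
#' Polygons are implicitly closed (the last point connects back to the
#' first), must be simple (non-self-intersecting) and have at least 3
#' vertices; z must be strictly increasing.
#'
#' @param slices list of `list(z = <mm>, points = <k x 2 matrix>)`.
#' @param organ organ label.
#' @param slice_thickness nominal slice spacing in mm.
#' @return an object of class `contour_stack`.
#' @export
contour_stack <- function(slices, organ = "organ", slice_thickness = NA_real_) {
  slices <- lapply(slices, function(s) {
    p <- as.matrix(s$points); storage.mode(p) <- "double"
    if (ncol(p) != 2L) stop("contour points must be 2-column (x, y)")
    list(z = as.numeric(s$z), points = p)
  })
  structure(list(organ = as.character(organ),
                 slice_thickness = as.numeric(slice_thickness),
                 slices = slices),
            class = "contour_stack")
}

#' @export
print.contour_stack <- function(x, ...) {
  zs <- vapply(x$slices, `[[`, 0, "z")
  cat(sprintf("contour_stack '%s': %d slices, z in [%.2f, %.2f] mm, thickness %.2f mm\n",
              x$organ, length(x$slices), min(zs), max(zs), x$slice_thickness))
  invisible(x)
}

segments_intersect <- function(p1, p2, p3, p4) {
  d1 <- p2 - p1; d2 <- p4 - p3
  den <- d1[1] * d2[2] - d1[2] * d2[1]
  if (abs(den) < 1e-14) return(FALSE) # parallel: treat as non-crossing
  t <- ((p3[1] - p1[1]) * d2[2] - (p3[2] - p1[2]) * d2[1]) / den
  u <- ((p3[1] - p1[1]) * d1[2] - (p3[2] - p1[2]) * d1[1]) / den
  eps <- 1e-12
  t > eps && t < 1 - eps && u > eps && u < 1 - eps
}

polygon_is_simple <- function(p) {
  n <- nrow(p)
  if (n < 3L) return(FALSE)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      # skip adjacent edges (sharing an endpoint), incl. the wrap pair
      if (j == i + 1L || (i == 1L && j == n)) next
      a1 <- p[i, ]; a2 <- p[i %% n + 1L, ]
      b1 <- p[j, ]; b2 <- p[j %% n + 1L, ]
      if (segments_intersect(a1, a2, b1, b2)) return(FALSE)
    }
  }
  TRUE
}

polygon_area <- function(p) {
  n <- nrow(p); j <- c(2:n, 1L)
  0.5 * sum(p[, 1] * p[j, 2] - p[j, 1] * p[, 2])
}

#' Validate a contour stack
#'
#' Enforces strictly increasing z, >= 3 points per polygon and simple
#' (non-self-intersecting) polygons. Idempotent.
#'
#' @param stack a [contour_stack()].
#' @param check_simple run the O(k^2) self-intersection test per polygon.
#' @return the validated stack, invisibly carrying `"validated" = TRUE`.
#' @export
validate_contours <- function(stack, check_simple = TRUE) {
  stopifnot(inherits(stack, "contour_stack"))
  if (length(stack$slices) == 0L) stop("contour stack has no slices")
  zs <- vapply(stack$slices, `[[`, 0, "z")
  if (any(!is.finite(zs))) stop("non-finite slice z")
  if (any(diff(zs) <= 0)) {
    stop(sprintf("slice z must be strictly increasing (violation near z = %g)",
                 zs[which(diff(zs) <= 0)[1] + 1L]))
  }
  for (i in seq_along(stack$slices)) {
    p <- stack$slices[[i]]$points
    if (nrow(p) < 3L) stop(sprintf("slice %d: polygon has fewer than 3 points", i))
    if (any(!is.finite(p))) stop(sprintf("slice %d: non-finite coordinates", i))
    if (check_simple && !polygon_is_simple(p)) {
      stop(sprintf("slice %d (z = %g): polygon self-intersects", i,
                   stack$slices[[i]]$z))
    }
  }
  attr(stack, "validated") <- TRUE
  stack
}

#' Read / write contour stacks as JSON
#'
#' See [contour_stack()] for the schema.
#'
#' @param path JSON file path.
#' @param validate validate after reading (default `TRUE`).
#' @return `read_contours` returns a [contour_stack()]; `write_contours`
#'   returns `path` invisibly.
#' @export
read_contours <- function(path, validate = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  obj <- jsonlite::fromJSON(path, simplifyMatrix = TRUE, simplifyDataFrame = FALSE)
  if (is.null(obj$slices)) stop("contour JSON missing 'slices'")
  slices <- lapply(obj$slices, function(s) list(z = s$z, points = s$points))
  st <- contour_stack(slices,
                      organ = if (!is.null(obj$organ)) obj$organ else "organ",
                      slice_thickness = if (!is.null(obj$slice_thickness_mm))
                        obj$slice_thickness_mm else NA_real_)
  if (validate) st <- validate_contours(st)
  st
}

#' @rdname read_contours
#' @param stack a [contour_stack()].
#' @export
write_contours <- function(stack, path) {
  stopifnot(inherits(stack, "contour_stack"))
  obj <- list(organ = stack$organ,
              slice_thickness_mm = stack$slice_thickness,
              slices = lapply(stack$slices, function(s)
                list(z = s$z, points = s$points)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
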