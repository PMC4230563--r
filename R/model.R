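#' Fit a statistical shape model to a training population of organ surfaces
#'
#' Runs the full modelling pipeline on a set of closed training meshes of
#' one organ:
#' \enumerate{
#'   \item align every training surface to the chosen reference by
#'     scaling + translation moment matching ([estimate_alignment()]);
#'   \item slice the reference into axial contours and loft a closed NURBS
#'     reference surface through them ([make_contour_stack()],
#'     [loft_contours()]);
#'   \item resample the reference surface on a fixed parameter grid and
#'     find, for every resampled point, its corresponding point on each
#'     aligned training surface ([correspond()]);
#'   \item deform the reference NURBS to each training surface through
#'     intermediate substeps ([match_surfaces()]) and resample the matched
#'     surface on the same grid, giving corresponded shape vectors;
#'   \item build the PCA point-distribution model `X = Xbar + P b`
#'     ([build_pdm()]) and fit a per-mode Gaussian-mixture density to the
#'     training coefficients ([fit_coefficient_models()]).
#' }
#' New statistically representative geometries are then drawn with
#' [simulate()].
#'
#' @param meshes list of closed [triangle_mesh()] training surfaces
#'   (N >= 2), or a list of [contour_stack()] objects (converted to lofted
#'   surface meshes first).
#' @param reference index of the training surface used as reference.
#' @param grid resampling [param_grid()] (default 50 x 50).
#' @param slice_thickness axial slice spacing (mm) for the reference
#'   contour extraction.
#' @param n_u contour resampling count / control columns of the loft.
#' @param k retained modes: a count, or a fraction in (0, 1) for the
#'   cumulative variance threshold (default 0.90).
#' @param r_max maximum mixture components per mode (BIC-selected).
#' @param match_cfg a [match_config()].
#' @param isotropic use a single alignment scale factor instead of
#'   per-axis factors.
#' @param seed integer seed controlling every stochastic stage.
#' @param verbose print per-stage progress.
#' @return an object of class `shape_model` with components `pdm`,
#'   `coefficients` (N x k training coefficient matrix), `coeff_model`,
#'   `reference_surface`, `grid`, `transforms`, `shapes` (N x 3m matrix),
#'   `match_traces`, `converged`, `config`, `call`.
#' @seealso [simulate.shape_model()], [predict.shape_model()],
#'   [plot.shape_model()], [write_model()]
#' @export
shape_model <- function(meshes, reference = 1L, grid = param_grid(50L, 50L),
                        slice_thickness = 2.5, n_u = 36L, k = 0.90,
                        r_max = 3L, match_cfg = match_config(),
                        isotropic = FALSE, seed = 1L, verbose = FALSE) {
  cl <- match.call()
  if (!is.list(meshes) || length(meshes) < 2L) {
    stop("need a list of at least N = 2 training surfaces")
  }
  meshes <- lapply(meshes, function(m) {
    if (inherits(m, "contour_stack")) {
      surf <- loft_contours(m, n_u = n_u)
      m <- shape_vector_to_mesh(as.vector(t(resample_points(surf, grid))), grid,
                                name = m$organ)
    }
    validate_mesh(m, closed = TRUE)
  })
  N <- length(meshes)
  reference <- as.integer(reference)
  if (reference < 1L || reference > N) stop("reference index out of range")
  say <- function(...) if (verbose) message(sprintf(...))

  ref_mesh <- meshes[[reference]]
  say("aligning %d surfaces to reference %d", N, reference)
  transforms <- vector("list", N)
  aligned <- vector("list", N)
  for (i in seq_len(N)) {
    transforms[[i]] <- if (i == reference) scale_translate() else
      estimate_alignment(meshes[[i]], ref_mesh, isotropic = isotropic)
    aligned[[i]] <- apply_alignment(transforms[[i]], meshes[[i]])
  }

  say("lofting reference NURBS surface")
  stack <- make_contour_stack(ref_mesh, slice_thickness)
  ref_surface <- loft_contours(stack, n_u = n_u)
  X_ref <- resample_points(ref_surface, grid)
  normals <- surface_normals(ref_surface, grid$uv[, "u"], grid$uv[, "v"])

  shapes <- matrix(NA_real_, N, 3L * nrow(X_ref))
  match_traces <- vector("list", N)
  converged <- rep(TRUE, N)
  for (i in seq_len(N)) {
    if (i == reference) {
      shapes[i, ] <- as.vector(t(X_ref))
      next
    }
    say("matching surface %d / %d", i, N)
    corr <- correspond(X_ref, aligned[[i]], normals = normals)
    mr <- match_surfaces(ref_surface, grid, corr, match_cfg)
    match_traces[[i]] <- mr$trace
    converged[i] <- mr$converged
    shapes[i, ] <- as.vector(t(resample_points(mr$surface, grid)))
  }

  say("building point-distribution model")
  pdm <- build_pdm(shapes, k = k)
  b <- pdm_project(pdm, shapes)
  say("fitting coefficient mixtures (k = %d modes)", pdm$k)
  coeff_model <- fit_coefficient_models(b, r_max = r_max,
                                        seed = (as.integer(seed) + 101L) %% 2147483647L)

  structure(list(pdm = pdm, coefficients = b, coeff_model = coeff_model,
                 reference_surface = ref_surface, grid = grid,
                 transforms = transforms, shapes = shapes,
                 match_traces = match_traces, converged = converged,
                 config = list(N = N, reference = reference,
                               slice_thickness = slice_thickness, n_u = n_u,
                               k = k, r_max = r_max, match_cfg = match_cfg,
                               isotropic = isotropic, seed = as.integer(seed)),
                 call = cl),
            class = "shape_model")
}

#' @export
print.shape_model <- function(x, ...) {
  spec <- variance_spectrum(x$pdm)
  cat("Statistical shape model (point-distribution model + mode mixtures)\n")
  cat(sprintf("  training shapes : %d (reference: %d)\n",
              x$config$N, x$config$reference))
  cat(sprintf("  surface points  : %d (grid %d x %d)\n",
              x$pdm$m, x$grid$m_u, x$grid$m_v))
  cat(sprintf("  retained modes  : %d, covering %.1f%% of shape variance\n",
              x$pdm$k, spec$cumulative[x$pdm$k]))
  rs <- vapply(x$coeff_model$mixtures, `[[`, 0L, "r")
  cat(sprintf("  mixture comps   : %s\n", paste(rs, collapse = ", ")))
  if (!all(x$converged)) {
    cat(sprintf("  warning: %d surface match(es) did not converge\n",
                sum(!x$converged)))
  }
  invisible(x)
}

#' @export
summary.shape_model <- function(object, n_modes = 10L, ...) {
  spec <- variance_spectrum(object$pdm)
  nm <- min(n_modes, length(spec$percent))
  res <- residuals(object)
  out <- list(spectrum = data.frame(mode = seq_len(nm),
                                    percent = spec$percent[seq_len(nm)],
                                    cumulative = spec$cumulative[seq_len(nm)]),
              k = object$pdm$k,
              eigenvalues = object$pdm$eigenvalues,
              coefficient_sd = apply(object$coefficients, 2L, stats::sd),
              mixture_components = vapply(object$coeff_model$mixtures, `[[`, 0L, "r"),
              match_rms = res,
              converged = object$converged,
              N = object$config$N)
  class(out) <- "summary.shape_model"
  out
}

#' @export
print.summary.shape_model <- function(x, ...) {
  cat("Shape model summary\n")
  cat(sprintf("  N = %d training shapes, k = %d retained modes\n", x$N, x$k))
  cat("  variance spectrum (%):\n")
  print(round(x$spectrum, 2), row.names = FALSE)
  cat(sprintf("  surface-match RMS residual: median %.3g mm (max %.3g mm)\n",
              stats::median(x$match_rms, na.rm = TRUE),
              suppressWarnings(max(x$match_rms, na.rm = TRUE))))
  cat(sprintf("  mixture components per mode: %s\n",
              paste(x$mixture_components, collapse = ", ")))
  invisible(x)
}

#' @export
coef.shape_model <- function(object, ...) object$coefficients

#' Residual surface-matching error per training shape
#'
#' Final-substep RMS distance (mm) between the deformed reference surface
#' points and the corresponded target points, `NA` for the reference
#' itself (which is matched by construction).
#'
#' @param object a [shape_model()].
#' @param ... unused.
#' @return numeric vector of length N.
#' @export
residuals.shape_model <- function(object, ...) {
  vapply(object$match_traces, function(tr) {
    if (is.null(tr)) NA_real_ else tr$rms[nrow(tr)]
  }, numeric(1))
}

#' Reconstruct shapes from mode coefficients
#'
#' With `newdata = NULL` returns the mean shape; otherwise reconstructs
#' `Xbar + P b` for each row of coefficients.
#'
#' @param object a [shape_model()].
#' @param newdata coefficient vector or `n x k` matrix.
#' @param type `"shape"` for 3m vectors, `"mesh"` for closed
#'   [triangle_mesh()] objects.
#' @param ... unused.
#' @return matrix of shape vectors, or list of meshes.
#' @export
predict.shape_model <- function(object, newdata = NULL,
                                type = c("shape", "mesh"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) newdata <- matrix(0, 1L, object$pdm$k)
  if (!is.matrix(newdata)) newdata <- matrix(newdata, nrow = 1L)
  shapes <- pdm_reconstruct(object$pdm, newdata)
  if (type == "shape") return(shapes)
  lapply(seq_len(nrow(shapes)), function(i) {
    shape_vector_to_mesh(shapes[i, ], object$grid,
                         sprintf("predicted_%03d", i))
  })
}

#' Simulate new organ geometries from a fitted shape model
#'
#' Draws `nsim` coefficient rows from the fitted per-mode mixtures by
#' inversion sampling and reconstructs the new shapes `X = Xbar + P W`.
#'
#' @param object a [shape_model()].
#' @param nsim number of new geometries.
#' @param seed integer seed (default: the model's own seed).
#' @param type `"shape"` (cohort of 3m vectors) or `"mesh"`.
#' @param ... unused.
#' @return a [generate_shapes()] cohort; for `type = "mesh"` with an extra
#'   element `meshes` (and `flagged`).
#' @export
simulate.shape_model <- function(object, nsim = 1L, seed = NULL,
                                 type = c("shape", "mesh"), ...) {
  type <- match.arg(type)
  if (is.null(seed)) seed <- object$config$seed
  cohort <- generate_shapes(object$pdm, object$coeff_model, n = nsim, seed = seed)
  if (type == "mesh") {
    ex <- cohort_to_meshes(cohort, object$grid)
    cohort$meshes <- ex$meshes
    cohort$flagged <- ex$flagged
  }
  cohort
}

#' Plot a fitted shape model
#'
#' `which = "spectrum"` draws the relative eigenvalue scree with its
#' cumulative curve; `which = "coefficients"` overlays the fitted mixture
#' density on a histogram of the training coefficients of `mode`.
#'
#' @param x a [shape_model()].
#' @param which `"spectrum"` or `"coefficients"`.
#' @param mode mode index for the coefficient panel.
#' @param ... forwarded to the base plotting calls.
#' @export
plot.shape_model <- function(x, which = c("spectrum", "coefficients"),
                             mode = 1L, ...) {
  which <- match.arg(which)
  if (which == "spectrum") {
    spec <- variance_spectrum(x$pdm)
    nshow <- min(10L, length(spec$percent))
    bp <- graphics::barplot(spec$percent[seq_len(nshow)],
                            names.arg = seq_len(nshow),
                            xlab = "mode", ylab = "relative eigenvalue (%)",
                            ylim = c(0, 105), ...)
    graphics::lines(bp, spec$cumulative[seq_len(nshow)], type = "b", pch = 19)
    graphics::abline(h = 90, lty = 2)
  } else {
    b <- x$coefficients[, mode]
    g <- x$coeff_model$mixtures[[mode]]
    xs <- seq(min(b) - 2 * stats::sd(b), max(b) + 2 * stats::sd(b), length.out = 300)
    dens <- exp(gmm_log_density(g, xs))
    graphics::hist(b, freq = FALSE, main = sprintf("mode %d coefficient", mode),
                   xlab = "b", ylim = c(0, max(dens) * 1.2), ...)
    graphics::lines(xs, dens, lwd = 2)
  }
  invisible(x)
}

#' Save / load a fitted shape model
#'
#' `write_model` serialises the complete fitted object (arrays round-trip
#' bit-exactly); `read_model` restores it. `export_model_json` writes the
#' numerical model content (mean, eigenvectors, eigenvalues, knots,
#' control points, mixture parameters, configuration) as a portable JSON
#' document for use outside R.
#'
#' @param model a [shape_model()].
#' @param path file path (`.rds` for the native archive, `.json` for the
#'   export).
#' @return `read_model` returns the model; the writers return `path`
#'   invisibly.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "shape_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "shape_model")) stop("file does not contain a shape_model")
  model
}

#' @rdname write_model
#' @export
export_model_json <- function(model, path) {
  stopifnot(inherits(model, "shape_model"))
  s <- model$reference_surface
  obj <- list(
    mean = model$pdm$mean,
    eigenvectors = model$pdm$eigenvectors,
    eigenvalues = model$pdm$eigenvalues,
    k = model$pdm$k,
    m = model$pdm$m,
    grid = list(m_u = model$grid$m_u, m_v = model$grid$m_v),
    nurbs = list(degree_u = s$degree_u, degree_v = s$degree_v,
                 knots_u = s$knots_u, knots_v = s$knots_v,
                 control_points = s$control_points, weights = s$weights,
                 periodic_u = s$periodic_u, caps = s$caps),
    mixtures = lapply(model$coeff_model$mixtures, function(g) {
      list(weights = g$weights, means = g$means, variances = g$variances)
    }),
    config = model$config[c("N", "reference", "slice_thickness", "n_u",
                            "r_max", "isotropic", "seed")]
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
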