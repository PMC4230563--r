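# one small end-to-end fit shared across the interface tests
fit_small_model <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      pop <- make_population(n = 6, mode_sds = c(4, 2.5, 1.5), noise_sd = 0.2,
                             n_theta = 24, n_phi = 14, seed = 81)
      cache <<- list(pop = pop,
                     fit = shape_model(pop$meshes, grid = param_grid(30, 30),
                                       n_u = 24, slice_thickness = 4,
                                       match_cfg = match_config(n_substeps = 4),
                                       seed = 81))
    }
    cache
  }
})

test_that("the fitted model exposes the standard modelling interface", {
  env <- fit_small_model()
  fit <- env$fit
  expect_s3_class(fit, "shape_model")
  expect_output(print(fit), "retained modes")
  sm <- summary(fit)
  expect_s3_class(sm, "summary.shape_model")
  expect_output(print(sm), "variance spectrum")

  b <- coef(fit)
  expect_equal(dim(b), c(6L, fit$pdm$k))
  # training coefficient variance equals the eigenvalues
  expect_equal(apply(b, 2, var), fit$pdm$eigenvalues[seq_len(fit$pdm$k)],
               tolerance = 1e-8)

  r <- residuals(fit)
  expect_length(r, 6L)
  expect_true(is.na(r[1])) # the reference needs no matching
  expect_true(all(r[-1] < 1.5)) # mm

  # predict: mean and reconstruction
  mu <- predict(fit)
  expect_equal(drop(mu), fit$pdm$mean)
  mesh <- predict(fit, type = "mesh")[[1]]
  expect_silent(validate_mesh(mesh))

  png_path <- tempfile(fileext = ".png")
  grDevices::png(png_path)
  expect_silent(plot(fit))
  expect_silent(plot(fit, which = "coefficients", mode = 1))
  grDevices::dev.off()
  unlink(png_path)
})

test_that("simulate draws deterministic cohorts of valid meshes", {
  fit <- fit_small_model()$fit
  s1 <- simulate(fit, nsim = 5, seed = 4)
  s2 <- simulate(fit, nsim = 5, seed = 4)
  expect_identical(s1$shapes, s2$shapes)
  sm <- simulate(fit, nsim = 2, seed = 4, type = "mesh")
  expect_length(sm$meshes, 2L)
  expect_silent(validate_mesh(sm$meshes[[1]]))
})

test_that("fitted models round-trip bit-exactly through the archive", {
  fit <- fit_small_model()$fit
  path <- tempfile(fileext = ".rds")
  write_model(fit, path)
  back <- read_model(path)
  expect_identical(back$pdm$mean, fit$pdm$mean)
  expect_identical(back$pdm$eigenvectors, fit$pdm$eigenvectors)
  expect_identical(back$reference_surface$control_points,
                   fit$reference_surface$control_points)
  expect_identical(back$shapes, fit$shapes)
  # and generation from the restored model is identical
  expect_identical(simulate(back, nsim = 3, seed = 2)$shapes,
                   simulate(fit, nsim = 3, seed = 2)$shapes)
  unlink(path)

  jpath <- tempfile(fileext = ".json")
  export_model_json(fit, jpath)
  obj <- jsonlite::fromJSON(jpath)
  expect_equal(obj$k, fit$pdm$k)
  expect_equal(obj$mean, fit$pdm$mean, tolerance = 1e-12)
  expect_length(obj$mixtures$weights, fit$pdm$k)
  unlink(jpath)
})

test_that("contour-stack input and degenerate configs are handled", {
  expect_error(shape_model(list(tetra_mesh())), "at least N = 2")
  pop <- fit_small_model()$pop
  expect_error(shape_model(pop$meshes, reference = 99), "out of range")

  # training from contour stacks instead of meshes
  stacks <- lapply(pop$meshes[1:3], make_contour_stack, slice_thickness = 4)
  fit2 <- shape_model(stacks, grid = param_grid(24, 24), n_u = 20,
                      slice_thickness = 4,
                      match_cfg = match_config(n_substeps = 3), seed = 5)
  expect_s3_class(fit2, "shape_model")
  expect_equal(fit2$config$N, 3L)
})

test_that("rerunning the pipeline with the same seed is bit-identical", {
  pop <- make_population(n = 4, mode_sds = c(3, 1.5), noise_sd = 0.2,
                         n_theta = 20, n_phi = 12, seed = 91)
  f1 <- shape_model(pop$meshes, grid = param_grid(24, 24), n_u = 18,
                    slice_thickness = 5,
                    match_cfg = match_config(n_substeps = 3), seed = 91)
  f2 <- shape_model(pop$meshes, grid = param_grid(24, 24), n_u = 18,
                    slice_thickness = 5,
                    match_cfg = match_config(n_substeps = 3), seed = 91)
  expect_identical(f1$shapes, f2$shapes)
  expect_identical(simulate(f1, nsim = 4)$shapes, simulate(f2, nsim = 4)$shapes)
})
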