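test_that("zero variance and zero noise reproduce the base mesh", {
  pop <- make_population(n = 3, mode_sds = rep(0, 3), noise_sd = 0,
                         n_theta = 16, n_phi = 10, seed = 1)
  for (m in pop$meshes) expect_equal(m$vertices, pop$base$vertices)
  expect_equal(pop$coefficients, matrix(0, 3, 3))
})

test_that("a single inflation mode yields a rank-1 vertex population", {
  pop <- make_population(n = 10, mode_sds = 5, noise_sd = 0,
                         n_theta = 16, n_phi = 10, seed = 2)
  X <- t(vapply(pop$meshes, function(m) as.vector(t(m$vertices)),
                numeric(3 * nrow(pop$base$vertices))))
  pdm <- build_pdm(X, k = 3)
  spec <- variance_spectrum(pdm)
  expect_gt(spec$percent[1], 99.9)
  # and the coefficient scale matches: lambda_1 ~ sd^2 * ||field||^2
  f1 <- pop$mode_fields[[1]]
  expect_equal(pdm$eigenvalues[1] / sum(f1^2), var(pop$coefficients[, 1]),
               tolerance = 1e-6)
})

test_that("populations are deterministic given config and seed", {
  p1 <- make_population(n = 4, n_theta = 14, n_phi = 8, seed = 33)
  p2 <- make_population(n = 4, n_theta = 14, n_phi = 8, seed = 33)
  p3 <- make_population(n = 4, n_theta = 14, n_phi = 8, seed = 34)
  expect_identical(p1$meshes[[3]]$vertices, p2$meshes[[3]]$vertices)
  expect_false(identical(p1$meshes[[3]]$vertices, p3$meshes[[3]]$vertices))
})

test_that("all presets produce valid closed meshes", {
  for (preset in c("bladder", "rectum", "intestine")) {
    pop <- make_population(n = 2, preset = preset, mode_sds = c(2, 1),
                           noise_sd = 0.1, n_theta = 20, n_phi = 12, seed = 5)
    for (m in pop$meshes) expect_silent(validate_mesh(m))
  }
})

test_that("bimodal mode-1 coefficients have the designed mixture law", {
  x <- draw_mode_coefficients(20000, 8, bimodal = TRUE, seed = 12)
  expect_equal(sd(x), 8, tolerance = 0.15)       # total SD preserved
  expect_equal(mean(x), 0, tolerance = 0.2)      # symmetric
  s <- 8 / sqrt(5)
  expect_equal(mean(x[x > 0]), 2 * s, tolerance = 0.15) # component mean at 2s
  # dip at zero: central mass well below that of an N(0, sd^2) with equal sd
  p_unimodal <- 2 * pnorm(s / 2 / 8) - 1
  expect_lt(mean(abs(x) < s / 2), 0.5 * p_unimodal)
})

test_that("mode fields are moment-neutralised on request", {
  pop <- make_population(n = 2, moment_neutral = TRUE, mode_sds = c(3, 2, 1),
                         n_theta = 20, n_phi = 12, seed = 3)
  v <- pop$base$vertices
  xc <- sweep(v, 2, colMeans(v))
  for (f in pop$mode_fields) {
    expect_lt(max(abs(colMeans(f))), 1e-12)               # no translation
    for (d in 1:3) {
      expect_lt(abs(sum(xc[, d] * f[, d])) / sum(xc[, d]^2), 1e-12) # no scale
    }
  }
  # population_mode_basis reproduces the vertex fields exactly
  rb <- population_mode_basis(v, pop)
  for (q in 1:3) expect_equal(rb[[q]], pop$mode_fields[[q]], tolerance = 1e-12)
})

test_that("mesh slicing matches analytic sphere sections", {
  s <- sphere_mesh(25, n_theta = 64, n_phi = 40)
  st <- make_contour_stack(s, 2.5)
  expect_equal(length(st$slices), 19L) # z = -22.5 .. 22.5
  for (k in c(1, 8, 19)) {
    sl <- st$slices[[k]]
    expect_lt(max(abs(sqrt(rowSums(sl$points^2)) - sqrt(625 - sl$z^2))), 0.08)
  }
  # slice -> loft -> resample round trip within 1% of the radius
  surf <- loft_contours(st, n_u = 36)
  pts <- resample_points(surf, param_grid(40, 40))
  expect_lt(max(abs(sqrt(rowSums(pts^2)) - 25)), 0.01 * 25)
})

test_that("invalid population configs are rejected", {
  expect_error(make_population(n = 1), "at least 2")
  expect_error(make_population(n = 3, mode_sds = c(-1, 2)), ">= 0")
  expect_error(make_population(n = 2, mode_sds = rep(1, 9)), "at most")
})
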