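test_that("intermediate targets follow the substep arithmetic", {
  X1 <- matrix(0, 4, 3)
  X2 <- matrix(8, 4, 3)
  tg <- intermediate_targets(X1, X2, 4)
  expect_length(tg, 4)
  expect_equal(tg[[2]], matrix(4, 4, 3)) # j = 2 of n = 4: 0 + 8 * 2/4
  expect_equal(tg[[4]], X2)              # j = n reaches the target exactly
  # degenerate: X1 = X2 keeps every substep at X1
  same <- intermediate_targets(X1, X1, 3)
  for (s in same) expect_equal(s, X1)
  expect_error(intermediate_targets(X1, matrix(0, 5, 3), 2), "identical dimensions")
})

test_that("warping to the current surface points changes nothing", {
  surf <- loft_contours(sphere_contours(15, 3), n_u = 16)
  g <- param_grid(24, 24)
  X <- resample_points(surf, g)
  out <- warp_step(surf, g, X, damping = 1, lambda = 0)
  expect_equal(out$control_points, surf$control_points, tolerance = 1e-9)
})

test_that("a translation target is matched exactly by shifted control points", {
  surf <- loft_contours(sphere_contours(15, 3), n_u = 16)
  g <- param_grid(24, 24)
  X <- resample_points(surf, g)
  t_vec <- c(3, 0, 0)
  out <- warp_step(surf, g, sweep(X, 2, t_vec, `+`), damping = 1, lambda = 0)
  expect_equal(out$control_points[, , 1], surf$control_points[, , 1] + 3,
               tolerance = 1e-8)
  expect_equal(out$control_points[, , 2], surf$control_points[, , 2],
               tolerance = 1e-8)

  # and through the full substep matcher with default ridge + damping
  co <- structure(list(reference_points = X,
                       target_points = sweep(X, 2, t_vec, `+`),
                       distance = rep(3, nrow(X)),
                       face = integer(nrow(X)),
                       element = rep("face", nrow(X)),
                       method = rep("closest", nrow(X))),
                  class = "correspondence_map")
  mr <- match_surfaces(surf, g, co,
                       match_config(n_substeps = 1, tol = 1e-10, max_iters = 200))
  expect_true(mr$converged)
  expect_lt(mr$trace$rms[nrow(mr$trace)], 1e-8)
  expect_equal(mr$surface$control_points[, , 1], surf$control_points[, , 1] + 3,
               tolerance = 1e-7)
  # topology preserved bit-for-bit
  expect_identical(mr$surface$knots_u, surf$knots_u)
  expect_identical(mr$surface$knots_v, surf$knots_v)
  expect_identical(mr$surface$degree_u, surf$degree_u)
})

test_that("residuals decrease monotonically within substeps", {
  set.seed(41)
  surf <- loft_contours(sphere_contours(15, 3), n_u = 16)
  g <- param_grid(24, 24)
  X <- resample_points(surf, g)
  tgt <- X * 1.08 + matrix(rnorm(length(X), 0, 0.2), nrow(X))
  co <- structure(list(reference_points = X, target_points = tgt,
                       distance = sqrt(rowSums((X - tgt)^2)),
                       face = integer(nrow(X)),
                       element = rep("face", nrow(X)),
                       method = rep("closest", nrow(X))),
                  class = "correspondence_map")
  # inspect per-iteration residuals via a manual warp loop
  op <- shapepop:::collocation_operator(surf, g)
  fac <- shapepop:::warp_factorization(op, 1e-6)
  cur <- surf
  rms <- numeric(0)
  for (it in 1:20) {
    st <- shapepop:::warp_step_internal(cur, op, fac, tgt, 0.8)
    cur <- st$surface
    rms <- c(rms, sqrt(mean(st$resid^2)))
  }
  expect_true(all(diff(rms) <= 1e-10))

  # full matcher trace is recorded per substep; each substep's residual is
  # against its own intermediate target, and the last one (the full target)
  # ends well below the initial displacement
  mr <- match_surfaces(surf, g, co, match_config(n_substeps = 5))
  expect_equal(nrow(mr$trace), 5)
  expect_lt(mr$trace$rms[5], 0.5 * mean(co$distance))
})

test_that("matching a scaled sphere surface converges below 0.1% of radius", {
  surf <- loft_contours(sphere_contours(20, 2.5, n_pts = 160), n_u = 28)
  g <- param_grid(40, 40)
  X <- resample_points(surf, g)
  ctr <- colMeans(X)
  tgt <- sweep(sweep(X, 2, ctr), 1, rep(1.1, nrow(X)), `*`)
  tgt <- sweep(tgt, 2, ctr, `+`)
  co <- structure(list(reference_points = X, target_points = tgt,
                       distance = sqrt(rowSums((X - tgt)^2)),
                       face = integer(nrow(X)),
                       element = rep("face", nrow(X)),
                       method = rep("closest", nrow(X))),
                  class = "correspondence_map")
  mr <- match_surfaces(surf, g, co, match_config(n_substeps = 5))
  expect_lt(mr$trace$rms[5], 0.001 * 20)
})

test_that("more substeps never worsen the final residual on a small battery", {
  set.seed(43)
  surf <- loft_contours(sphere_contours(15, 3), n_u = 16)
  g <- param_grid(24, 24)
  X <- resample_points(surf, g)
  finals <- sapply(1:3, function(case) {
    tgt <- X * (1 + 0.05 * case) + matrix(rnorm(length(X), 0, 0.3), nrow(X))
    co <- structure(list(reference_points = X, target_points = tgt,
                         distance = sqrt(rowSums((X - tgt)^2)),
                         face = integer(nrow(X)),
                         element = rep("face", nrow(X)),
                         method = rep("closest", nrow(X))),
                    class = "correspondence_map")
    c(match_surfaces(surf, g, co, match_config(n_substeps = 1))$trace$rms[1],
      match_surfaces(surf, g, co, match_config(n_substeps = 5))$trace$rms[5])
  })
  expect_true(all(finals[2, ] <= finals[1, ] + 1e-8))
})

test_that("a too-coarse grid is rejected as rank deficient", {
  surf <- loft_contours(sphere_contours(15, 3), n_u = 16)
  g <- param_grid(8, 8) # 64 points for ~200 free controls
  X <- matrix(0, 64, 3)
  expect_error(warp_step(surf, g, X, lambda = 0), "denser grid")
})
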