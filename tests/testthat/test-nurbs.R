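test_that("basis functions reproduce Bernstein values and partition unity", {
  expect_equal(basis_functions(2, c(0, 0, 0, 1, 1, 1), 0.5), c(0.25, 0.5, 0.25))
  expect_error(basis_functions(2, c(0, 0, 0, 1, 1, 1), 1.5), "outside")

  set.seed(31)
  knots <- c(0, 0, 0, 0, sort(runif(5)), 1, 1, 1, 1)
  for (u in c(0, runif(20), 1)) {
    b <- basis_functions(3, knots, u)
    expect_true(all(b >= 0))
    expect_equal(sum(b), 1, tolerance = 1e-12)
  }
})

test_that("triangular-scheme basis equals the recursive Cox-de Boor oracle", {
  knots <- c(0, 0, 0, 0, 1, 2, 3, 3, 3, 3)
  n <- length(knots) - 4
  for (u in c(0.3, 1, 1.5, 2.2, 2.9)) {
    impl <- basis_functions(3, knots, u)
    oracle <- vapply(seq_len(n), function(i) coxdeboor_recursive(i, 3, knots, u),
                     numeric(1))
    expect_equal(impl, oracle, tolerance = 1e-12)
  }
  # and on a random clamped knot vector, degree 2
  set.seed(7)
  k2 <- c(0, 0, 0, sort(runif(4)), 1, 1, 1)
  n2 <- length(k2) - 3
  for (u in runif(10)) {
    expect_equal(basis_functions(2, k2, u),
                 vapply(seq_len(n2), function(i) coxdeboor_recursive(i, 2, k2, u),
                        numeric(1)),
                 tolerance = 1e-12)
  }
})

test_that("surface evaluation is affine-invariant and matches closed forms", {
  # constant control net: every parameter returns that point
  cp <- array(rep(c(3, -1, 2), each = 8), c(4, 2, 3))
  s <- nurbs_surface(2, 1, c(0, 0, 0, 0.5, 1, 1, 1), c(0, 0, 1, 1), cp)
  pts <- evaluate_surface(s, c(0, 0.3, 0.9), c(0.1, 0.5, 1))
  expect_equal(pts, matrix(rep(c(3, -1, 2), each = 3), 3), tolerance = 1e-12)

  # bilinear patch over the unit square
  cpb <- array(NA_real_, c(2, 2, 3))
  cpb[1, 1, ] <- c(0, 0, 0); cpb[2, 1, ] <- c(1, 0, 0)
  cpb[1, 2, ] <- c(0, 1, 0); cpb[2, 2, ] <- c(1, 1, 0)
  bl <- nurbs_surface(1, 1, c(0, 0, 1, 1), c(0, 0, 1, 1), cpb)
  expect_equal(drop(evaluate_surface(bl, 0.5, 0.5)), c(0.5, 0.5, 0))

  # affine invariance under scaling + translation
  surf <- loft_contours(sphere_contours(20, 4), n_u = 16)
  T1 <- scale_translate(c(1.5, 0.7, 2), c(3, -4, 1))
  surf2 <- surf
  for (d in 1:3) {
    surf2$control_points[, , d] <-
      surf$control_points[, , d] * T1$scale[d] + T1$translation[d]
  }
  uv <- cbind(runif(20), runif(20))
  p1 <- evaluate_surface(surf, uv[, 1], uv[, 2])
  p2 <- evaluate_surface(surf2, uv[, 1], uv[, 2])
  expect_equal(p2, sweep(sweep(p1, 2, T1$scale, `*`), 2, T1$translation, `+`),
               tolerance = 1e-9)
})

test_that("unit-weight evaluation equals an independent tensor B-spline sum", {
  surf <- loft_contours(sphere_contours(15, 3), n_u = 12)
  d <- dim(surf$control_points)
  for (uv in list(c(0.12, 0.4), c(0.77, 0.9), c(0.5, 0.05))) {
    bu_full <- vapply(seq_len(d[1] + surf$degree_u), function(i)
      coxdeboor_recursive(i, surf$degree_u, surf$knots_u, uv[1]), numeric(1))
    bu <- numeric(d[1])
    for (i in seq_along(bu_full)) {
      j <- (i - 1L) %% d[1] + 1L
      bu[j] <- bu[j] + bu_full[i]
    }
    bv <- vapply(seq_len(d[2]), function(j)
      coxdeboor_recursive(j, surf$degree_v, surf$knots_v, uv[2]), numeric(1))
    oracle <- vapply(1:3, function(k) drop(bu %*% surf$control_points[, , k] %*% bv),
                     numeric(1))
    expect_equal(drop(evaluate_surface(surf, uv[1], uv[2])), oracle,
                 tolerance = 1e-10)
  }
})

test_that("loft interpolates its resampled contour points", {
  st <- sphere_contours(20, 2.5)
  surf <- loft_contours(st, n_u = 24)
  up <- attr(surf, "u_params"); vp <- attr(surf, "v_params")
  # skip the two cap rows; interior rows must hit the resampled points
  for (k in c(2, 5, length(vp) - 1)) {
    z_k <- st$slices[[k - 1]]$z
    pts <- evaluate_surface(surf, up, rep(vp[k], length(up)))
    expect_lt(max(abs(pts[, 3] - z_k)), 1e-6)
    r_true <- sqrt(400 - z_k^2)
    # points lie on the resampled polygon: radius within polygon chord error
    expect_lt(max(abs(sqrt(rowSums(pts[, 1:2]^2)) - r_true)), 0.05)
  }
})

test_that("identical stacked circles loft to a straight cylinder", {
  th <- 2 * pi * (0:63) / 64
  st <- contour_stack(lapply(0:7, function(k)
    list(z = 2.5 * k, points = 20 * cbind(cos(th), sin(th)))),
    organ = "cyl", slice_thickness = 2.5)
  surf <- loft_contours(st, n_u = 32, cap_ends = FALSE)
  up <- attr(surf, "u_params"); vp <- attr(surf, "v_params")
  pts <- evaluate_surface(surf, rep(up, length(vp)), rep(vp, each = length(up)))
  expect_lt(max(abs(sqrt(rowSums(pts[, 1:2]^2)) - 20)), 1e-6 + 20 * (1 - cos(pi / 64)))
})

test_that("cone loft reproduces the linear radius profile", {
  th <- 2 * pi * (0:63) / 64
  radii <- seq(30, 6, length.out = 9)
  st <- contour_stack(lapply(seq_along(radii), function(k)
    list(z = 2.5 * (k - 1), points = radii[k] * cbind(cos(th), sin(th)))),
    organ = "cone", slice_thickness = 2.5)
  surf <- loft_contours(st, n_u = 32, cap_ends = FALSE)
  vs <- seq(0, 1, length.out = 41)
  pts <- evaluate_surface(surf, rep(0.3, length(vs)), vs)
  r_obs <- sqrt(rowSums(pts[, 1:2]^2))
  r_lin <- 30 + (6 - 30) * (pts[, 3] - 0) / 20
  expect_lt(max(abs(r_obs - r_lin) / r_obs), 0.01)
})

test_that("resampling a sphere loft stays within 0.5% of the true radius", {
  surf <- loft_contours(sphere_contours(25, 2.5, n_pts = 200), n_u = 36)
  pts <- resample_points(surf, param_grid(50, 50))
  err <- abs(sqrt(rowSums(pts^2)) - 25)
  expect_lt(max(err), 0.005 * 25)
  # determinism: same grid twice gives identical output
  expect_identical(pts, resample_points(surf, param_grid(50, 50)))
})

test_that("control points have local support", {
  surf <- loft_contours(sphere_contours(20, 2.5), n_u = 24)
  g <- param_grid(40, 40)
  base_pts <- resample_points(surf, g)
  pert <- surf
  i0 <- 10L; j0 <- 8L
  pert$control_points[i0, j0, ] <- pert$control_points[i0, j0, ] + c(5, 5, 5)
  pert_pts <- resample_points(pert, g)
  moved <- rowSums((pert_pts - base_pts)^2) > 1e-16
  # the affected parameter window in v: [knots_v[j0], knots_v[j0+deg+1]]
  vwin <- c(surf$knots_v[j0], surf$knots_v[j0 + surf$degree_v + 1])
  v_of <- g$uv[, "v"]
  expect_true(all(v_of[moved] >= vwin[1] - 1e-9 & v_of[moved] <= vwin[2] + 1e-9))
  expect_true(any(moved)) # and the perturbation is visible somewhere
})
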