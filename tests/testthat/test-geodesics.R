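test_that("explicit geodesic satisfies the initial conditions", {
  set.seed(51)
  for (i in 1:10) {
    n <- sample(2:3, 1)
    v <- fr_tangent(rnorm(n), sym(matrix(rnorm(n * n), n, n)))
    g0 <- geodesic_natural(v, 0)
    expect_equal(g0$delta, rep(0, n))
    expect_equal(g0$Delta, diag(n))

    # central-difference derivatives at t = 0: (x, -B)
    h <- 1e-4
    gp <- geodesic_natural(v, h)
    gm <- geodesic_natural(v, -h)
    expect_equal((gp$delta - gm$delta) / (2 * h), v$x, tolerance = 1e-6)
    expect_equal((gp$Delta - gm$Delta) / (2 * h), -v$B, tolerance = 1e-6)

    # the precision matrix stays positive definite along the curve
    for (t in c(0.5, 1, 2)) {
      expect_gt(min(eigen(geodesic_natural(v, t)$Delta, symmetric = TRUE,
                          only.values = TRUE)$values), 0)
    }
  }

  # pure covariance tangent: Delta(1) = exp(-B)
  B <- matrix(c(0.4, 0.15, 0.15, -0.3), 2, 2)
  g <- geodesic_natural(fr_tangent(c(0, 0), B), 1)
  expect_equal(g$delta, c(0, 0))
  expect_equal(g$Delta, spd_fun(-B, "exp"), tolerance = 1e-12)
})

test_that("tangent speed matches the metric and the arclength", {
  expect_equal(tangent_speed(fr_tangent(c(0, 0), matrix(0, 2, 2))), 0)
  expect_equal(tangent_speed(fr_tangent(c(1, 0), matrix(0, 2, 2))), 1)
  b <- 0.6; x0 <- 1.3
  v <- fr_tangent(c(x0, 0), matrix(c(0, b, b, 0), 2, 2))
  expect_equal(tangent_speed(v), sqrt(b^2 + x0^2), tolerance = 1e-12)

  set.seed(52)
  theta0 <- fr_gaussian(c(0, 0), diag(2))
  for (i in 1:10) {
    v <- fr_tangent(rnorm(2), sym(matrix(rnorm(4), 2, 2)))
    expect_equal(tangent_speed(v), sqrt(metric_inner(theta0, v)),
                 tolerance = 1e-12)
    # speed is constant along the curve: evaluate |gamma'(t)|_G numerically
    h <- 1e-5
    for (t in c(0.2, 0.7)) {
      gp <- from_natural(geodesic_natural(v, t + h))
      gm <- from_natural(geodesic_natural(v, t - h))
      gc <- from_natural(geodesic_natural(v, t))
      vt <- fr_tangent((gp$mu - gm$mu) / (2 * h), (gp$sigma - gm$sigma) / (2 * h))
      expect_equal(sqrt(metric_inner(gc, vt)), tangent_speed(v),
                   tolerance = 1e-5)
    }
  }
})

test_that("geodesic shooting matches the closed forms", {
  t0 <- fr_gaussian(c(0, 0), diag(2))
  expect_equal(geodesic_shooting(t0, t0)$distance, 0, tolerance = 1e-10)

  sol <- geodesic_shooting(t0, fr_gaussian(c(0, 0), diag(c(exp(2), exp(-2)))))
  expect_equal(sol$distance, 2, tolerance = 1e-5)
  expect_lt(sol$endpoint_error, 1e-9)

  pr <- example_common_sigma_pair()
  expect_equal(geodesic_shooting(pr[[1]], pr[[2]])$distance,
               dist_common_sigma(pr[[1]], pr[[2]]), tolerance = 1e-4)
})

test_that("connecting geodesic hits both endpoints", {
  set.seed(53)
  t1 <- random_gaussian(2)
  t2 <- random_gaussian(2)
  path <- fr_geodesic(t1, t2, c(0, 0.5, 1))
  expect_equal(path[[1]]$mu, t1$mu, tolerance = 1e-7)
  expect_equal(path[[1]]$sigma, t1$sigma, tolerance = 1e-7)
  expect_equal(path[[3]]$mu, t2$mu, tolerance = 1e-7)
  expect_equal(path[[3]]$sigma, t2$sigma, tolerance = 1e-7)
})

test_that("mirror structure detection", {
  pr <- mirrored_pair_ref(2)
  expect_true(is_mirrored(pr[[1]], pr[[2]]))

  # diagonal covariance: the reflection fixes it
  expect_true(is_mirrored(fr_gaussian(c(-1, 0), diag(c(2, 1))),
                          fr_gaussian(c(1, 0), diag(c(2, 1)))))

  # covariances with different spectra can never be mirrored
  expect_false(is_mirrored(fr_gaussian(c(-1, 0), diag(c(2, 1))),
                           fr_gaussian(c(1, 0), diag(c(3, 1)))))

  # detection is frame-independent: rotate a mirrored pair rigidly
  set.seed(54)
  for (i in 1:5) {
    pr <- make_mirrored_pair(3, separation = 1.5)
    iso <- fr_isometry(c(0, 0, 0), random_orthogonal(3))
    expect_true(is_mirrored(apply_isometry(iso, pr[[1]]),
                            apply_isometry(iso, pr[[2]])))
  }
})

test_that("mirrored system solves the reference family", {
  pr <- mirrored_pair_ref(1)
  sol <- mirrored_solve(pr[[1]], pr[[2]])
  expect_equal(sol$distance, 2.77395, tolerance = 1e-5)
  expect_lt(sol$residual, 1e-10)
  # distance identity against the solved tangent entries
  expect_equal(sol$distance, 2 * sqrt(sum(sol$b^2) + sol$x^2), tolerance = 1e-14)

  # diagonal mirrored pair reduces to the eigen-axis closed form
  d1 <- fr_gaussian(c(-1, 0), diag(2))
  d2 <- fr_gaussian(c(1, 0), diag(2))
  expect_equal(mirrored_solve(d1, d2)$distance, dist_diag_eigenmean(d1, d2),
               tolerance = 1e-8)
  expect_equal(mirrored_solve(d1, d2)$distance, sqrt(2) * acosh(2),
               tolerance = 1e-8)

  expect_error(mirrored_solve(d1, fr_gaussian(c(1, 0), diag(c(3, 1)))),
               "not mirrored")

  # trivariate mirrored pair: system solution agrees with shooting
  pr3 <- make_mirrored_pair(3, seed = 55, separation = 1.2)
  s3 <- mirrored_solve(pr3[[1]], pr3[[2]])
  gs3 <- geodesic_shooting(pr3[[1]], pr3[[2]])
  expect_equal(s3$distance, gs3$distance, tolerance = 1e-4)
})

test_that("mirrored geodesic endpoints, midpoint structure and mean hyperbola", {
  pr <- mirrored_pair_ref(2)
  sol <- mirrored_solve(pr[[1]], pr[[2]])

  g1 <- mirrored_geodesic(sol, -1)
  g2 <- mirrored_geodesic(sol, 1)
  expect_equal(g1$mu, pr[[1]]$mu, tolerance = 1e-6)
  expect_equal(g1$sigma, pr[[1]]$sigma, tolerance = 1e-6)
  expect_equal(g2$mu, pr[[2]]$mu, tolerance = 1e-6)
  expect_equal(g2$sigma, pr[[2]]$sigma, tolerance = 1e-6)

  g0 <- mirrored_geodesic(sol, 0)
  expect_lt(abs(g0$sigma[1, 2]), 1e-8)
  expect_equal(g0$mu[1], 0, tolerance = 1e-8)

  # the natural-coordinate mean path lies on a hyperbola
  x <- sol$x; b <- sol$b[1]
  c2 <- b^2 + 2 * x^2
  k <- b * x / c2
  for (t in c(-0.8, -0.3, 0.25, 0.6, 1)) {
    d <- geodesic_natural(mirrored_tangent(sol$x, sol$b), t)$delta
    lhs <- ((d[2] - k) / k)^2 - (d[1] / (x / sqrt(c2)))^2
    expect_equal(lhs, 1, tolerance = 1e-8)
  }

  # mirrored symmetry of the curve about t = 0
  M1 <- diag(c(-1, 1))
  for (t in c(0.25, 0.5, 1)) {
    gp <- geodesic_natural(mirrored_tangent(sol$x, sol$b), t)
    gm <- geodesic_natural(mirrored_tangent(sol$x, sol$b), -t)
    expect_equal(gm$Delta, M1 %*% gp$Delta %*% M1, tolerance = 1e-10)
    expect_equal(gm$delta, drop(M1 %*% gp$delta), tolerance = 1e-10)
  }
})

test_that("dispatcher routes to exact methods and satisfies the triangle inequality", {
  pr <- example_common_sigma_pair()
  r <- fisher_rao(pr[[1]], pr[[2]])
  expect_equal(r$method, "common-sigma")
  expect_equal(r$distance, 5.00648, tolerance = 1e-5)

  r <- fisher_rao(pr[[1]], pr[[1]])
  expect_equal(r$method, "identical")
  expect_equal(r$distance, 0)

  pr2 <- mirrored_pair_ref(2)
  r <- fisher_rao(pr2[[1]], pr2[[2]])
  expect_equal(r$method, "mirrored")
  expect_equal(r$distance, 3.67027, tolerance = 1e-5)

  r <- fisher_rao(fr_gaussian(c(1, 1), diag(2)),
                  fr_gaussian(c(1, 1), 2 * diag(2)))
  expect_equal(r$method, "common-mean")

  r <- fisher_rao(fr_gaussian(c(1, 0), diag(c(1, 2))),
                  fr_gaussian(c(2, 0), diag(c(2, 1))))
  expect_equal(r$method, "eigenmean")

  set.seed(56)
  r <- fisher_rao(random_gaussian(2), random_gaussian(2))
  expect_equal(r$method, "shooting")

  # dispatched distance always sits inside the bound sandwich
  set.seed(57)
  for (i in 1:10) {
    t1 <- random_gaussian(2)
    t2 <- random_gaussian(2)
    d <- fisher_rao(t1, t2)$distance
    b <- fr_bounds(t1, t2)
    expect_lte(b$lb, d + 1e-6)
    expect_lte(d, b$ub123 + 1e-6)
  }

  # triangle inequality over random triples
  set.seed(58)
  for (i in 1:25) {
    ts <- lapply(1:3, function(j) random_gaussian(2))
    d12 <- fisher_rao(ts[[1]], ts[[2]])$distance
    d13 <- fisher_rao(ts[[1]], ts[[3]])$distance
    d32 <- fisher_rao(ts[[3]], ts[[2]])$distance
    expect_lte(d12, d13 + d32 + 1e-8)
  }
})
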