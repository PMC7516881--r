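test_that("mixture construction and log density", {
  expect_error(fr_dgmm(c(0.5, 0.6), matrix(0, 2, 1), matrix(1, 2, 1)), "sum to 1")
  expect_error(fr_dgmm(1, matrix(0, 1, 1), matrix(-1, 1, 1)), "positive")

  f <- fr_dgmm(1, 0, 1)
  expect_equal(dgmm_logpdf(f, 0), log(1 / sqrt(2 * pi)), tolerance = 1e-12)

  # a zero-weight component contributes nothing
  f2 <- fr_dgmm(c(1, 0), matrix(c(0, 5), 2, 1), matrix(c(1, 1), 2, 1))
  x <- seq(-3, 7, by = 0.5)
  expect_equal(dgmm_logpdf(f2, matrix(x, ncol = 1)),
               dgmm_logpdf(f, matrix(x, ncol = 1)), tolerance = 1e-12)

  # symmetric equal-weight mixture is symmetric about the midpoint
  fs <- fr_dgmm(c(0.5, 0.5), matrix(c(-2, 2), 2, 1), matrix(1, 2, 1))
  expect_equal(dgmm_logpdf(fs, matrix(x, ncol = 1)),
               dgmm_logpdf(fs, matrix(-x, ncol = 1)), tolerance = 1e-12)
})

test_that("sampling is reproducible and follows the weights", {
  f <- fr_dgmm(c(0.3, 0.7), matrix(c(-5, 5), 2, 1), matrix(c(1, 4), 2, 1))
  s1 <- dgmm_sample(f, 500, seed = 7)
  s2 <- dgmm_sample(f, 500, seed = 7)
  expect_identical(s1, s2)

  # component frequencies within a 4-sigma binomial band
  n <- 4000
  s <- dgmm_sample(f, n, seed = 8)
  phat <- mean(s$component == 2)
  expect_lt(abs(phat - 0.7), 4 * sqrt(0.7 * 0.3 / n))

  f1 <- fr_dgmm(c(1, 0), matrix(c(0, 5), 2, 1), matrix(1, 2, 1))
  s <- dgmm_sample(f1, 200, seed = 9)
  expect_true(all(s$component == 1))
  expect_lt(abs(mean(s$x)), 4 / sqrt(200))
})

test_that("Monte-Carlo KL estimates the Gaussian closed form", {
  f <- fr_dgmm(c(0.4, 0.6), matrix(c(0, 3), 2, 1), matrix(c(1, 2), 2, 1))
  expect_identical(kl_monte_carlo(f, f, 1000, seed = 10)$kl, 0)

  # single components: KL(N(0,1) || N(delta,1)) = delta^2 / 2
  for (delta in c(0.5, 1)) {
    a <- fr_dgmm(1, 0, 1)
    b <- fr_dgmm(1, delta, 1)
    est <- kl_monte_carlo(a, b, 5000, seed = 11)
    expect_lt(abs(est$kl - delta^2 / 2), 3 * est$se)
  }

  set.seed(12)
  for (i in 1:5) {
    a <- fr_dgmm(1, matrix(rnorm(2), 1, 2), matrix(exp(rnorm(2)), 1, 2))
    b <- fr_dgmm(1, matrix(rnorm(2), 1, 2), matrix(exp(rnorm(2)), 1, 2))
    est <- kl_monte_carlo(a, b, 2000, seed = i)
    expect_gt(est$kl, -3 * est$se)
  }
})

test_that("cluster centroids: hyperbolic and moment matching", {
  one <- centroid_fisher_rao(1, matrix(c(0.3, -1), 1, 2), matrix(c(1, 4), 1, 2))
  expect_equal(one$mu, c(0.3, -1))
  expect_equal(one$var, c(1, 4))

  two <- centroid_fisher_rao(c(1, 1), matrix(c(-1, 1), 2, 1), matrix(1, 2, 1))
  expect_equal(two$mu, 0, tolerance = 1e-12)
  expect_equal(two$var, 1.5, tolerance = 1e-12)

  br <- centroid_bregman(c(1, 1), matrix(c(-1, 1), 2, 1), matrix(1, 2, 1))
  expect_equal(br$mu, 0)
  expect_equal(br$var, 2)

  # equal means: Bregman variance is the weighted mean of variances
  br <- centroid_bregman(c(0.25, 0.75), matrix(c(2, 2), 2, 1),
                         matrix(c(1, 3), 2, 1))
  expect_equal(br$mu, 2)
  expect_equal(br$var, 0.25 * 1 + 0.75 * 3)

  # permutation invariance
  set.seed(13)
  mu <- matrix(rnorm(6), 3, 2); va <- matrix(exp(rnorm(6)), 3, 2)
  w <- runif(3)
  p <- c(3, 1, 2)
  a <- centroid_fisher_rao(w, mu, va)
  b <- centroid_fisher_rao(w[p], mu[p, ], va[p, ])
  expect_equal(a, b, tolerance = 1e-12)
  expect_error(centroid_fisher_rao(numeric(0), mu[0, , drop = FALSE],
                                   va[0, , drop = FALSE]), "empty")

  # the moment-matched centroid minimizes the weighted left KL locally
  kl_gauss <- function(m1, v1, m2, v2) {
    0.5 * (v1 / v2 + (m2 - m1)^2 / v2 - 1 + log(v2 / v1))
  }
  wt <- w / sum(w)
  obj <- function(m, v) sum(wt * kl_gauss(mu[, 1], va[, 1], m, v))
  cb <- centroid_bregman(w, mu, va)
  f0 <- obj(cb$mu[1], cb$var[1])
  for (eps in c(0.01, -0.01)) {
    expect_gte(obj(cb$mu[1] + eps, cb$var[1]), f0)
    expect_gte(obj(cb$mu[1], cb$var[1] * (1 + eps)), f0)
  }
})

test_that("linkage distances are ordered and symmetric", {
  f <- make_planted_dgmm(n = 2, groups = 2, per_group = 2, seed = 14)
  d_single <- linkage_distance(f, 1:2, 3:4, "single")
  d_avg <- linkage_distance(f, 1:2, 3:4, "average")
  d_comp <- linkage_distance(f, 1:2, 3:4, "complete")
  expect_lte(d_single, d_avg)
  expect_lte(d_avg, d_comp)
  expect_equal(linkage_distance(f, 1, 1, "complete"), 0)
  expect_equal(d_comp, linkage_distance(f, 3:4, 1:2, "complete"))
  # singleton clusters: all linkages coincide with the component distance
  expect_equal(linkage_distance(f, 1, 3, "single"),
               linkage_distance(f, 1, 3, "complete"))
})

test_that("agglomeration recovers planted structure", {
  f1 <- fr_dgmm(1, 0, 1)
  tr <- agglomerate(f1)
  expect_equal(nrow(tr$merges), 0)
  expect_equal(cut_merge_tree(tr, 1), list(1L))

  # duplicated components merge first at height zero
  f <- fr_dgmm(rep(1 / 3, 3), matrix(c(0, 10, 0), 3, 1), matrix(1, 3, 1))
  tr <- agglomerate(f)
  expect_equal(tr$merges$height[1], 0)
  expect_equal(sort(unlist(cut_merge_tree(tr, 2)[
    which.max(lengths(cut_merge_tree(tr, 2)))])), c(1L, 3L))

  # well-separated pairs recovered at level 2
  f <- make_planted_dgmm(n = 2, groups = 2, per_group = 2, seed = 15)
  parts <- cut_merge_tree(agglomerate(f), 2)
  expect_setequal(lapply(parts, sort), list(1:2, 3:4))
})

test_that("simplification conserves weight and improves with level", {
  f <- make_planted_dgmm(n = 1, groups = 2, per_group = 3, seed = 16)
  for (l in 1:6) {
    g <- simplify_dgmm(f, l)
    expect_equal(sum(g$weights), 1, tolerance = 1e-12)
    expect_equal(nrow(g$mu), l)
  }
  g <- simplify_dgmm(f, 6)
  expect_setequal(round(g$mu[, 1], 10), round(f$mu[, 1], 10))
  expect_error(simplify_dgmm(f, 0), "out of range")

  pair <- fr_dgmm(c(0.5, 0.5), matrix(c(-1, 1), 2, 1), matrix(1, 2, 1))
  g1 <- simplify_dgmm(pair, 1, centroid = "fisher-rao")
  expect_equal(g1$weights, 1)
  expect_equal(g1$mu[1, 1], 0, tolerance = 1e-12)
  expect_equal(g1$var[1, 1], 1.5, tolerance = 1e-12)

  # two-group fixture: the 2-component simplification is much closer than 1
  kl2 <- kl_monte_carlo(f, simplify_dgmm(f, 2), 4000, seed = 17)$kl
  kl1 <- kl_monte_carlo(f, simplify_dgmm(f, 1), 4000, seed = 17)$kl
  expect_lt(kl2, kl1)
})

test_that("component-count selection scans to the threshold", {
  f <- make_planted_dgmm(n = 1, groups = 3, per_group = 4, seed = 18)
  expect_equal(learn_components(f, 1e6, seed = 18)$l, 1)
  res <- learn_components(f, 0.2, seed = 18)
  expect_lte(res$l, 3)
  expect_lte(kl_monte_carlo(f, res$g, 5000, seed = 18)$kl, 0.2)

  # duplicate components merge at zero KL cost
  fd <- fr_dgmm(rep(0.25, 4), matrix(c(0, 0, 8, 16), 4, 1), matrix(1, 4, 1))
  expect_lte(learn_components(fd, 1e-9, seed = 19)$l, 3)
})

test_that("maximum-density classification", {
  f <- fr_dgmm(c(0.9, 0.1), matrix(c(0, 10), 2, 1), matrix(1, 2, 1))
  expect_equal(classify_points(f, matrix(c(0, 10), 2, 1)), c(1L, 2L))
  # equidistant tie goes to the lowest index
  expect_equal(classify_points(f, matrix(5, 1, 1)), 1L)
  # the rule ignores the weights entirely
  g <- fr_dgmm(c(0.1, 0.9), f$mu, f$var)
  x <- matrix(seq(-2, 12, by = 0.5), ncol = 1)
  expect_equal(classify_points(f, x), classify_points(g, x))
})

test_that("EM fits diagonal mixtures with monotone likelihood", {
  set.seed(20)
  x <- matrix(rnorm(400, mean = 3, sd = 2), ncol = 1)
  f <- fit_dgmm(x, 1)
  expect_equal(f$mu[1, 1], mean(x), tolerance = 1e-6)
  expect_equal(f$var[1, 1], stats::var(as.numeric(x)) * (399 / 400),
               tolerance = 1e-3)

  # separated planted clusters: means recovered, log-likelihood ascends
  x <- rbind(matrix(rnorm(300), ncol = 2),
             matrix(rnorm(300, mean = 10), ncol = 2))
  f <- fit_dgmm(x, 2, seed = 21)
  ll <- attr(f, "loglik")
  expect_true(all(diff(ll) >= -1e-6))
  mus <- f$mu[order(f$mu[, 1]), ]
  expect_lt(max(abs(mus - rbind(c(0, 0), c(10, 10)))), 0.3)

  expect_error(fit_dgmm(matrix(0, 1, 2), 2), "at least as many points")
})
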