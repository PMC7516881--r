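# Diagonal Gaussian mixture models and their simplification by Fisher-Rao
# agglomerative clustering: product-metric distances between components,
# hyperbolic (Galperin) and moment-matching (Bregman left-sided) centroids,
# linkage criteria, the merge tree, Monte-Carlo KL model selection and
# maximum-density pixel classification.

#' Diagonal Gaussian mixture model
#'
#' A weighted mixture of normals with diagonal covariances. Parameters are
#' stored as matrices with one row per component.
#'
#' @param weights Nonnegative weights summing to 1.
#' @param mu m x n matrix of component means (a vector for n = 1).
#' @param var m x n matrix of component variances (diagonal of each
#'   covariance).
#' @return An object of class `fr_dgmm`.
#' @export
fr_dgmm <- function(weights, mu, var) {
  if (!is.matrix(mu)) mu <- matrix(mu, ncol = 1)
  if (!is.matrix(var)) var <- matrix(var, ncol = 1)
  m <- nrow(mu)
  if (m < 1) stop("mixture needs at least one component")
  if (!all(dim(mu) == dim(var))) stop("mu and var dimensions disagree")
  if (length(weights) != m) stop("one weight per component required")
  if (any(weights < 0)) stop("weights must be nonnegative")
  if (abs(sum(weights) - 1) > 1e-9) stop("weights must sum to 1")
  if (any(var <= 0)) stop("variances must be positive")
  structure(list(weights = as.numeric(weights), mu = mu, var = var),
            class = "fr_dgmm")
}

#' @export
print.fr_dgmm <- function(x, ...) {
  cat(sprintf("Diagonal Gaussian mixture: %d components in %d dimension(s)\n",
              nrow(x$mu), ncol(x$mu)))
  df <- data.frame(weight = x$weights)
  for (j in seq_len(ncol(x$mu))) {
    df[[paste0("mu", j)]] <- x$mu[, j]
    df[[paste0("var", j)]] <- x$var[, j]
  }
  print(utils::head(df, 10), digits = 4)
  if (nrow(df) > 10) cat(sprintf("... and %d more components\n", nrow(df) - 10))
  invisible(x)
}

n_components <- function(f) nrow(f$mu)

# Per-component log density matrix: rows = points, cols = components.
component_logpdf <- function(f, X) {
  if (!is.matrix(X)) X <- matrix(X, ncol = ncol(f$mu))
  m <- n_components(f)
  out <- matrix(0, nrow(X), m)
  for (k in seq_len(m)) {
    lp <- -0.5 * sweep(sweep(X, 2, f$mu[k, ])^2, 2, f$var[k, ], "/")
    out[, k] <- rowSums(lp) - 0.5 * sum(log(2 * pi * f$var[k, ]))
  }
  out
}

#' Mixture log density
#'
#' Log-sum-exp evaluation of \eqn{\log \sum_i w_i p_i(x)}.
#'
#' @param f An `fr_dgmm`.
#' @param x A point (vector) or a matrix of points (one row each).
#' @return Numeric vector of log densities.
#' @export
dgmm_logpdf <- function(f, x) {
  lp <- component_logpdf(f, x)
  lw <- ifelse(f$weights > 0, log(f$weights), -Inf)
  lp <- sweep(lp, 2, lw, "+")
  M <- apply(lp, 1, max)
  M + log(rowSums(exp(lp - M)))
}

#' Sample from a diagonal Gaussian mixture
#'
#' @param f An `fr_dgmm`.
#' @param n Number of draws.
#' @param seed Optional integer seed for reproducibility.
#' @return A list with `x` (n x d matrix) and `component` (integer labels).
#' @export
dgmm_sample <- function(f, n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- n_components(f)
  d <- ncol(f$mu)
  k <- sample.int(m, n, replace = TRUE, prob = f$weights)
  z <- matrix(stats::rnorm(n * d), n, d)
  x <- f$mu[k, , drop = FALSE] + z * sqrt(f$var[k, , drop = FALSE])
  list(x = x, component = k)
}

#' Monte-Carlo Kullback-Leibler divergence between mixtures
#'
#' Estimates \eqn{d_{KL}(f \| g)} as the sample mean of
#' \eqn{\log f(x) - \log g(x)} over draws \eqn{x \sim f}; no closed form
#' exists for mixtures. Identical mixtures give exactly zero by term-wise
#' cancellation.
#'
#' @param f,g `fr_dgmm` mixtures of the same dimension.
#' @param n Number of Monte-Carlo draws (default 5000).
#' @param seed Optional integer seed.
#' @return A list with `kl` (estimate), `se` (standard error), `n`.
#' @export
kl_monte_carlo <- function(f, g, n = 5000, seed = NULL) {
  if (ncol(f$mu) != ncol(g$mu)) stop("dimension mismatch")
  s <- dgmm_sample(f, n, seed)
  d <- dgmm_logpdf(f, s$x) - dgmm_logpdf(g, s$x)
  list(kl = mean(d), se = stats::sd(d) / sqrt(n), n = n)
}

#' Cluster centroids for diagonal Gaussian components
#'
#' `centroid_fisher_rao` applies the weighted hyperbolic (Galperin) centroid
#' coordinate-wise in the (mean, standard deviation) half-planes;
#' `centroid_bregman` is the left-sided KL (moment-matching) centroid:
#' weighted mean and matched second moment per coordinate.
#'
#' @param w Nonnegative member weights (positive total).
#' @param mu,var Matrices of member means and variances (one row each).
#' @return A list with vectors `mu` and `var` of the merged component.
#' @export
centroid_fisher_rao <- function(w, mu, var) {
  if (!is.matrix(mu)) mu <- matrix(mu, ncol = 1)
  if (!is.matrix(var)) var <- matrix(var, ncol = 1)
  if (nrow(mu) == 0) stop("empty cluster")
  if (sum(w) <= 0) stop("cluster weights must have positive total")
  d <- ncol(mu)
  out_mu <- numeric(d)
  out_var <- numeric(d)
  for (j in seq_len(d)) {
    c_j <- galperin_centroid(mu[, j], sqrt(var[, j]), w)
    out_mu[j] <- c_j[1]
    out_var[j] <- c_j[2]^2
  }
  list(mu = out_mu, var = out_var)
}

#' @rdname centroid_fisher_rao
#' @export
centroid_bregman <- function(w, mu, var) {
  if (!is.matrix(mu)) mu <- matrix(mu, ncol = 1)
  if (!is.matrix(var)) var <- matrix(var, ncol = 1)
  if (nrow(mu) == 0) stop("empty cluster")
  if (sum(w) <= 0) stop("cluster weights must have positive total")
  wt <- w / sum(w)
  m <- drop(wt %*% mu)
  v <- drop(wt %*% (var + mu^2)) - m^2
  list(mu = as.numeric(m), var = pmax(as.numeric(v), .Machine$double.eps))
}

# Product-metric distance between two components of a mixture.
component_dist <- function(f, i, j) {
  sqrt(sum(uv_fisher_rao(f$mu[i, ], sqrt(f$var[i, ]),
                         f$mu[j, ], sqrt(f$var[j, ]))^2))
}

#' Linkage distance between two clusters of mixture components
#'
#' Single, complete, or group-average linkage built on the diagonal-manifold
#' product Fisher-Rao distance between member components.
#'
#' @param f An `fr_dgmm`.
#' @param A,B Integer vectors of component indices.
#' @param kind `"single"`, `"complete"` or `"average"`.
#' @return The linkage distance.
#' @export
linkage_distance <- function(f, A, B, kind = c("complete", "single", "average")) {
  kind <- match.arg(kind)
  if (length(A) == 0 || length(B) == 0) stop("clusters must be nonempty")
  d <- outer(A, B, Vectorize(function(i, j) component_dist(f, i, j)))
  switch(kind, single = min(d), complete = max(d), average = mean(d))
}

#' Agglomerative clustering of mixture components
#'
#' Greedy hierarchical clustering under the chosen linkage: starting from
#' singletons, repeatedly merge the globally closest pair of clusters (ties
#' broken toward the lowest index pair) until one cluster remains. The
#' returned merge tree supports extraction of the partition at any level.
#'
#' @param f An `fr_dgmm`.
#' @param kind Linkage criterion (default complete).
#' @return An object of class `fr_merge_tree` with a data frame of merges.
#' @export
agglomerate <- function(f, kind = c("complete", "single", "average")) {
  kind <- match.arg(kind)
  m <- n_components(f)
  clusters <- as.list(seq_len(m))
  active <- seq_len(m)
  merges <- data.frame(a = integer(0), b = integer(0), height = numeric(0))
  while (length(active) > 1) {
    best <- NULL
    for (ii in seq_along(active)) {
      for (jj in seq_along(active)) {
        if (jj <= ii) next
        d <- linkage_distance(f, clusters[[active[ii]]], clusters[[active[jj]]],
                              kind)
        if (is.null(best) || d < best$d) {
          best <- list(i = active[ii], j = active[jj], d = d)
        }
      }
    }
    new_id <- length(clusters) + 1
    clusters[[new_id]] <- c(clusters[[best$i]], clusters[[best$j]])
    merges <- rbind(merges,
                    data.frame(a = best$i, b = best$j, height = best$d))
    active <- c(setdiff(active, c(best$i, best$j)), new_id)
  }
  structure(list(merges = merges, m = m, clusters = clusters),
            class = "fr_merge_tree")
}

#' @export
print.fr_merge_tree <- function(x, ...) {
  cat(sprintf("Merge tree over %d components (%d merges, linkage heights %.4g .. %.4g)\n",
              x$m, nrow(x$merges),
              if (nrow(x$merges)) min(x$merges$height) else NA,
              if (nrow(x$merges)) max(x$merges$height) else NA))
  invisible(x)
}

#' Extract the partition at a given number of clusters
#'
#' @param tree An `fr_merge_tree`.
#' @param l Number of clusters, between 1 and the leaf count.
#' @return A list of integer index vectors, one per cluster.
#' @export
cut_merge_tree <- function(tree, l) {
  m <- tree$m
  if (l < 1 || l > m) stop("l out of range")
  active <- seq_len(m)
  k <- 0
  while (length(active) > l) {
    k <- k + 1
    mg <- tree$merges[k, ]
    active <- c(setdiff(active, c(mg$a, mg$b)), m + k)
  }
  lapply(active, function(id) sort(tree$clusters[[id]]))
}

#' Simplify a diagonal Gaussian mixture to l components
#'
#' Cuts the agglomerative merge tree at l clusters and replaces each cluster
#' by its centroid (hyperbolic Fisher-Rao or Bregman left-sided), with weight
#' equal to the summed member weights.
#'
#' @param f An `fr_dgmm`.
#' @param l Target number of components.
#' @param kind Linkage criterion.
#' @param centroid `"fisher-rao"` or `"bregman"`.
#' @param tree Optionally a precomputed [agglomerate] tree for `f`.
#' @return The simplified `fr_dgmm` with l components.
#' @export
simplify_dgmm <- function(f, l, kind = c("complete", "single", "average"),
                          centroid = c("fisher-rao", "bregman"), tree = NULL) {
  kind <- match.arg(kind)
  centroid <- match.arg(centroid)
  m <- n_components(f)
  if (l < 1 || l > m) stop("l out of range")
  if (is.null(tree)) tree <- agglomerate(f, kind)
  parts <- cut_merge_tree(tree, l)
  cfun <- if (centroid == "fisher-rao") centroid_fisher_rao else centroid_bregman
  d <- ncol(f$mu)
  mu <- matrix(0, l, d)
  var <- matrix(0, l, d)
  wts <- numeric(l)
  for (k in seq_along(parts)) {
    idx <- parts[[k]]
    cen <- cfun(f$weights[idx], f$mu[idx, , drop = FALSE],
                f$var[idx, , drop = FALSE])
    mu[k, ] <- cen$mu
    var[k, ] <- cen$var
    wts[k] <- sum(f$weights[idx])
  }
  fr_dgmm(wts / sum(wts), mu, var)
}

#' Smallest mixture meeting a KL quality threshold
#'
#' Scans l = 1, ..., m and returns the first simplification whose estimated
#' \eqn{d_{KL}(f \| g)} falls below `tau`; the KL is not guaranteed monotone
#' in l, so the scan is explicit.
#'
#' @param f An `fr_dgmm`.
#' @param tau Positive KL threshold.
#' @param kind Linkage criterion.
#' @param centroid Centroid type.
#' @param n_mc Monte-Carlo sample size.
#' @param seed Optional integer seed.
#' @return A list with `l` and the simplified mixture `g`.
#' @export
learn_components <- function(f, tau, kind = c("complete", "single", "average"),
                             centroid = c("fisher-rao", "bregman"),
                             n_mc = 5000, seed = NULL) {
  kind <- match.arg(kind)
  centroid <- match.arg(centroid)
  if (tau <= 0) stop("tau must be positive")
  m <- n_components(f)
  tree <- agglomerate(f, kind)
  for (l in seq_len(m)) {
    g <- simplify_dgmm(f, l, kind, centroid, tree = tree)
    if (kl_monte_carlo(f, g, n_mc, seed)$kl <= tau) {
      return(list(l = l, g = g))
    }
  }
  list(l = m, g = f)
}

#' Maximum-density classification of points
#'
#' Assigns each point to the component with the highest (unweighted) density,
#' ties broken toward the lowest component index — the rule used for
#' clustering-based image segmentation, where each pixel is a point in RGB
#' space.
#'
#' @param f An `fr_dgmm`.
#' @param x Matrix of points (one row each) or a single point vector.
#' @return Integer vector of component labels.
#' @export
classify_points <- function(f, x) {
  lp <- component_logpdf(f, x)
  apply(lp, 1, which.max)
}

#' Fit a diagonal Gaussian mixture by EM
#'
#' Standard diagonal-covariance expectation-maximization with k-means
#' initialization; variances are floored at 1e-6 and the log-likelihood is
#' non-decreasing across iterations.
#'
#' @param x Matrix of points (one row each).
#' @param m Number of components.
#' @param seed Optional integer seed (initialization).
#' @param maxit Maximum EM iterations.
#' @param reltol Relative log-likelihood convergence tolerance.
#' @return An `fr_dgmm`, with attribute `"loglik"` holding the trace.
#' @export
fit_dgmm <- function(x, m, seed = NULL, maxit = 200, reltol = 1e-8) {
  if (!is.matrix(x)) x <- matrix(x, ncol = 1)
  if (nrow(x) < m) stop("need at least as many points as components")
  if (!is.null(seed)) set.seed(seed)
  d <- ncol(x)
  if (m == 1) {
    km_centers <- matrix(colMeans(x), 1, d)
    assign0 <- rep(1L, nrow(x))
  } else {
    km <- stats::kmeans(x, centers = m, nstart = 5, iter.max = 50)
    km_centers <- km$centers
    assign0 <- km$cluster
  }
  mu <- km_centers
  var <- matrix(0, m, d)
  w <- numeric(m)
  for (k in seq_len(m)) {
    idx <- which(assign0 == k)
    w[k] <- length(idx) / nrow(x)
    v <- if (length(idx) > 1) apply(x[idx, , drop = FALSE], 2, stats::var) else rep(1, d)
    var[k, ] <- pmax(v, 1e-6)
  }
  w <- pmax(w, 1e-8); w <- w / sum(w)
  f <- fr_dgmm(w, mu, var)
  ll <- -Inf
  trace <- numeric(0)
  for (it in seq_len(maxit)) {
    lp <- sweep(component_logpdf(f, x), 2, log(pmax(f$weights, 1e-300)), "+")
    M <- apply(lp, 1, max)
    lse <- M + log(rowSums(exp(lp - M)))
    ll_new <- sum(lse)
    trace <- c(trace, ll_new)
    r <- exp(lp - lse)                       # responsibilities
    nk <- colSums(r)
    w <- nk / nrow(x)
    mu <- (t(r) %*% x) / nk
    for (k in seq_len(m)) {
      dev2 <- sweep(x, 2, mu[k, ])^2
      var[k, ] <- pmax(colSums(r[, k] * dev2) / nk[k], 1e-6)
    }
    f <- fr_dgmm(w / sum(w), mu, var)
    if (is.finite(ll) && abs(ll_new - ll) <= reltol * (abs(ll) + 1)) break
    ll <- ll_new
  }
  attr(f, "loglik") <- trace
  f
}
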