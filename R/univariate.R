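# Univariate normal geometry: the (mu, sigma) half-plane is hyperbolic.
# With u = mu / sqrt(2) the Fisher metric is sqrt(2) times the standard
# Poincare half-plane metric in (u, sigma), which gives both the closed-form
# distance and the Minkowski hyperboloid chart used for centroids.

#' Fisher-Rao distance between univariate normal distributions
#'
#' Closed form: \eqn{\sqrt{2}\,\mathrm{acosh}(1 + ((u_1-u_2)^2 +
#' (\sigma_1-\sigma_2)^2) / (2\sigma_1\sigma_2))} with \eqn{u_i =
#' \mu_i/\sqrt{2}}. The equivalent quotient-log form (ratio of chordal
#' distances to the mirrored point) is available as a cross-check.
#'
#' @param mu1,sigma1,mu2,sigma2 Means and standard deviations (vectorized).
#' @param form `"acosh"` (default) or `"log"` for the quotient form.
#' @return Numeric vector of distances.
#' @examples
#' uv_fisher_rao(0, 1, 0, exp(1))   # sqrt(2)
#' @export
uv_fisher_rao <- function(mu1, sigma1, mu2, sigma2, form = c("acosh", "log")) {
  form <- match.arg(form)
  if (any(sigma1 <= 0) || any(sigma2 <= 0)) stop("standard deviations must be positive")
  u1 <- mu1 / sqrt(2)
  u2 <- mu2 / sqrt(2)
  if (form == "acosh") {
    arg <- 1 + ((u1 - u2)^2 + (sigma1 - sigma2)^2) / (2 * sigma1 * sigma2)
    sqrt(2) * acosh(pmax(arg, 1))
  } else {
    # log of the cross-ratio with the conjugate (sigma-negated) point
    a <- sqrt((u1 - u2)^2 + (sigma1 + sigma2)^2)
    b <- sqrt((u1 - u2)^2 + (sigma1 - sigma2)^2)
    sqrt(2) * log((a + b) / (a - b))
  }
}

#' Map a univariate normal to the Minkowski hyperboloid
#'
#' Uses the scaled half-plane coordinates \eqn{(u, v) = (\mu/\sqrt{2},
#' \sigma)} and the classical chart onto the upper sheet of
#' \eqn{z^2 - x^2 - y^2 = 1}. The Minkowski inner product then reproduces
#' the Fisher-Rao distance: \eqn{d_{F^*} = \sqrt{2}\,\mathrm{acosh}(z_1 z_2 -
#' x_1 x_2 - y_1 y_2)}.
#'
#' @param mu,sigma Mean and standard deviation.
#' @return Numeric vector `c(x, y, z)` on the upper hyperboloid.
#' @export
to_hyperboloid <- function(mu, sigma) {
  if (sigma <= 0) stop("sigma must be positive")
  u <- mu / sqrt(2)
  v <- sigma
  c(x = (u^2 + v^2 - 1) / (2 * v), y = u / v, z = (u^2 + v^2 + 1) / (2 * v))
}

#' @rdname to_hyperboloid
#' @param h Numeric vector `c(x, y, z)` with `z > x` on the upper hyperboloid.
#' @return For `from_hyperboloid`, a vector `c(mu, sigma)`.
#' @export
from_hyperboloid <- function(h) {
  h <- as.numeric(h)
  if (length(h) != 3) stop("hyperboloid point must have 3 coordinates")
  if (h[3] <= h[1]) stop("point is not on the upper hyperboloid (z <= x)")
  v <- 1 / (h[3] - h[1])
  u <- h[2] * v
  c(mu = u * sqrt(2), sigma = v)
}

# Minkowski bilinear form <p, q> = z1 z2 - x1 x2 - y1 y2.
minkowski_dot <- function(p, q) p[3] * q[3] - p[1] * q[1] - p[2] * q[2]

#' Constant-speed geodesic between univariate normals
#'
#' The geodesics of the hyperbolic (mu, sigma) half-plane are half-vertical
#' lines and half-ellipses centered on sigma = 0; they are evaluated here
#' through the hyperboloid model with a constant-fraction-of-arclength
#' parametrization on [0, 1].
#'
#' @param mu1,sigma1,mu2,sigma2 Endpoint parameters.
#' @param t Curve parameter(s) in `[0, 1]` (values outside extend the geodesic).
#' @return A matrix with columns `mu`, `sigma` (one row per `t`).
#' @export
uv_geodesic <- function(mu1, sigma1, mu2, sigma2, t) {
  p <- to_hyperboloid(mu1, sigma1)
  q <- to_hyperboloid(mu2, sigma2)
  d <- acosh(max(minkowski_dot(p, q), 1))
  out <- matrix(0, length(t), 2, dimnames = list(NULL, c("mu", "sigma")))
  for (i in seq_along(t)) {
    if (d < 1e-12) {
      g <- p
    } else {
      w <- (q - cosh(d) * p) / sinh(d)
      g <- cosh(t[i] * d) * p + sinh(t[i] * d) * w
    }
    out[i, ] <- from_hyperboloid(g)
  }
  if (length(t) == 1) drop(out) else out
}

#' Weighted hyperbolic (Galperin) centroid of univariate normals
#'
#' Maps each point to the Minkowski hyperboloid, forms the weighted sum
#' \eqn{c' = \sum_i u_i q_i}, projects back onto the hyperboloid by dividing
#' by the Minkowski norm \eqn{\sqrt{z'^2 - x'^2 - y'^2}}, and returns the
#' corresponding (mu, sigma).
#'
#' @param mu,sigma Numeric vectors of component parameters.
#' @param w Nonnegative weights (at least one positive); need not sum to 1.
#' @return Vector `c(mu, sigma)` of the centroid.
#' @examples
#' galperin_centroid(c(-1, 1), c(1, 1), c(1, 1))  # (0, sqrt(1.5))
#' @export
galperin_centroid <- function(mu, sigma, w = rep(1, length(mu))) {
  if (length(mu) != length(sigma) || length(mu) != length(w)) {
    stop("mu, sigma and w must have equal length")
  }
  if (any(w < 0)) stop("weights must be nonnegative")
  if (sum(w) <= 0) stop("at least one weight must be positive")
  cp <- c(0, 0, 0)
  for (i in seq_along(mu)) cp <- cp + w[i] * to_hyperboloid(mu[i], sigma[i])
  nrm2 <- minkowski_dot(cp, cp)
  if (nrm2 <= 0) stop("weighted sum is not timelike; cannot normalize")
  from_hyperboloid(cp / sqrt(nrm2))
}
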