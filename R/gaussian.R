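#' Multivariate normal parameter point
#'
#' Constructs a validated parameter point \eqn{\theta = (\mu, \Sigma)} of the
#' manifold of n-variate normal distributions. The covariance is symmetrized
#' on construction and must be positive definite.
#'
#' @param mu Numeric mean vector of length n.
#' @param sigma Numeric symmetric positive-definite n x n covariance matrix.
#'   A scalar or a vector is accepted for n = 1 / diagonal shorthand.
#' @return An object of class `fr_gaussian` with fields `mu` and `sigma`.
#' @examples
#' theta <- fr_gaussian(c(-1, 0), matrix(c(1.1, 0.9, 0.9, 1.1), 2, 2))
#' theta
#' @export
fr_gaussian <- function(mu, sigma) {
  mu <- as.numeric(mu)
  n <- length(mu)
  if (n < 1) stop("mean vector must have length >= 1")
  if (!is.matrix(sigma)) {
    sigma <- if (length(sigma) == 1) matrix(sigma, 1, 1) else diag(as.numeric(sigma))
  }
  if (!is_square(sigma)) stop("covariance must be a square matrix")
  if (nrow(sigma) != n) {
    stop(sprintf("dimension mismatch: mean has length %d, covariance is %d x %d",
                 n, nrow(sigma), ncol(sigma)))
  }
  scale <- max(fnorm(sigma), .Machine$double.eps)
  if (max(abs(sigma - t(sigma))) > 1e-9 * scale) {
    stop("covariance is not symmetric within tolerance")
  }
  sigma <- sym(sigma)
  ev <- eigen(sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-12 * scale) {
    stop(sprintf("covariance is not positive definite (smallest eigenvalue %.3e)",
                 min(ev)))
  }
  structure(list(mu = mu, sigma = sigma), class = "fr_gaussian")
}

#' @export
print.fr_gaussian <- function(x, ...) {
  cat(sprintf("Gaussian parameter point (n = %d)\n", length(x$mu)))
  cat("mu:   ", paste(format(x$mu, digits = 6), collapse = "  "), "\n")
  cat("sigma:\n")
  print(x$sigma, digits = 6)
  invisible(x)
}

#' Tangent vector at the standard point
#'
#' A tangent vector to the normal-family manifold at \eqn{(0, I_n)},
#' represented as a pair (x, B) of a vector and a symmetric matrix.
#'
#' @param x Numeric vector of length n.
#' @param B Symmetric n x n matrix.
#' @return An object of class `fr_tangent`.
#' @export
fr_tangent <- function(x, B) {
  x <- as.numeric(x)
  if (!is.matrix(B)) B <- matrix(B, 1, 1)
  if (!is_square(B) || nrow(B) != length(x)) stop("dimension mismatch in tangent vector")
  if (max(abs(B - t(B))) > 1e-9 * max(1, fnorm(B))) stop("B must be symmetric")
  structure(list(x = x, B = sym(B)), class = "fr_tangent")
}

#' Scalar matrix functions of a symmetric positive-definite matrix
#'
#' Applies sqrt, inverse sqrt, log or exp to an SPD (symmetric for `exp`)
#' matrix through its symmetric eigendecomposition.
#'
#' @param S Symmetric matrix; positive definite for `sqrt`, `inv_sqrt`, `log`.
#' @param fun One of `"sqrt"`, `"inv_sqrt"`, `"log"`, `"exp"`.
#' @return A symmetric matrix of the same order.
#' @export
spd_fun <- function(S, fun = c("sqrt", "inv_sqrt", "log", "exp")) {
  fun <- match.arg(fun)
  if (!is.matrix(S)) S <- matrix(S, 1, 1)
  e <- eigen(sym(S), symmetric = TRUE)
  if (fun != "exp" && min(e$values) <= 0) {
    stop(sprintf("matrix %s requires a positive-definite input (min eigenvalue %.3e)",
                 fun, min(e$values)))
  }
  g <- switch(fun,
    sqrt = sqrt(e$values),
    inv_sqrt = 1 / sqrt(e$values),
    log = log(e$values),
    exp = exp(e$values))
  sym(e$vectors %*% (g * t(e$vectors)))
}

#' Affine isometry of the normal-family manifold
#'
#' The map \eqn{(\mu, \Sigma) \mapsto (Q\mu + c, Q\Sigma Q^t)} is an isometry
#' of the Fisher-Rao metric for any invertible Q.
#'
#' @param c Numeric translation vector.
#' @param Q Invertible n x n matrix.
#' @return An object of class `fr_isometry`.
#' @export
fr_isometry <- function(c, Q) {
  c <- as.numeric(c)
  if (!is.matrix(Q)) Q <- matrix(Q, 1, 1)
  if (!is_square(Q) || nrow(Q) != length(c)) stop("dimension mismatch in isometry")
  if (abs(det(Q)) < .Machine$double.eps * max(1, fnorm(Q))) stop("Q must be invertible")
  structure(list(c = c, Q = Q), class = "fr_isometry")
}

#' Apply an affine isometry to a Gaussian parameter point
#'
#' @param iso An `fr_isometry`.
#' @param theta An `fr_gaussian`.
#' @return The transformed `fr_gaussian` \eqn{(Q\mu + c, Q\Sigma Q^t)}.
#' @export
apply_isometry <- function(iso, theta) {
  stopifnot(inherits(iso, "fr_isometry"), inherits(theta, "fr_gaussian"))
  if (length(iso$c) != length(theta$mu)) stop("dimension mismatch")
  fr_gaussian(drop(iso$Q %*% theta$mu) + iso$c,
              sym(iso$Q %*% theta$sigma %*% t(iso$Q)))
}

#' Canonicalize a pair of Gaussians to ((0, I), theta3)
#'
#' Whitening by the first argument: with \eqn{Q = \Sigma_1^{-1/2}} and
#' \eqn{c = -Q\mu_1}, the pair \eqn{(\theta_1, \theta_2)} is mapped
#' isometrically to \eqn{((0, I_n), \theta_3)} with
#' \eqn{\theta_3 = (\Sigma_1^{-1/2}(\mu_2 - \mu_1),
#' \Sigma_1^{-1/2}\Sigma_2\Sigma_1^{-1/2})}, so all pairwise distance
#' computations may assume the first point is standard.
#'
#' @param theta1,theta2 `fr_gaussian` points of the same dimension.
#' @return A list with `theta3` (`fr_gaussian`) and `iso` (`fr_isometry`).
#' @export
canonicalize_pair <- function(theta1, theta2) {
  stopifnot(inherits(theta1, "fr_gaussian"), inherits(theta2, "fr_gaussian"))
  if (length(theta1$mu) != length(theta2$mu)) stop("dimension mismatch")
  Q <- spd_fun(theta1$sigma, "inv_sqrt")
  iso <- fr_isometry(-drop(Q %*% theta1$mu), Q)
  list(theta3 = apply_isometry(iso, theta2), iso = iso)
}

#' Natural coordinates of a Gaussian
#'
#' The chart \eqn{(\delta, \Delta) = (\Sigma^{-1}\mu, \Sigma^{-1})} in which
#' the Fisher-Rao geodesic through \eqn{(0, I_n)} has a closed form.
#'
#' @param theta An `fr_gaussian`.
#' @return A list with fields `delta` (vector) and `Delta` (SPD matrix),
#'   class `fr_natural`.
#' @export
to_natural <- function(theta) {
  stopifnot(inherits(theta, "fr_gaussian"))
  Delta <- sym(solve(theta$sigma))
  structure(list(delta = drop(Delta %*% theta$mu), Delta = Delta),
            class = "fr_natural")
}

#' @rdname to_natural
#' @param nc An `fr_natural` coordinate pair.
#' @export
from_natural <- function(nc) {
  sigma <- sym(solve(nc$Delta))
  fr_gaussian(drop(sigma %*% nc$delta), sigma)
}

#' Fisher metric inner product of two tangent vectors
#'
#' Evaluates \eqn{x_1^t \Sigma^{-1} x_2 +
#' \frac{1}{2}\mathrm{tr}(\Sigma^{-1} B_1 \Sigma^{-1} B_2)} at the point
#' `theta`.
#'
#' @param theta An `fr_gaussian`.
#' @param v1,v2 `fr_tangent` vectors.
#' @return A scalar.
#' @export
metric_inner <- function(theta, v1, v2 = v1) {
  stopifnot(inherits(theta, "fr_gaussian"),
            inherits(v1, "fr_tangent"), inherits(v2, "fr_tangent"))
  Si <- solve(theta$sigma)
  drop(t(v1$x) %*% Si %*% v2$x) + 0.5 * sum(diag(Si %*% v1$B %*% Si %*% v2$B))
}
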