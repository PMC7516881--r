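# Closed-form Fisher-Rao distances and geodesics on the classical
# submanifolds, and the exact full-manifold closed form for pairs sharing a
# covariance matrix (Householder rotation + UDU^t factorization).

same_sigma <- function(theta1, theta2, tol = 1e-9) {
  fnorm(theta1$sigma - theta2$sigma) <=
    tol * max(fnorm(theta1$sigma), fnorm(theta2$sigma), .Machine$double.eps)
}

diag_part <- function(theta, tol = 1e-9) {
  S <- theta$sigma
  off <- S - diag(diag(S), nrow(S))
  if (max(abs(off)) > tol * max(fnorm(S), .Machine$double.eps)) {
    stop("covariance is not diagonal")
  }
  diag(S)
}

#' Mahalanobis distance (constant-covariance submanifold)
#'
#' The Fisher-Rao distance restricted to normals sharing the covariance
#' \eqn{\Sigma_0}: \eqn{\sqrt{(\mu_1-\mu_2)^t \Sigma_0^{-1} (\mu_1-\mu_2)}},
#' i.e. the Euclidean distance after whitening. This submanifold is not
#' totally geodesic, so the value strictly exceeds the full-manifold
#' distance ([dist_common_sigma]) for non-diagonal directions.
#'
#' @param theta1,theta2 `fr_gaussian` points with equal covariance.
#' @return The restricted (Mahalanobis) distance.
#' @export
dist_mahalanobis <- function(theta1, theta2) {
  if (!same_sigma(theta1, theta2)) {
    stop("covariances differ; use fisher_rao() for the general distance")
  }
  d <- theta1$mu - theta2$mu
  sqrt(drop(t(d) %*% solve(theta1$sigma) %*% d))
}

#' @rdname dist_mahalanobis
#' @param t Curve parameter in `[0, 1]`.
#' @return For `geodesic_const_sigma`, the point \eqn{((1-t)\mu_1 + t\mu_2,
#'   \Sigma_0)} on the restricted geodesic.
#' @export
geodesic_const_sigma <- function(theta1, theta2, t) {
  if (!same_sigma(theta1, theta2)) stop("covariances differ")
  fr_gaussian((1 - t) * theta1$mu + t * theta2$mu, theta1$sigma)
}

#' Fisher-Rao distance between normals with a common mean
#'
#' On the totally geodesic submanifold of fixed mean the distance is the
#' affine-invariant SPD distance \eqn{\sqrt{\frac{1}{2}\sum_i
#' \log^2 \lambda_i}} with \eqn{\lambda_i} the eigenvalues of
#' \eqn{\Sigma_1^{-1/2}\Sigma_2\Sigma_1^{-1/2}}; it equals the full-manifold
#' distance.
#'
#' @param theta1,theta2 `fr_gaussian` points with equal means.
#' @return The exact Fisher-Rao distance.
#' @export
dist_common_mean <- function(theta1, theta2) {
  if (max(abs(theta1$mu - theta2$mu)) > 1e-9 * max(1, sqrt(sum(theta1$mu^2)))) {
    stop("means differ")
  }
  W <- spd_fun(theta1$sigma, "inv_sqrt")
  lam <- eigen(sym(W %*% theta2$sigma %*% W), symmetric = TRUE,
               only.values = TRUE)$values
  sqrt(0.5 * sum(log(lam)^2))
}

#' @rdname dist_common_mean
#' @param t Curve parameter in `[0, 1]`.
#' @return For `geodesic_common_mean`, the point
#'   \eqn{(\mu_0, \Sigma_1^{1/2}\exp(t\log(\Sigma_1^{-1/2}\Sigma_2
#'   \Sigma_1^{-1/2}))\Sigma_1^{1/2})}.
#' @export
geodesic_common_mean <- function(theta1, theta2, t) {
  if (max(abs(theta1$mu - theta2$mu)) > 1e-9 * max(1, sqrt(sum(theta1$mu^2)))) {
    stop("means differ")
  }
  H <- spd_fun(theta1$sigma, "sqrt")
  W <- spd_fun(theta1$sigma, "inv_sqrt")
  L <- spd_fun(sym(W %*% theta2$sigma %*% W), "log")
  fr_gaussian(theta1$mu, sym(H %*% spd_fun(t * L, "exp") %*% H))
}

#' Product-metric distance on the diagonal-covariance submanifold
#'
#' \eqn{d_D = \sqrt{\sum_i d_{F^*}^2((\mu_{1i}, \sigma_{1i}),
#' (\mu_{2i}, \sigma_{2i}))}}. The diagonal submanifold is not totally
#' geodesic, so this is an upper bound on the full-manifold distance.
#'
#' @param theta1,theta2 `fr_gaussian` points with diagonal covariances.
#' @return The restricted product-metric distance.
#' @export
dist_diagonal <- function(theta1, theta2) {
  s1 <- sqrt(diag_part(theta1))
  s2 <- sqrt(diag_part(theta2))
  sqrt(sum(uv_fisher_rao(theta1$mu, s1, theta2$mu, s2)^2))
}

#' Exact distance when the means lie on a common covariance eigen-axis
#'
#' On the totally geodesic submanifold of diagonal covariances with mean
#' along the first canonical axis, the full-manifold distance is
#' \eqn{\sqrt{d_{F^*}^2((\mu_{11},\sigma_{11}), (\mu_{21},\sigma_{21})) +
#' \sum_{i\ge 2} d_{F^*}^2((0,\sigma_{1i}), (0,\sigma_{2i}))}}.
#'
#' @param theta1,theta2 `fr_gaussian` points with diagonal covariances and
#'   means proportional to the first canonical vector.
#' @return The exact Fisher-Rao distance.
#' @export
dist_diag_eigenmean <- function(theta1, theta2) {
  s1 <- sqrt(diag_part(theta1))
  s2 <- sqrt(diag_part(theta2))
  n <- length(s1)
  for (theta in list(theta1, theta2)) {
    if (n > 1 && max(abs(theta$mu[-1])) > 1e-9 * max(1, abs(theta$mu[1]))) {
      stop("means must be proportional to the first canonical vector")
    }
  }
  d2 <- uv_fisher_rao(theta1$mu[1], s1[1], theta2$mu[1], s2[1])^2
  if (n > 1) d2 <- d2 + sum(uv_fisher_rao(0, s1[-1], 0, s2[-1])^2)
  sqrt(d2)
}

#' UDU^t factorization of an SPD matrix
#'
#' Factors S = U D U^t with U unit-upper-triangular and D positive diagonal,
#' via the reversal-conjugated Cholesky factorization. The unit-triangular
#' factor fixes the first canonical vector (U^{-1} e1 = e1), which is what
#' keeps the mean on the e1 axis in the common-covariance closed form.
#'
#' @param S SPD matrix.
#' @return List with components `U` (unit upper triangular) and `d`
#'   (diagonal entries of D).
#' @export
udu_decompose <- function(S) {
  if (!is.matrix(S)) S <- matrix(S, 1, 1)
  n <- nrow(S)
  J <- diag(n)[n:1, , drop = FALSE]
  R <- tryCatch(chol(sym(J %*% S %*% J)), error = function(e) {
    stop("matrix is not positive definite")
  })
  Up <- J %*% t(R) %*% J              # upper triangular, S = Up Up^t
  d <- diag(Up)
  U <- Up %*% diag(1 / d, n)
  list(U = U, d = d^2)
}

#' Exact Fisher-Rao distance between normals sharing a covariance matrix
#'
#' Full-manifold closed form: rotate the mean difference onto the first
#' canonical axis with an orthogonal P, factor \eqn{P\Sigma P^t = U D U^t}
#' with U unit-upper-triangular, and evaluate the totally geodesic
#' eigen-axis distance between \eqn{(0, D)} and
#' \eqn{(|\mu_2 - \mu_1| e_1, D)}. Always bounded above by the Mahalanobis
#' distance, strictly when the whitened geometry is curved.
#'
#' @param theta1,theta2 `fr_gaussian` points with equal covariance matrices.
#' @return The exact Fisher-Rao distance in the full manifold.
#' @examples
#' S <- matrix(c(1.1, 0.9, 0.9, 1.1), 2, 2)
#' dist_common_sigma(fr_gaussian(c(-1, 0), S), fr_gaussian(c(6, 3), S))
#' @export
dist_common_sigma <- function(theta1, theta2) {
  if (!same_sigma(theta1, theta2)) stop("covariances differ")
  dm <- theta2$mu - theta1$mu
  r <- sqrt(sum(dm^2))
  if (r == 0) return(0)
  P <- householder_to_e1(dm)
  f <- udu_decompose(sym(P %*% theta1$sigma %*% t(P)))
  s <- sqrt(f$d)
  # dDmu((0, D), (r e1, D)): only the first coordinate contributes, the
  # remaining univariate pairs (0, s_i) coincide.
  uv_fisher_rao(0, s[1], r, s[1])
}
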