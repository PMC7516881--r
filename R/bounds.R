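# Lower and upper bounds for the Fisher-Rao distance in the full manifold:
# the Calvo-Oller embedding lower bound, the diagonalization bound UB1, the
# analytic triangle bound UB3 and its numerically optimized refinement UB2.

#' Isometric SPD embedding of a Gaussian
#'
#' The (n+1)-order SPD block matrix
#' \eqn{S = [[\Sigma + \mu\mu^t, \mu], [\mu^t, 1]]} realizing the
#' Calvo-Oller embedding of the normal family into the SPD cone.
#'
#' @param theta An `fr_gaussian`.
#' @return An (n+1) x (n+1) SPD matrix.
#' @export
embed_spd <- function(theta) {
  stopifnot(inherits(theta, "fr_gaussian"))
  mu <- theta$mu
  S <- rbind(cbind(theta$sigma + outer(mu, mu), mu), c(mu, 1))
  dimnames(S) <- NULL
  S
}

#' Calvo-Oller lower bound on the Fisher-Rao distance
#'
#' Half the affine-invariant SPD distance between the embedded matrices:
#' \eqn{\sqrt{\frac12 \sum_{i=1}^{n+1} \log^2 \lambda_i}} with
#' \eqn{\lambda_i} the eigenvalues of \eqn{S_1^{-1/2} S_2 S_1^{-1/2}}.
#' This is itself a metric on the normal family.
#'
#' @param theta1,theta2 `fr_gaussian` points of the same dimension.
#' @return The lower bound.
#' @export
fr_lower_bound <- function(theta1, theta2) {
  W <- spd_fun(embed_spd(theta1), "inv_sqrt")
  lam <- eigen(sym(W %*% embed_spd(theta2) %*% W), symmetric = TRUE,
               only.values = TRUE)$values
  sqrt(0.5 * sum(log(lam)^2))
}

#' Upper bound UB1 by simultaneous diagonalization
#'
#' Whitens by the first covariance, diagonalizes the whitened second
#' covariance \eqn{A = Q\Lambda Q^t}, rotates the whitened mean difference
#' into the eigenbasis, and sums squared univariate distances per coordinate:
#' \eqn{\sqrt{\sum_i d_{F^*}^2((0,1), (\mu_i, \sqrt{\lambda_i}))}}. Each
#' eigenvalue is paired with the mean component along the same eigenvector.
#'
#' @param theta1,theta2 `fr_gaussian` points of the same dimension.
#' @return The upper bound UB1.
#' @export
fr_ub1 <- function(theta1, theta2) {
  W <- spd_fun(theta1$sigma, "inv_sqrt")
  A <- sym(W %*% theta2$sigma %*% W)
  e <- eigen(A, symmetric = TRUE)
  mu <- drop(t(e$vectors) %*% W %*% (theta2$mu - theta1$mu))
  sqrt(sum(uv_fisher_rao(0, 1, mu, sqrt(e$values))^2))
}

#' Analytic upper bound UB3 via the totally geodesic eigen-axis submanifold
#'
#' Canonicalizes the pair to ((0, I), theta3), rotates the mean onto e1, and
#' inserts the intermediate point with covariance
#' \eqn{\bar\Sigma = P^{-1} D P^{-t}}, \eqn{D = \mathrm{diag}(\sigma_*^2,
#' 1, \ldots, 1)} where \eqn{\sigma_*^2 = (|\mu_3|^2 + 2)/2} is the analytic
#' minimizer of \eqn{d \mapsto d_{F^*}((0,1), (|\mu_3|, d))} (the foot of the
#' hyperbolic perpendicular). The bound is the triangle sum
#' \eqn{d_{F^*}((0,1),(|\mu_3|,\sigma_*)) + d_\mu(\bar\theta, \theta_3)}.
#'
#' @param theta1,theta2 `fr_gaussian` points of the same dimension.
#' @return The upper bound UB3.
#' @export
fr_ub3 <- function(theta1, theta2) {
  theta3 <- canonicalize_pair(theta1, theta2)$theta3
  mu3 <- theta3$mu
  r <- sqrt(sum(mu3^2))
  if (r < 1e-12) return(dist_common_mean(fr_gaussian(mu3, diag(length(mu3))) ,
                                         fr_gaussian(mu3, theta3$sigma)))
  sstar2 <- (r^2 + 2) / 2
  P <- householder_to_e1(mu3)
  D <- diag(c(sstar2, rep(1, length(mu3) - 1)), length(mu3))
  Sbar <- sym(t(P) %*% D %*% P)
  W <- spd_fun(Sbar, "inv_sqrt")
  lam <- eigen(sym(W %*% theta3$sigma %*% W), symmetric = TRUE,
               only.values = TRUE)$values
  uv_fisher_rao(0, 1, r, sqrt(sstar2)) + sqrt(0.5 * sum(log(lam)^2))
}

#' Optimized upper bound UB2
#'
#' Same triangle construction as [fr_ub3], but the diagonal matrix D of the
#' intermediate point is optimized numerically (BFGS in log standard
#' deviations, multistart from the UB3 solution and the identity). Any
#' evaluation of the objective is itself a valid upper bound, so the
#' achieved minimum is returned even on non-convergence; always
#' \eqn{\le} UB3.
#'
#' @param theta1,theta2 `fr_gaussian` points of the same dimension.
#' @return The upper bound UB2.
#' @export
fr_ub2 <- function(theta1, theta2) {
  theta3 <- canonicalize_pair(theta1, theta2)$theta3
  n <- length(theta3$mu)
  mu3 <- theta3$mu
  r <- sqrt(sum(mu3^2))
  P <- householder_to_e1(mu3)
  obj <- function(logs) {
    s <- exp(logs)
    # d_Dmu((0, I), (r e1, diag(s^2)))
    d1 <- sqrt(uv_fisher_rao(0, 1, r, s[1])^2 +
                 sum(uv_fisher_rao(0, 1, 0, s[-1])^2))
    Sbar <- sym(t(P) %*% diag(s^2, n) %*% P)
    W <- spd_fun(Sbar, "inv_sqrt")
    lam <- eigen(sym(W %*% theta3$sigma %*% W), symmetric = TRUE,
                 only.values = TRUE)$values
    d1 + sqrt(0.5 * sum(log(lam)^2))
  }
  sstar <- sqrt((r^2 + 2) / 2)
  inits <- list(log(c(sstar, rep(1, n - 1))), rep(0, n))
  best <- Inf
  for (z0 in inits) {
    o <- tryCatch(
      stats::optim(z0, obj, method = "BFGS",
                   control = list(maxit = 500, reltol = 1e-12)),
      error = function(e) NULL)
    if (!is.null(o) && is.finite(o$value)) best <- min(best, o$value)
    best <- min(best, obj(z0))
  }
  best
}

#' Bound report: lower bound and the upper-bound envelope
#'
#' Assembles LB, UB1, UB2, UB3 and their envelope
#' \eqn{UB123 = \min(UB1, UB2, UB3)} for a pair of Gaussians.
#'
#' @param theta1,theta2 `fr_gaussian` points of the same dimension.
#' @return An object of class `fr_bounds` with fields `lb`, `ub1`, `ub2`,
#'   `ub3`, `ub123`.
#' @export
fr_bounds <- function(theta1, theta2) {
  lb <- fr_lower_bound(theta1, theta2)
  u1 <- fr_ub1(theta1, theta2)
  u2 <- fr_ub2(theta1, theta2)
  u3 <- fr_ub3(theta1, theta2)
  structure(list(lb = lb, ub1 = u1, ub2 = u2, ub3 = u3,
                 ub123 = min(u1, u2, u3)),
            class = "fr_bounds")
}

#' @export
print.fr_bounds <- function(x, ...) {
  cat(sprintf("Fisher-Rao distance bounds:\n  LB    %.6f\n  UB1   %.6f\n  UB2   %.6f\n  UB3   %.6f\n  UB123 %.6f\n",
              x$lb, x$ub1, x$ub2, x$ub3, x$ub123))
  invisible(x)
}

#' Bound comparison sweep over the rotated-eigenvalue family
#'
#' Evaluates LB, UB1, UB2, UB3 and the shooting distance between the
#' standard point and \eqn{(\mu e_1, R_\alpha \mathrm{diag}(\lambda_1,
#' \lambda_2) R_\alpha^t)} over a grid of rotation angles, the family on
#' which the relative quality of the bounds flips with the mean separation.
#'
#' @param lambda1,lambda2 Covariance eigenvalues.
#' @param mu Mean offset along e1.
#' @param alpha Vector of rotation angles (radians).
#' @param shooting If `TRUE`, also compute the geodesic-shooting distance.
#' @return A data frame with one row per angle.
#' @export
bounds_sweep <- function(lambda1 = 2, lambda2 = 0.5, mu = 1,
                         alpha = seq(0, pi / 2, length.out = 65),
                         shooting = FALSE) {
  rows <- lapply(alpha, function(a) {
    pair <- make_rotated_pair(lambda1, lambda2, mu, a)
    b <- fr_bounds(pair[[1]], pair[[2]])
    gs <- if (shooting) geodesic_shooting(pair[[1]], pair[[2]])$distance else NA_real_
    data.frame(alpha = a, lb = b$lb, ub1 = b$ub1, ub2 = b$ub2, ub3 = b$ub3,
               ub123 = b$ub123, shooting = gs)
  })
  do.call(rbind, rows)
}
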