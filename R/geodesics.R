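# The explicit Fisher-Rao geodesic in natural coordinates, a geodesic
# shooting boundary-value solver built on it, and the mirrored-pair
# non-linear system with its closed-form distance.

#' Explicit geodesic through (0, I) in natural coordinates
#'
#' Evaluates the closed-form geodesic of the normal-family manifold emanating
#' from the standard point with initial tangent (x, B): in the natural chart
#' \eqn{(\delta, \Delta) = (\Sigma^{-1}\mu, \Sigma^{-1})},
#' \deqn{\delta(t) = -B(\cosh(tG) - I)(G^-)^2 x + \sinh(tG) G^- x}
#' \deqn{\Delta(t) = I + \tfrac12(\cosh(tG) - I) + \tfrac12 B(\cosh(tG) -
#'   I)(G^-)^2 B - \tfrac12 \sinh(tG) G^- B - \tfrac12 B \sinh(tG) G^-}
#' with \eqn{G^2 = B^2 + 2xx^t}. The generalized inverse is realized
#' spectrally through the scalar kernels \eqn{(\cosh(tg)-1)/g^2} and
#' \eqn{\sinh(tg)/g} with their analytic limits at g = 0.
#'
#' @param v An `fr_tangent` (x, B).
#' @param t Curve parameter (scalar).
#' @return An `fr_natural` coordinate pair \eqn{(\delta(t), \Delta(t))}.
#' @export
geodesic_natural <- function(v, t) {
  stopifnot(inherits(v, "fr_tangent"))
  x <- v$x
  B <- v$B
  n <- length(x)
  G2 <- sym(B %*% B + 2 * outer(x, x))
  e <- eigen(G2, symmetric = TRUE)
  g <- sqrt(pmax(e$values, 0))
  small <- g < 1e-6
  k0 <- cosh(t * g) - 1
  k1 <- ifelse(small, t^2 / 2 + t^4 * g^2 / 24, k0 / g^2)
  k2 <- ifelse(small, t + t^3 * g^2 / 6, sinh(t * g) / g)
  V <- e$vectors
  C2 <- V %*% (k1 * t(V))     # (cosh(tG) - I)(G^-)^2
  S1 <- V %*% (k2 * t(V))     # sinh(tG) G^-
  C0 <- V %*% (k0 * t(V))     # cosh(tG) - I
  delta <- drop(-B %*% C2 %*% x + S1 %*% x)
  Delta <- diag(n) + 0.5 * C0 + 0.5 * B %*% C2 %*% B -
    0.5 * S1 %*% B - 0.5 * B %*% S1
  structure(list(delta = delta, Delta = sym(Delta)), class = "fr_natural")
}

#' Speed (and endpoint distance) of the explicit geodesic
#'
#' The geodesic with tangent (x, B) has constant speed
#' \eqn{\sqrt{\frac12 \mathrm{tr}(B^2) + |x|^2}}, which is the Fisher-Rao
#' distance from (0, I) to the time-1 endpoint whenever the geodesic is
#' minimizing.
#'
#' @param v An `fr_tangent`.
#' @return A scalar speed.
#' @export
tangent_speed <- function(v) {
  stopifnot(inherits(v, "fr_tangent"))
  sqrt(0.5 * sum(v$B^2) + sum(v$x^2))
}

# Residual of the shooting problem in the canonical frame: the time-1
# endpoint of the geodesic with tangent u = (x, vech(B)) must match the
# target natural coordinates (delta*, Delta*).
shoot_residual <- function(u, n, delta_t, Delta_t) {
  x <- u[seq_len(n)]
  B <- unvech(u[-seq_len(n)], n)
  g <- geodesic_natural(fr_tangent(x, B), 1)
  c(g$delta - delta_t, vech(g$Delta - Delta_t))
}

#' Geodesic shooting between two Gaussians
#'
#' Solves the boundary-value problem by canonicalizing the pair to
#' ((0, I), theta3) and finding the initial tangent (x, B) whose explicit
#' time-1 endpoint matches theta3 in natural coordinates. A damped Newton
#' iteration on the square endpoint-residual system is tried from a matrix-log
#' initialization (B = -log(Delta_target), x = delta-based), with scaled
#' multistarts and a mean-separation continuation fallback for distant pairs.
#'
#' @param theta1,theta2 `fr_gaussian` points of the same dimension.
#' @param tol Convergence tolerance on the endpoint residual norm.
#' @return A list of class `fr_shooting` with `tangent` (`fr_tangent` at the
#'   canonical frame), `distance`, and `endpoint_error`.
#' @export
geodesic_shooting <- function(theta1, theta2, tol = 1e-10) {
  can <- canonicalize_pair(theta1, theta2)
  theta3 <- can$theta3
  n <- length(theta3$mu)
  nc <- to_natural(theta3)

  solve_target <- function(delta_t, Delta_t, u0) {
    fn <- function(u) shoot_residual(u, n, delta_t, Delta_t)
    damped_newton(fn, u0, tol = tol, maxit = 100L)
  }

  B0 <- -spd_fun(nc$Delta, "log")
  inits <- list(c(nc$delta, vech(B0)),
                0.5 * c(nc$delta, vech(B0)),
                c(nc$delta, 0.25 * vech(B0)))
  best <- NULL
  for (u0 in inits) {
    sol <- solve_target(nc$delta, nc$Delta, u0)
    if (is.null(best) || sol$residual < best$residual) best <- sol
    if (best$converged) break
  }
  if (!best$converged) {
    # continuation on the mean separation: shrink delta* toward zero, where
    # the equal-mean matrix-log solution is exact, then walk back out
    u <- c(rep(0, n), vech(B0))
    ok <- TRUE
    for (s in seq(0.1, 1, by = 0.1)) {
      sol <- solve_target(s * nc$delta, nc$Delta, u)
      if (!sol$converged) { ok <- FALSE; break }
      u <- sol$u
    }
    if (ok) best <- sol
  }
  if (!best$converged) {
    stop(sprintf("geodesic shooting did not converge (best endpoint error %.3e)",
                 best$residual))
  }
  x <- best$u[seq_len(n)]
  B <- unvech(best$u[-seq_len(n)], n)
  v <- fr_tangent(x, B)
  structure(list(tangent = v, distance = tangent_speed(v),
                 endpoint_error = best$residual),
            class = "fr_shooting")
}

#' @export
print.fr_shooting <- function(x, ...) {
  cat(sprintf("Geodesic shooting: distance %.6f (endpoint error %.2e)\n",
              x$distance, x$endpoint_error))
  invisible(x)
}

# ---- mirrored pairs --------------------------------------------------------

# Canonical frame for a candidate mirrored pair: rotate the mean difference
# onto e1 when needed. Returns the rotation and the rotated pair.
mirrored_frame <- function(theta1, theta2) {
  dm <- theta2$mu - theta1$mu
  if (sqrt(sum(dm^2)) > 0 && length(dm) > 1 &&
      max(abs(dm[-1])) > 1e-12 * max(1, abs(dm[1]))) {
    P <- householder_to_e1(dm)
  } else {
    P <- diag(length(dm))
  }
  iso <- fr_isometry(rep(0, length(dm)), P)
  list(P = P, t1 = apply_isometry(iso, theta1), t2 = apply_isometry(iso, theta2))
}

#' Test whether two Gaussians form a mirrored pair
#'
#' A pair is mirrored when (after rotating the mean difference onto the first
#' canonical axis) the means differ only in their first coordinate and the
#' covariances are conjugate by the reflection negating that axis:
#' \eqn{\Sigma_2 = M_1 \Sigma_1 M_1} with \eqn{M_1 =
#' \mathrm{diag}(-1, 1, \ldots, 1)} (first row/column off-diagonal entries
#' negated, all other entries equal).
#'
#' @param theta1,theta2 `fr_gaussian` points.
#' @param tol Relative tolerance of the structure test.
#' @return Logical flag.
#' @export
is_mirrored <- function(theta1, theta2, tol = 1e-9) {
  if (length(theta1$mu) != length(theta2$mu)) return(FALSE)
  n <- length(theta1$mu)
  if (n < 2) return(FALSE)
  fr <- mirrored_frame(theta1, theta2)
  t1 <- fr$t1; t2 <- fr$t2
  if (max(abs(t1$mu[-1] - t2$mu[-1])) > tol * max(1, sqrt(sum(t1$mu^2)))) {
    return(FALSE)
  }
  M1 <- diag(c(-1, rep(1, n - 1)))
  fnorm(t2$sigma - M1 %*% t1$sigma %*% M1) <=
    tol * max(fnorm(t1$sigma), .Machine$double.eps)
}

# Unpack the mirrored-system unknown vector for dimension n:
# (x, b[1..n-1], eta[1..n-1], d11, vech(Dmid)).
mirrored_unpack <- function(u, n) {
  m <- n - 1
  x <- u[1]
  b <- u[2:(1 + m)]
  eta <- u[(2 + m):(1 + 2 * m)]
  d11 <- u[2 + 2 * m]
  Dmid <- unvech(u[(3 + 2 * m):length(u)], m)
  list(x = x, b = b, eta = eta, d11 = d11, Dmid = Dmid)
}

mirrored_tangent <- function(x, b) {
  n <- length(b) + 1
  B <- matrix(0, n, n)
  B[1, 2:n] <- b
  B[2:n, 1] <- b
  fr_tangent(c(x, rep(0, n - 1)), B)
}

# Cholesky factor (lower triangular) of blockdiag(d11^2, Dmid); NULL if the
# block is not positive definite.
mirrored_chol <- function(d11, Dmid) {
  m <- nrow(Dmid)
  R <- tryCatch(chol(sym(Dmid)), error = function(e) NULL)
  if (is.null(R) || d11 <= 0) return(NULL)
  L <- matrix(0, m + 1, m + 1)
  L[1, 1] <- d11
  L[2:(m + 1), 2:(m + 1)] <- t(R)
  L
}

# Residual of the mirrored boundary system in a frame where the mean
# difference is along e1 and the shared mean tail is `tail`.
mirrored_residual <- function(u, n, mu1_1, mu2_1, tail, Delta2, delta2) {
  p <- mirrored_unpack(u, n)
  L <- mirrored_chol(p$d11, p$Dmid)
  if (is.null(L)) return(rep(1e6, length(u)))
  g <- geodesic_natural(mirrored_tangent(p$x, p$b), 1)
  mu_half <- c((mu1_1 + mu2_1) / 2, tail + p$eta)
  rD <- g$Delta - t(L) %*% Delta2 %*% L
  rd <- g$delta - drop(t(L) %*% (delta2 - Delta2 %*% mu_half))
  c(vech(rD), rd)
}

#' Solve the mirrored-pair boundary system
#'
#' For a mirrored pair the connecting geodesic has midpoint
#' \eqn{\theta_{1/2} = (\mu_{1/2}, \Sigma_{1/2})} with block-diagonal
#' covariance \eqn{\mathrm{blockdiag}(d_{11}^2, D)} and a tangent of the
#' special form x along e1 and B with only first-row/column entries b. These
#' unknowns (together with the midpoint mean tail eta) satisfy a square
#' non-linear system of order n + n(n+1)/2 matching the explicit time-1
#' geodesic endpoint to the second distribution; the Fisher-Rao distance is
#' then \eqn{2\sqrt{\sum_l b_l^2 + x^2}}. The system is solved by damped
#' Newton with a mean-separation continuation fallback (robust up to large
#' separations where plain shooting fails).
#'
#' @param theta1,theta2 A mirrored `fr_gaussian` pair (see [is_mirrored]).
#' @param tol Residual max-norm tolerance of the Newton solve.
#' @return A list of class `fr_mirrored` with fields `x`, `b`, `eta`, `d11`,
#'   `Dmid`, `distance`, `residual`, plus the canonical-frame data used by
#'   [mirrored_geodesic].
#' @examples
#' S1 <- matrix(c(0.55, -0.45, -0.45, 0.55), 2, 2)
#' S2 <- matrix(c(0.55, 0.45, 0.45, 0.55), 2, 2)
#' sol <- mirrored_solve(fr_gaussian(c(-0.5, 0), S1), fr_gaussian(c(0.5, 0), S2))
#' sol$distance   # 2.77395
#' @export
mirrored_solve <- function(theta1, theta2, tol = 1e-10) {
  if (!is_mirrored(theta1, theta2)) stop("pair is not mirrored")
  n <- length(theta1$mu)
  m <- n - 1
  fr <- mirrored_frame(theta1, theta2)
  t1 <- fr$t1; t2 <- fr$t2
  tail <- t2$mu[-1]
  Delta2 <- sym(solve(t2$sigma))
  delta2 <- drop(Delta2 %*% t2$mu)

  init_for <- function(t2loc) {
    # midpoint covariance guess: diagonal block average of the two ends
    Shalf <- (t1$sigma + t2loc$sigma) / 2
    d11 <- sqrt(Shalf[1, 1])
    Dmid <- sym(Shalf[2:n, 2:n, drop = FALSE])
    L <- mirrored_chol(d11, Dmid)
    D2l <- sym(solve(t2loc$sigma))
    Bf <- -spd_fun(sym(t(L) %*% D2l %*% L), "log")
    x0 <- 0.5 * drop(t(L) %*% D2l %*% (t2loc$mu - c((t1$mu[1] + t2loc$mu[1]) / 2, tail)))[1]
    c(x0, Bf[1, 2:n], rep(0, m), d11, vech(Dmid))
  }

  # direct solve at the true separation
  sep <- t2$mu[1] - t1$mu[1]
  fn_full <- function(u) mirrored_residual(u, n, t1$mu[1], t2$mu[1], tail,
                                           Delta2, delta2)
  sol <- damped_newton(fn_full, init_for(t2), tol = tol, maxit = 200L)
  if (!sol$converged) {
    # continuation on the separation, starting from a close symmetric pair
    mid <- (t1$mu[1] + t2$mu[1]) / 2
    steps <- seq(0.25, 1, by = 0.25 / max(1, ceiling(abs(sep))))
    u <- NULL
    ok <- TRUE
    for (s in steps) {
      m1 <- mid - s * sep / 2
      m2 <- mid + s * sep / 2
      fn_s <- function(u_) mirrored_residual(u_, n, m1, m2, tail, Delta2,
                                             drop(Delta2 %*% c(m2, tail)))
      if (is.null(u)) {
        t2s <- fr_gaussian(c(m2, tail), t2$sigma)
        u <- init_for(t2s)
      }
      sol_s <- damped_newton(fn_s, u, tol = tol, maxit = 200L)
      if (!sol_s$converged) { ok <- FALSE; break }
      u <- sol_s$u
    }
    if (ok) sol <- sol_s
  }
  if (!sol$converged) {
    stop(sprintf("mirrored system solve failed (best residual %.3e)", sol$residual))
  }
  p <- mirrored_unpack(sol$u, n)
  structure(c(p, list(distance = 2 * sqrt(sum(p$b^2) + p$x^2),
                      residual = sol$residual,
                      frame_P = fr$P, theta1 = theta1,
                      mu_half = c((t1$mu[1] + t2$mu[1]) / 2, tail + p$eta))),
            class = "fr_mirrored")
}

#' @export
print.fr_mirrored <- function(x, ...) {
  cat(sprintf("Mirrored-pair solution: distance %.6f (residual %.2e)\n",
              x$distance, x$residual))
  cat(sprintf("x = %.6f, b = %s\n", x$x,
              paste(format(x$b, digits = 6), collapse = ", ")))
  invisible(x)
}

#' Evaluate the geodesic connecting a mirrored pair
#'
#' Maps the explicit natural-coordinate geodesic of the solved system back
#' through the midpoint isometry, so that \eqn{\gamma(-1) = \theta_1} and
#' \eqn{\gamma(1) = \theta_2}; \eqn{\gamma(0)} has the block-diagonal
#' midpoint covariance.
#'
#' @param sol An `fr_mirrored` solution.
#' @param t Curve parameter in `[-1, 1]` (values outside extend the geodesic).
#' @return An `fr_gaussian` on the geodesic.
#' @export
mirrored_geodesic <- function(sol, t) {
  stopifnot(inherits(sol, "fr_mirrored"))
  n <- length(sol$b) + 1
  g <- geodesic_natural(mirrored_tangent(sol$x, sol$b), t)
  theta_bar <- from_natural(g)
  L <- mirrored_chol(sol$d11, sol$Dmid)
  # psi^{-1}: (mu, S) -> (L mu + mu_half, L S L^t), then undo the frame rotation
  mu <- drop(L %*% theta_bar$mu) + sol$mu_half
  S <- L %*% theta_bar$sigma %*% t(L)
  P <- sol$frame_P
  fr_gaussian(drop(t(P) %*% mu), sym(t(P) %*% S %*% P))
}

#' Fisher-Rao distance with automatic method dispatch
#'
#' Routes each pair to the cheapest exact method: identical parameters,
#' common mean (affine-invariant SPD closed form), common covariance
#' (Householder + UDU^t closed form), diagonal covariances with means on the
#' first canonical axis (totally geodesic product form), mirrored pairs
#' (non-linear system), and geodesic shooting otherwise.
#'
#' @param theta1,theta2 `fr_gaussian` points of the same dimension.
#' @return A list of class `fr_dist` with `distance` and `method`.
#' @export
fisher_rao <- function(theta1, theta2) {
  stopifnot(inherits(theta1, "fr_gaussian"), inherits(theta2, "fr_gaussian"))
  if (length(theta1$mu) != length(theta2$mu)) stop("dimension mismatch")
  mu_tol <- 1e-9 * max(1, sqrt(sum(theta1$mu^2)))
  res <- if (max(abs(theta1$mu - theta2$mu)) <= mu_tol && same_sigma(theta1, theta2)) {
    list(distance = 0, method = "identical")
  } else if (max(abs(theta1$mu - theta2$mu)) <= mu_tol) {
    list(distance = dist_common_mean(theta1, theta2), method = "common-mean")
  } else if (same_sigma(theta1, theta2)) {
    list(distance = dist_common_sigma(theta1, theta2), method = "common-sigma")
  } else if (is_diag_eigenmean_pair(theta1, theta2)) {
    list(distance = dist_diag_eigenmean(theta1, theta2), method = "eigenmean")
  } else if (length(theta1$mu) >= 2 && is_mirrored(theta1, theta2)) {
    list(distance = mirrored_solve(theta1, theta2)$distance, method = "mirrored")
  } else {
    list(distance = geodesic_shooting(theta1, theta2)$distance,
         method = "shooting")
  }
  structure(res, class = "fr_dist")
}

#' Evaluate the connecting geodesic between two Gaussians
#'
#' Solves the boundary-value problem by shooting in the canonical frame and
#' maps the explicit natural-coordinate curve back through the whitening
#' isometry, so that `t = 0` gives `theta1` and `t = 1` gives `theta2`.
#'
#' @param theta1,theta2 `fr_gaussian` points of the same dimension.
#' @param t Vector of curve parameters in `[0, 1]` (outside values extend).
#' @return A list of `fr_gaussian` points, one per `t`.
#' @export
fr_geodesic <- function(theta1, theta2, t) {
  can <- canonicalize_pair(theta1, theta2)
  v <- geodesic_shooting(theta1, theta2)$tangent
  Qi <- solve(can$iso$Q)
  back <- fr_isometry(-drop(Qi %*% can$iso$c), Qi)
  lapply(t, function(ti) {
    apply_isometry(back, from_natural(geodesic_natural(v, ti)))
  })
}

is_diag_eigenmean_pair <- function(theta1, theta2) {
  ok <- tryCatch({
    diag_part(theta1); diag_part(theta2)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) return(FALSE)
  for (theta in list(theta1, theta2)) {
    mu <- theta$mu
    if (length(mu) > 1 && max(abs(mu[-1])) > 1e-9 * max(1, abs(mu[1]))) {
      return(FALSE)
    }
  }
  TRUE
}

#' @export
print.fr_dist <- function(x, ...) {
  cat(sprintf("Fisher-Rao distance: %.6f (method: %s)\n", x$distance, x$method))
  invisible(x)
}
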