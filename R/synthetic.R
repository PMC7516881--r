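# Seeded generators for the structured families used throughout the tests
# and experiments: random SPD matrices, the rotated-eigenvalue bound
# comparison family, mirrored pairs, planted mixtures and synthetic RGB
# images.

#' Random symmetric positive-definite matrix
#'
#' Draws a random orthogonal basis (QR of a Gaussian matrix) and log-uniform
#' eigenvalues inside `eig_range`.
#'
#' @param n Matrix order.
#' @param seed Optional integer seed.
#' @param eig_range Positive eigenvalue range (length 2).
#' @return An n x n SPD matrix.
#' @export
random_spd <- function(n, seed = NULL, eig_range = c(0.5, 2)) {
  if (!is.null(seed)) set.seed(seed)
  if (any(eig_range <= 0)) stop("eigenvalue range must be positive")
  lam <- exp(stats::runif(n, log(eig_range[1]), log(eig_range[2])))
  if (n == 1) return(matrix(lam, 1, 1))
  Q <- qr.Q(qr(matrix(stats::rnorm(n * n), n, n)))
  sym(Q %*% (lam * t(Q)))
}

#' Rotated-eigenvalue bivariate pair for bound comparisons
#'
#' Returns the standard point \eqn{(0, I_2)} together with
#' \eqn{(\mu e_1, R_\alpha \mathrm{diag}(\lambda_1, \lambda_2)
#' R_\alpha^t)}, the two-parameter family on which the quality ordering of
#' the distance bounds is studied.
#'
#' @param lambda1,lambda2 Positive covariance eigenvalues.
#' @param mu Mean offset along the first axis.
#' @param alpha Rotation angle in radians.
#' @return A list of two `fr_gaussian` points.
#' @export
make_rotated_pair <- function(lambda1, lambda2, mu, alpha) {
  if (lambda1 <= 0 || lambda2 <= 0) stop("eigenvalues must be positive")
  R <- matrix(c(cos(alpha), -sin(alpha), sin(alpha), cos(alpha)), 2, 2)
  S <- sym(R %*% diag(c(lambda1, lambda2)) %*% t(R))
  list(fr_gaussian(c(0, 0), diag(2)), fr_gaussian(c(mu, 0), S))
}

#' Random mirrored pair
#'
#' Means at \eqn{\mp(\mathrm{separation}/2) e_1} and covariances conjugate
#' by the axis reflection: \eqn{\Sigma_2 = M_1 \Sigma_1 M_1}. The mirror
#' structure holds exactly by construction.
#'
#' @param n Dimension (at least 2).
#' @param seed Optional integer seed for the random covariance.
#' @param separation Mean separation \eqn{|\mu_2 - \mu_1|}.
#' @param sigma1 Optional explicit first covariance (overrides the draw).
#' @return A list of two `fr_gaussian` points.
#' @export
make_mirrored_pair <- function(n = 2, seed = NULL, separation = 2,
                               sigma1 = NULL) {
  if (n < 2) stop("mirrored pairs need n >= 2")
  if (is.null(sigma1)) sigma1 <- random_spd(n, seed)
  M1 <- diag(c(-1, rep(1, n - 1)))
  sigma2 <- sym(M1 %*% sigma1 %*% M1)
  e1 <- c(1, rep(0, n - 1))
  list(fr_gaussian(-separation / 2 * e1, sigma1),
       fr_gaussian(separation / 2 * e1, sigma2))
}

#' Planted group-structured diagonal Gaussian mixture
#'
#' Builds `groups` well-separated centers and `per_group` near-duplicate
#' components around each, giving a mixture whose ideal simplification level
#' and partition are known. The planted partition is attached as attribute
#' `"partition"`.
#'
#' @param n Dimension.
#' @param groups Number of planted groups.
#' @param per_group Components per group.
#' @param seed Optional integer seed.
#' @param separation Distance scale between group centers (within-group
#'   jitter has scale 1/20 of it).
#' @return An `fr_dgmm` with `groups * per_group` components.
#' @export
make_planted_dgmm <- function(n = 1, groups = 3, per_group = 4, seed = NULL,
                              separation = 10) {
  if (!is.null(seed)) set.seed(seed)
  if (groups < 1 || per_group < 1) stop("groups and per_group must be >= 1")
  m <- groups * per_group
  centers <- matrix(0, groups, n)
  centers[, 1] <- separation * (seq_len(groups) - 1)
  if (n > 1) centers[, -1] <- stats::rnorm(groups * (n - 1), sd = separation / 10)
  mu <- matrix(0, m, n)
  var <- matrix(0, m, n)
  part <- integer(m)
  k <- 0
  for (g in seq_len(groups)) {
    # members of a group are near-duplicates: a shared base variance with
    # small multiplicative jitter, and means jittered around the center
    base_var <- exp(stats::runif(n, log(0.5), log(2)))
    for (j in seq_len(per_group)) {
      k <- k + 1
      mu[k, ] <- centers[g, ] + stats::rnorm(n, sd = separation / 20)
      var[k, ] <- base_var * exp(stats::rnorm(n, sd = 0.1))
      part[k] <- g
    }
  }
  w <- stats::runif(m, 0.5, 1.5)
  f <- fr_dgmm(w / sum(w), mu, var)
  attr(f, "partition") <- part
  f
}

#' Synthetic RGB image drawn from a 3-dimensional mixture
#'
#' Samples each pixel independently from the mixture and clips the channels
#' to [0, 255]; the true component labels are returned for segmentation
#' scoring.
#'
#' @param width,height Image size in pixels.
#' @param dgmm An `fr_dgmm` of dimension 3 (RGB).
#' @param seed Optional integer seed.
#' @return A list with `pixels` (height*width x 3 matrix, rows in raster
#'   order), `labels` (true component per pixel), `width`, `height`.
#' @export
make_synthetic_image <- function(width, height, dgmm, seed = NULL) {
  if (ncol(dgmm$mu) != 3) stop("image mixtures must be 3-dimensional (RGB)")
  s <- dgmm_sample(dgmm, width * height, seed)
  px <- pmin(pmax(s$x, 0), 255)
  list(pixels = px, labels = s$component, width = width, height = height)
}
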