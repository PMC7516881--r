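# Shared fixtures built in code.

# Bivariate pair sharing the covariance [[1.1, 0.9], [0.9, 1.1]] with means
# (-1, 0) and (6, 3); its exact distance has a known closed form.
example_common_sigma_pair <- function() {
  S <- matrix(c(1.1, 0.9, 0.9, 1.1), 2, 2)
  list(fr_gaussian(c(-1, 0), S), fr_gaussian(c(6, 3), S))
}

# First covariance of the reference mirrored family.
mirrored_sigma1 <- function() matrix(c(0.55, -0.45, -0.45, 0.55), 2, 2)

# Reference mirrored pair at mean separation `sep`.
mirrored_pair_ref <- function(sep) {
  make_mirrored_pair(2, separation = sep, sigma1 = mirrored_sigma1())
}

# Random Gaussian with eigenvalues in a moderate range.
random_gaussian <- function(n, seed = NULL, mean_sd = 1, eig_range = c(0.5, 2)) {
  S <- random_spd(n, seed, eig_range)
  fr_gaussian(stats::rnorm(n, sd = mean_sd), S)
}

# Random orthogonal matrix.
random_orthogonal <- function(n) qr.Q(qr(matrix(stats::rnorm(n * n), n, n)))
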