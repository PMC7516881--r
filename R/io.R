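# JSON interchange for Gaussian parameters and diagonal mixtures.
# Gaussian schema: {"mu": [..], "sigma": [[..], [..]]} (row-major matrix).
# DGMM schema: {"weights": [..], "components": [{"mu": [..],
# "sigma_diag": [..]}, ...]} with sigma_diag the covariance diagonal
# (variances).

#' Read / write Gaussian parameters as JSON
#'
#' @param path File path.
#' @return `read_gaussian` returns an `fr_gaussian`.
#' @export
read_gaussian <- function(path) {
  j <- jsonlite::fromJSON(path)
  sigma <- j$sigma
  if (!is.matrix(sigma)) sigma <- matrix(unlist(sigma), length(j$mu), byrow = TRUE)
  fr_gaussian(j$mu, sigma)
}

#' @rdname read_gaussian
#' @param theta An `fr_gaussian`.
#' @export
write_gaussian <- function(theta, path) {
  stopifnot(inherits(theta, "fr_gaussian"))
  jsonlite::write_json(list(mu = theta$mu, sigma = theta$sigma), path,
                       digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' Read / write diagonal Gaussian mixtures as JSON
#'
#' @param path File path.
#' @return `read_dgmm` returns an `fr_dgmm`.
#' @export
read_dgmm <- function(path) {
  j <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  mu <- do.call(rbind, lapply(j$components, function(cc) as.numeric(cc$mu)))
  var <- do.call(rbind, lapply(j$components, function(cc) as.numeric(cc$sigma_diag)))
  fr_dgmm(as.numeric(j$weights), mu, var)
}

#' @rdname read_dgmm
#' @param f An `fr_dgmm`.
#' @export
write_dgmm <- function(f, path) {
  stopifnot(inherits(f, "fr_dgmm"))
  comps <- lapply(seq_len(nrow(f$mu)), function(k) {
    list(mu = f$mu[k, ], sigma_diag = f$var[k, ])
  })
  jsonlite::write_json(list(weights = f$weights, components = comps), path,
                       digits = NA, auto_unbox = FALSE)
  invisible(path)
}
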