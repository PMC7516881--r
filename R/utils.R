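# Internal numerical helpers shared across the package.

# Symmetrize a square matrix (averages away round-off asymmetry).
sym <- function(S) (S + t(S)) / 2

# Half-vectorization of a symmetric matrix (column-major upper triangle
# including the diagonal) and its inverse.
vech <- function(S) S[upper.tri(S, diag = TRUE)]

unvech <- function(v, n) {
  S <- matrix(0, n, n)
  S[upper.tri(S, diag = TRUE)] <- v
  S <- S + t(S)
  diag(S) <- diag(S) / 2
  S
}

# Frobenius norm.
fnorm <- function(S) sqrt(sum(S^2))

is_square <- function(S) is.matrix(S) && nrow(S) == ncol(S)

# Damped (line-searched) Newton iteration for a square non-linear system.
# `fn` maps the unknown vector to the residual vector (same length);
# `feasible` guards the line search (e.g. positivity constraints).
# The Jacobian is formed by forward finite differences.
damped_newton <- function(fn, u0, feasible = function(u) TRUE,
                          tol = 1e-12, maxit = 100L) {
  u <- u0
  p <- length(u0)
  r <- fn(u)
  nr <- sqrt(sum(r^2))
  for (it in seq_len(maxit)) {
    if (!is.finite(nr)) break
    if (nr < tol) break
    J <- matrix(0, length(r), p)
    for (j in seq_len(p)) {
      h <- 1e-7 * max(1, abs(u[j]))
      up <- u
      up[j] <- u[j] + h
      J[, j] <- (fn(up) - r) / h
    }
    du <- tryCatch(solve(J, -r), error = function(e) NULL)
    if (is.null(du) || any(!is.finite(du))) break
    step <- 1
    improved <- FALSE
    while (step > 1e-10) {
      un <- u + step * du
      if (feasible(un)) {
        rn <- fn(un)
        nrn <- sqrt(sum(rn^2))
        if (is.finite(nrn) && nrn < nr) {
          u <- un; r <- rn; nr <- nrn
          improved <- TRUE
          break
        }
      }
      step <- step / 2
    }
    if (!improved) break
  }
  list(u = u, residual = nr, converged = is.finite(nr) && nr < tol)
}

# Householder-style orthogonal matrix P with P v = |v| e1.
# Sign-stable: when v is already along +e1 returns the identity.
householder_to_e1 <- function(v) {
  n <- length(v)
  nv <- sqrt(sum(v^2))
  if (nv == 0) return(diag(n))
  u <- v / nv
  e1 <- c(1, rep(0, n - 1))
  if (abs(u[1] - 1) < 1e-14) return(diag(n))
  w <- u - e1
  w <- w / sqrt(sum(w^2))
  diag(n) - 2 * outer(w, w)
}
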