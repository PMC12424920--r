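# Shared fixtures and independent oracles used across test files.

# Random centered pair of plain matrices (not a case_control_pair), for
# exercising the linear-algebra layer directly.
random_centered_pair <- function(m, n1, n0, seed) {
  set.seed(seed)
  X <- matrix(rnorm(m * n1), m, n1)
  Y <- matrix(rnorm(m * n0), m, n0)
  list(X = X - rowMeans(X), Y = Y - rowMeans(Y))
}

# Labeled random case/control pair with no latent structure.
random_pair <- function(m, n1, n0, seed) {
  set.seed(seed)
  X <- matrix(rnorm(m * n1), m, n1,
              dimnames = list(sprintf("f%03d", 1:m), sprintf("case_%02d", 1:n1)))
  Y <- matrix(rnorm(m * n0), m, n0,
              dimnames = list(sprintf("f%03d", 1:m), sprintf("ctrl_%02d", 1:n0)))
  case_control_pair(X, Y)
}

# Independent CCA oracle: form S_XX^-1 S_XY S_YY^-1 S_YX explicitly and
# eigendecompose the (non-symmetric) product. Returns canonical
# correlations and an orthonormal basis for span(X a_1..a_r).
cca_eigen_oracle <- function(X, Y, r, ridge_x = NULL, ridge_y = NULL) {
  Sxx <- crossprod(X)
  Syy <- crossprod(Y)
  if (is.null(ridge_x)) ridge_x <- 1e-8 * mean(diag(Sxx))
  if (is.null(ridge_y)) ridge_y <- 1e-8 * mean(diag(Syy))
  Sxx <- Sxx + diag(ridge_x, ncol(X))
  Syy <- Syy + diag(ridge_y, ncol(Y))
  Sxy <- crossprod(X, Y)
  M <- solve(Sxx, Sxy) %*% solve(Syy, t(Sxy))
  ev <- eigen(M)
  ord <- order(Re(ev$values), decreasing = TRUE)
  cors <- sqrt(pmax(Re(ev$values)[ord], 0))[seq_len(r)]
  A <- Re(ev$vectors)[, ord[seq_len(r)], drop = FALSE]
  U <- qr.Q(qr(X %*% A))
  list(cors = cors, U = U)
}

# Default A1-style simulation settings (dominant shared, subtle case
# signal); small variants are derived from this in individual tests.
a1_config <- function(seed, k1 = 1L, m = 2000L, n1 = 150L, n0 = 150L,
                      shared_scales = 5, case_scales = 2) {
  simulation_config(m = m, n1 = n1, n0 = n0, k0 = 5L, k1 = k1,
                    sigma = 1, shared_scales = shared_scales,
                    case_scales = case_scales, seed = seed)
}

principal_angles_est <- function(A, B) {
  s <- svd(crossprod(qr.Q(qr(A)), qr.Q(qr(B))), nu = 0, nv = 0)$d
  acos(pmin(pmax(s, -1), 1))
}

expect_orthonormal <- function(U, tol = 1e-8) {
  if (ncol(U) == 0L) return(invisible(TRUE))
  expect_lt(max(abs(crossprod(U) - diag(ncol(U)))), tol)
}
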