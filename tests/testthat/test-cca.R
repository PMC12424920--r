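test_that("canonical correlations and spans match the dense eigen oracle", {
  # fixed small instance at tight tolerance
  p <- random_centered_pair(10, 4, 3, seed = 7)
  b <- fit_shared_cca(p$X, p$Y, r = 2)
  oracle <- cca_eigen_oracle(p$X, p$Y, r = 2)
  expect_equal(b$canonical_correlations, oracle$cors, tolerance = 1e-10)
  expect_lt(max(principal_angles_est(b$U0, oracle$U)), 1e-8)

  # property: random instances m <= 20, n <= 8
  set.seed(11)
  for (case in 1:20) {
    m <- sample(8:20, 1); n1 <- sample(3:8, 1); n0 <- sample(3:8, 1)
    p <- random_centered_pair(m, n1, n0, seed = 100 + case)
    r <- min(n0, n1) - 1L
    b <- fit_shared_cca(p$X, p$Y, r = r)
    oracle <- cca_eigen_oracle(p$X, p$Y, r = r)
    expect_equal(b$canonical_correlations, oracle$cors, tolerance = 1e-8)
    expect_lt(max(principal_angles_est(b$U0, oracle$U)), 1e-6)
  }
})

test_that("identical case and control matrices give perfect correlations on the top PCs", {
  p <- random_centered_pair(15, 5, 5, seed = 3)
  b <- fit_shared_cca(p$X, p$X, r = 3)
  expect_equal(b$canonical_correlations, rep(1, 3), tolerance = 1e-6)
  sv <- svd(p$X)
  expect_lt(max(principal_angles_est(b$U0, sv$u[, 1:3])), 1e-6)
})

test_that("shared rank-1 factor with small noise is recovered", {
  set.seed(21)
  m <- 400; n1 <- 30; n0 <- 25
  w <- rnorm(m); w <- w / sqrt(sum(w^2))
  X <- w %*% t(rnorm(n1, sd = 10 * sqrt(m))) + matrix(rnorm(m * n1), m, n1)
  Y <- w %*% t(rnorm(n0, sd = 10 * sqrt(m))) + matrix(rnorm(m * n0), m, n0)
  X <- X - rowMeans(X); Y <- Y - rowMeans(Y)
  b <- fit_shared_cca(X, Y, r = 1)
  expect_gt(b$canonical_correlations[1], 0.95)
  expect_gt(abs(cor(b$U0[, 1], w)), 0.95)
})

test_that("preconditions and the singular-Gram error are enforced", {
  p <- random_centered_pair(10, 4, 3, seed = 9)
  expect_error(fit_shared_cca(p$X, p$Y, r = 3), "exceeds min\\(n0, n1\\) - 1")
  wide <- random_centered_pair(4, 6, 5, seed = 9)
  expect_error(fit_shared_cca(wide$X, wide$Y, r = 1), "fit_rpaca")
  # centered Gram matrices are singular: ridge = 0 must error with advice
  expect_error(fit_shared_cca(p$X, p$Y, r = 2, ridge = 0), "positive ridge")
})

test_that("U0 is orthonormal and the sign convention is deterministic", {
  p <- random_centered_pair(18, 6, 6, seed = 5)
  b <- fit_shared_cca(p$X, p$Y, r = 4)
  expect_orthonormal(b$U0, tol = 1e-8)
  for (j in 1:4) {
    col <- b$U0[, j]
    expect_gt(col[which.max(abs(col))], 0)
  }
  b2 <- fit_shared_cca(p$X, p$Y, r = 4)
  expect_identical(b$U0, b2$U0)
})

test_that("remove_shared projects exactly and idempotently", {
  p <- random_centered_pair(12, 5, 4, seed = 13)
  b <- fit_shared_cca(p$X, p$Y, r = 2)
  Xr <- remove_shared(p$X, b)
  expect_lt(max(abs(crossprod(b$U0, Xr))), 1e-10)
  expect_lt(max(abs(remove_shared(Xr, b) - Xr)), 1e-10)

  # r = 0 is a no-op
  b0 <- fit_shared_cca(p$X, p$Y, r = 0)
  expect_identical(remove_shared(p$X, b0), p$X)

  # complete projection: U0 spanning the full column space kills X
  sv <- svd(p$X)
  full <- structure(list(U0 = sv$u[, 1:4], r = 4L,
                         canonical_correlations = rep(1, 4)),
                    class = "shared_basis")
  expect_lt(max(abs(remove_shared(p$X, full))), 1e-10)

  # removing the top left singular vector leaves sigma_2 on top
  b1 <- structure(list(U0 = sv$u[, 1, drop = FALSE], r = 1L,
                       canonical_correlations = 1), class = "shared_basis")
  expect_equal(svd(remove_shared(p$X, b1))$d[1], sv$d[2], tolerance = 1e-10)

  expect_error(remove_shared(p$X[1:6, ], b), "features")
})

test_that("scale equivariance: a global positive factor changes nothing structural", {
  p <- random_centered_pair(20, 6, 5, seed = 17)
  b1 <- fit_shared_cca(p$X, p$Y, r = 3)
  b2 <- fit_shared_cca(7.3 * p$X, 7.3 * p$Y, r = 3)
  expect_equal(b1$canonical_correlations, b2$canonical_correlations,
               tolerance = 1e-8)
  expect_equal(b1$U0, b2$U0, tolerance = 1e-8)
})
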