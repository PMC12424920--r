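test_that("r = 0 reduces to plain PCA of the centered case matrix", {
  pair <- random_pair(30, 8, 7, seed = 2)
  fit <- fit_paca(pair, r = 0, k1 = 3)
  Xc <- unclass(pair$X) - rowMeans(pair$X)
  sv <- svd(Xc)
  expect_equal(fit$singular_values, sv$d[1:3], tolerance = 1e-10)
  for (j in 1:3) {
    expect_equal(abs(sum(fit$feature_loadings[, j] * sv$u[, j])), 1,
                 tolerance = 1e-8)
    expect_equal(abs(cor(fit$case_scores[, j], sv$v[, j])), 1,
                 tolerance = 1e-8)
  }
})

test_that("fit invariants: orthonormal loadings, orthogonal to removed directions", {
  sim <- simulate_case_control(simulation_config(
    m = 500, n1 = 40, n0 = 35, k0 = 3, k1 = 2, seed = 31))
  fit <- fit_paca(sim$pair, r = 3, k1 = 2)
  expect_orthonormal(fit$feature_loadings, tol = 1e-8)
  expect_orthonormal(fit$shared_basis$U0, tol = 1e-8)
  expect_lt(max(abs(crossprod(fit$shared_basis$U0, fit$feature_loadings))), 1e-6)
  expect_true(all(diff(fit$singular_values) <= 0))
  expect_true(all(fit$singular_values >= 0))
  # sign convention: largest-|.| loading entry positive, deterministic refit
  for (j in 1:2) {
    col <- fit$feature_loadings[, j]
    expect_gt(col[which.max(abs(col))], 0)
  }
  expect_identical(fit$feature_loadings,
                   fit_paca(sim$pair, r = 3, k1 = 2)$feature_loadings)
})

test_that("case factors are recovered once shared variation is removed", {
  sim <- simulate_case_control(simulation_config(
    m = 800, n1 = 60, n0 = 60, k0 = 4, k1 = 1, shared_scales = 5,
    case_scales = 2, seed = 33))
  fit <- fit_paca(sim$pair, r = 4, k1 = 1)
  rec <- recovery_score(fit, sim$truth)
  expect_gt(rec$mean_abs_cor, 0.9)
  # without removal the dominant shared factors mask the case signal
  pca <- fit_paca(sim$pair, r = 0, k1 = 1)
  expect_lt(recovery_score(pca, sim$truth)$mean_abs_cor,
            rec$mean_abs_cor - 0.15)
})

test_that("scale equivariance of the full fit", {
  pair <- random_pair(60, 10, 9, seed = 4)
  f1 <- fit_paca(pair, r = 2, k1 = 2)
  pair2 <- case_control_pair(unclass(pair$X) * 3.7, unclass(pair$Y) * 3.7)
  f2 <- fit_paca(pair2, r = 2, k1 = 2)
  expect_equal(f1$shared_basis$canonical_correlations,
               f2$shared_basis$canonical_correlations, tolerance = 1e-8)
  expect_equal(f1$feature_loadings, f2$feature_loadings, tolerance = 1e-8)
  n1 <- function(M) sweep(M, 2, sqrt(colSums(M^2)), "/")
  expect_equal(n1(f1$case_scores), n1(f2$case_scores), tolerance = 1e-8)
})

test_that("degenerate rank-deficient cases are flagged", {
  set.seed(6)
  x <- rnorm(20)
  X <- matrix(x, 20, 6)  # identical case columns: centered X is exactly 0
  Y <- matrix(rnorm(20 * 5), 20, 5)
  rownames(X) <- rownames(Y) <- sprintf("f%02d", 1:20)
  colnames(X) <- paste0("c", 1:6); colnames(Y) <- paste0("k", 1:5)
  pair <- case_control_pair(X, Y)
  expect_warning(fit <- fit_paca(pair, r = 0, k1 = 1), "degenerate")
  expect_lt(fit$singular_values[1], 1e-12)
})

test_that("recovery is non-decreasing in the case-specific signal scale", {
  scales <- c(0.5, 1.5, 3)
  med <- vapply(seq_along(scales), function(s) {
    rec <- vapply(1:20, function(rep) {
      sim <- simulate_case_control(simulation_config(
        m = 400, n1 = 50, n0 = 50, k0 = 3, k1 = 1, shared_scales = 5,
        case_scales = scales[s], sigma = 1, seed = 7000 + 100 * s + rep))
      fit <- fit_paca(sim$pair, r = 3, k1 = 1)
      recovery_score(fit, sim$truth)$mean_abs_cor
    }, numeric(1))
    median(rec)
  }, numeric(1))
  expect_true(all(diff(med) >= 0))
})

test_that("auto-selected r flows through fit_paca", {
  sim <- simulate_case_control(simulation_config(
    m = 600, n1 = 50, n0 = 50, k0 = 2, k1 = 1, seed = 41))
  fit <- fit_paca(sim$pair, r = "auto", k1 = 1,
                  dim_args = list(r_max = 5, n_permutations = 49, seed = 99))
  expect_s3_class(fit$dim_selection, "dim_selection")
  expect_identical(fit$r, fit$dim_selection$chosen_r)
  expect_gt(recovery_score(fit, sim$truth)$mean_abs_cor, 0.9)
})
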