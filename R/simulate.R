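#' Configuration for the case/control generator
#'
#' Describes a low-rank factor model with known ground truth: both groups
#' share `k0` orthonormal feature-space directions `W0`, cases carry `k1`
#' additional directions `W1` orthogonal to `W0` (unless
#' `orthogonality_violation > 0`), and isotropic Gaussian noise with
#' standard deviation `sigma` is added entry-wise.
#'
#' Component scales are per-entry signal standard deviations in the same
#' units as `sigma`: a component with scale `s` contributes `s^2` to the
#' variance of every matrix entry on average (the individual-level factor
#' rows are drawn with SD `s * sqrt(m)` on unit-norm directions). Defaults
#' follow the dominant-shared / subtle-case regime: shared components at
#' `5*sigma`, case-specific at `2*sigma`.
#'
#' @param m,n1,n0 features, case samples, control samples. `m` must exceed
#'   `max(n0, n1)` unless `rpaca_regime = TRUE`.
#' @param k0 number of shared components.
#' @param k1 number of case-specific components (0 for a null dataset).
#' @param sigma noise standard deviation (default 1).
#' @param shared_scales per-entry SD of each shared component (recycled to
#'   length `k0`; default 5).
#' @param case_scales per-entry SD of each case component (recycled to
#'   length `k1`; default 2).
#' @param orthogonality_violation cosine in `[0, 1)` between each case
#'   direction and the shared subspace (0 = exactly orthogonal; requires
#'   `k1 <= k0` when positive).
#' @param rpaca_regime allow `m <= max(n0, n1)` (for [fit_rpaca()]).
#' @param seed integer; identical seeds give bit-identical datasets.
#' @return a validated `simulation_config` list.
#' @export
simulation_config <- function(m, n1, n0, k0, k1 = 1L, sigma = 1,
                              shared_scales = 5, case_scales = 2,
                              orthogonality_violation = 0,
                              rpaca_regime = FALSE, seed = NULL) {
  m <- .assert_count(m, "m", 2L)
  n1 <- .assert_count(n1, "n1", 2L)
  n0 <- .assert_count(n0, "n0", 2L)
  k0 <- .assert_count(k0, "k0")
  k1 <- .assert_count(k1, "k1")
  if (!rpaca_regime && m <= max(n0, n1)) {
    .stopf(paste0("m = %d must exceed max(n0, n1) = %d ",
                  "(set rpaca_regime = TRUE for the wide regime)"),
           m, max(n0, n1))
  }
  if (k0 + k1 > min(m, n1)) .stopf("k0 + k1 too large for m = %d, n1 = %d", m, n1)
  if (sigma < 0) .stopf("sigma must be non-negative")
  shared_scales <- rep_len(as.numeric(shared_scales), k0)
  case_scales <- rep_len(as.numeric(case_scales), k1)
  if (any(shared_scales <= 0) || any(case_scales <= 0)) {
    .stopf("component scales must be positive")
  }
  if (orthogonality_violation < 0 || orthogonality_violation >= 1) {
    .stopf("orthogonality_violation must be in [0, 1)")
  }
  if (orthogonality_violation > 0 && k1 > k0) {
    .stopf("orthogonality_violation > 0 requires k1 <= k0")
  }
  structure(list(m = m, n1 = n1, n0 = n0, k0 = k0, k1 = k1, sigma = sigma,
                 shared_scales = shared_scales, case_scales = case_scales,
                 orthogonality_violation = orthogonality_violation,
                 rpaca_regime = isTRUE(rpaca_regime),
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "simulation_config")
}

#' Generate a case/control dataset with known ground truth
#'
#' Draws `W0` as an orthonormalized Gaussian matrix, `W1` orthonormal
#' within the orthogonal complement of `W0` (then tilted toward the shared
#' subspace when the violation knob is positive), individual-level factors
#' with the configured per-entry scales, and adds isotropic noise:
#' `X = W0 Z_X0 + W1 Z_X1 + E_X`, `Y = W0 Z_Y0 + E_Y`.
#'
#' @param config a [simulation_config()].
#' @param basis optional `simulation_truth` (or list with `W0`, `W1`) whose
#'   feature-space directions are reused, for generating replication
#'   cohorts that share the latent structure of a discovery cohort.
#' @return list with `pair` (a [case_control_pair()]) and `truth`
#'   (`simulation_truth`: `W0`, `W1`, `Z_X0`, `Z_Y0`, `Z_X1`, `sigma`,
#'   `shared_scales`, `case_scales`, `seed`).
#' @examples
#' sim <- simulate_case_control(simulation_config(
#'   m = 200, n1 = 20, n0 = 20, k0 = 2, k1 = 1, seed = 7))
#' sim$pair
#' @export
simulate_case_control <- function(config, basis = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  .with_seed(config$seed, .simulate_impl(config, basis))
}

.simulate_impl <- function(cf, basis) {
  m <- cf$m; n1 <- cf$n1; n0 <- cf$n0; k0 <- cf$k0; k1 <- cf$k1
  if (is.null(basis)) {
    W0 <- .random_orthonormal(m, k0)
    W1 <- .complement_orthonormal(m, k1, W0)
    v <- cf$orthogonality_violation
    if (v > 0 && k1 > 0L) {
      # tilt each case direction toward a distinct shared direction so the
      # cosine to span(W0) equals v while W1 stays orthonormal
      W1 <- sqrt(1 - v^2) * W1 + v * W0[, seq_len(k1), drop = FALSE]
    }
  } else {
    W0 <- basis$W0
    W1 <- basis$W1
    stopifnot(nrow(W0) == m, ncol(W0) == k0, ncol(W1) == k1)
  }
  Z_X0 <- matrix(stats::rnorm(k0 * n1, sd = rep(cf$shared_scales * sqrt(m), n1)), k0, n1)
  Z_Y0 <- matrix(stats::rnorm(k0 * n0, sd = rep(cf$shared_scales * sqrt(m), n0)), k0, n0)
  Z_X1 <- matrix(stats::rnorm(k1 * n1, sd = rep(cf$case_scales * sqrt(m), n1)), k1, n1)
  E_X <- matrix(stats::rnorm(m * n1, sd = cf$sigma), m, n1)
  E_Y <- matrix(stats::rnorm(m * n0, sd = cf$sigma), m, n0)
  X <- W0 %*% Z_X0 + E_X
  if (k1 > 0L) X <- X + W1 %*% Z_X1
  Y <- W0 %*% Z_Y0 + E_Y
  fid <- sprintf("f%05d", seq_len(m))
  dimnames(X) <- list(fid, sprintf("case_%03d", seq_len(n1)))
  dimnames(Y) <- list(fid, sprintf("control_%03d", seq_len(n0)))
  truth <- structure(list(
    W0 = W0, W1 = W1, Z_X0 = Z_X0, Z_Y0 = Z_Y0, Z_X1 = Z_X1,
    sigma = cf$sigma, shared_scales = cf$shared_scales,
    case_scales = cf$case_scales, k0 = k0, k1 = k1,
    seed = cf$seed
  ), class = "simulation_truth")
  list(pair = case_control_pair(X, Y), truth = truth)
}

# Orthonormal m x k matrix in the orthogonal complement of span(W0).
.complement_orthonormal <- function(m, k, W0) {
  if (k == 0L) return(matrix(0, m, 0L))
  G <- matrix(stats::rnorm(m * k), m, k)
  if (ncol(W0) > 0L) G <- G - W0 %*% crossprod(W0, G)
  qr_G <- qr(G)
  Q <- qr.Q(qr_G)
  d <- sign(diag(qr.R(qr_G)))
  d[d == 0] <- 1
  sweep(Q, 2L, d, `*`)
}

#' Score recovery of the simulated case-specific factors
#'
#' Compares estimated component scores against the true case factors
#' `Z_X1` by absolute Pearson correlation under a greedy best-match
#' assignment (components and truth rows are defined up to order and
#' sign), and reports the principal angles between the estimated shared
#' subspace and `span(W0)` when the fit carries one.
#'
#' @param fit a `paca_fit`, a `cpca_result`, or a scores matrix
#'   (samples x components).
#' @param truth a `simulation_truth` with `k1 >= 1`.
#' @return list with `matches` (data.frame: `component`,
#'   `truth_component`, `abs_cor`), `mean_abs_cor`, and
#'   `shared_angles` (radians; `NULL` when no shared basis is available).
#' @export
recovery_score <- function(fit, truth) {
  stopifnot(inherits(truth, "simulation_truth"))
  if (truth$k1 < 1L) .stopf("truth has no case-specific factors (k1 = 0)")
  scores <- if (is.matrix(fit)) fit else fit$case_scores
  if (is.null(scores)) .stopf("`fit` carries no case scores")
  Zt <- t(truth$Z_X1)  # n1 x k1
  if (nrow(scores) != nrow(Zt)) {
    .stopf("score rows (%d) != simulated case samples (%d)",
           nrow(scores), nrow(Zt))
  }
  C <- abs(stats::cor(scores, Zt))
  k <- min(ncol(scores), ncol(Zt))
  matches <- data.frame(component = integer(k), truth_component = integer(k),
                        abs_cor = numeric(k))
  Cw <- C
  for (i in seq_len(k)) {
    ij <- arrayInd(which.max(Cw), dim(Cw))
    matches$component[i] <- ij[1L]
    matches$truth_component[i] <- ij[2L]
    matches$abs_cor[i] <- C[ij[1L], ij[2L]]
    Cw[ij[1L], ] <- -Inf
    Cw[, ij[2L]] <- -Inf
  }
  angles <- NULL
  if (!is.matrix(fit) && !is.null(fit$shared_basis) && fit$shared_basis$r > 0L) {
    angles <- .principal_angles(fit$shared_basis$U0, truth$W0)
  }
  list(matches = matches[order(matches$component), , drop = FALSE],
       mean_abs_cor = mean(matches$abs_cor),
       shared_angles = angles)
}
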