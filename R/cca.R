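# Sample-space canonical correlation analysis.
#
# Classical CCA correlates linear combinations of *features* across two
# datasets measured on the same samples. Here the roles are transposed: the
# two groups share features but not samples, and we seek linear combinations
# of *samples* -- i.e. directions u = X a in feature space -- maximizing
# a' X'Y b subject to ||Xa|| = ||Yb|| = 1. Successive directions are
# constrained orthogonal to their predecessors. The constraint (Gram)
# matrices are S_XX = X'X and S_YY = Y'Y in sample space, which is why the
# method needs more features than samples (m > max(n0, n1)); see
# [fit_rpaca()] for the opposite regime.
#
# Numerically we whiten: with S_XX + ridge*I = Rx'Rx and S_YY + ridge*I =
# Ry'Ry (Cholesky), the singular vectors of K = Rx^-T S_XY Ry^-1 give the
# canonical coefficients a = Rx^-1 u_K, b = Ry^-1 v_K and the singular
# values the canonical correlations -- equivalent to eigendecomposing
# S_XX^-1 S_XY S_YY^-1 S_YX but stable. Per-group row-centering makes S_XX
# exactly singular (centered columns sum to zero), so a positive ridge is
# required; the centered cross-Gram vanishes along the same null direction,
# so the ridge introduces no spurious correlation.

.default_ridge <- function(G) 1e-8 * mean(diag(G))

# Core solver on Gram matrices only (no m-dimensional object touched), so
# the permutation scheme can run entirely in sample space.
# Returns coefficients A (n1 x r) re-orthonormalized in the exact
# (ridge-free) Gxx metric, so u_j = X a_j are orthonormal, plus B and the
# canonical correlations.
.cca_core <- function(Gxx, Gyy, Gxy, r, ridge_x, ridge_y) {
  n1 <- nrow(Gxx)
  n0 <- nrow(Gyy)
  if (r == 0L) {
    return(list(A = matrix(0, n1, 0L), B = matrix(0, n0, 0L),
                cors = numeric(0)))
  }
  Rx <- .chol_or_advise(Gxx, ridge_x, "S_XX")
  Ry <- .chol_or_advise(Gyy, ridge_y, "S_YY")
  K <- backsolve(Rx, Gxy, transpose = TRUE)
  K <- t(backsolve(Ry, t(K), transpose = TRUE))
  sv <- svd(K, nu = r, nv = r)
  cors <- pmin(pmax(sv$d[seq_len(r)], 0), 1)
  A <- backsolve(Rx, sv$u)
  B <- backsolve(Ry, sv$v)
  # Gram-Schmidt in the Gxx metric (triangular correction preserves the
  # sequential structure): exact ||X a_j|| = 1 and mutual orthogonality.
  A <- .metric_orthonormalize(A, Gxx)
  B <- .metric_orthonormalize(B, Gyy)
  list(A = A, B = B, cors = cors)
}

.chol_or_advise <- function(G, ridge, label) {
  Greg <- G
  if (ridge > 0) Greg <- Greg + diag(ridge, nrow(G))
  out <- tryCatch(chol(Greg), error = function(e) e)
  if (inherits(out, "error")) {
    .stopf(paste0("constraint matrix %s is singular (centered Gram matrices ",
                  "always are); use a positive ridge"), label)
  }
  out
}

.metric_orthonormalize <- function(A, G) {
  if (ncol(A) == 0L) return(A)
  M <- crossprod(A, G %*% A)
  M <- (M + t(M)) / 2
  R <- tryCatch(chol(M), error = function(e) NULL)
  if (is.null(R)) {
    # near-degenerate trailing directions: symmetric eigen-whitening
    # (loses the triangular/nested structure, but only when the requested
    # directions already hit the numerical rank of the data)
    e <- eigen(M, symmetric = TRUE)
    lam <- pmax(e$values, max(e$values) * 1e-12)
    return(A %*% e$vectors %*% (t(e$vectors) / sqrt(lam)))
  }
  t(backsolve(R, t(A), transpose = TRUE))
}

#' Estimate shared directions of variation by sample-space CCA
#'
#' Finds `r` feature-space directions `u_j = X a_j` that are maximally
#' correlated between the (centered) case matrix `X` and control matrix `Y`,
#' i.e. the strongest sources of variation shared by the two groups (cell
#' composition, batch, ancestry, ...). Direction `j` maximizes
#' `a' X' Y b` subject to `||Xa|| = ||Yb|| = 1` and orthogonality of `u_j`
#' to `u_1 .. u_{j-1}`.
#'
#' @param X centered case matrix (m x n1), features as rows.
#' @param Y centered control matrix (m x n0), same features.
#' @param r number of canonical directions to extract
#'   (`0 <= r <= min(n0, n1) - 1`).
#' @param ridge non-negative regularizer added to the sample-space Gram
#'   matrices `X'X` and `Y'Y`. The default `NULL` uses
#'   `1e-8 * trace(S)/n` per matrix; per-group centering makes the Gram
#'   matrices exactly singular, so `ridge = 0` errors.
#' @return a `shared_basis`: list with `U0` (m x r, orthonormal columns),
#'   `canonical_correlations` (non-increasing, in `[0,1]`), `r`,
#'   `a_coeffs` (n1 x r), `b_coeffs` (n0 x r).
#' @seealso [remove_shared()], [fit_paca()]
#' @export
fit_shared_cca <- function(X, Y, r, ridge = NULL) {
  X <- unclass(X); Y <- unclass(Y)
  m <- nrow(X); n1 <- ncol(X); n0 <- ncol(Y)
  if (nrow(Y) != m) .stopf("X and Y must have the same number of features")
  if (m <= max(n0, n1)) {
    .stopf(paste0("sample-space CCA needs more features than samples ",
                  "(m = %d, max group size = %d); use fit_rpaca() for the ",
                  "more-samples-than-features regime"), m, max(n0, n1))
  }
  r <- .assert_count(r, "r")
  if (r > min(n0, n1) - 1L) {
    .stopf("r = %d exceeds min(n0, n1) - 1 = %d", r, min(n0, n1) - 1L)
  }
  Gxx <- crossprod(X)
  Gyy <- crossprod(Y)
  Gxy <- crossprod(X, Y)
  ridge_x <- if (is.null(ridge)) .default_ridge(Gxx) else ridge
  ridge_y <- if (is.null(ridge)) .default_ridge(Gyy) else ridge
  core <- .cca_core(Gxx, Gyy, Gxy, r, ridge_x, ridge_y)
  U0 <- X %*% core$A
  fixed <- .fix_signs(U0, list(core$A, core$B))
  structure(list(
    U0 = fixed[[1L]],
    canonical_correlations = core$cors,
    r = r,
    a_coeffs = fixed[[2L]],
    b_coeffs = fixed[[3L]]
  ), class = "shared_basis")
}

#' @export
print.shared_basis <- function(x, ...) {
  cat(sprintf("<shared_basis> r = %d shared directions over %d features\n",
              x$r, nrow(x$U0)))
  if (x$r > 0L) {
    cat("canonical correlations:",
        paste(sprintf("%.4f", utils::head(x$canonical_correlations, 6L)),
              collapse = " "),
        if (x$r > 6L) "..." else "", "\n")
  }
  invisible(x)
}

#' Project shared variation out of the case matrix
#'
#' Removes the expected effect of the shared directions on `X` by orthogonal
#' projection: `X' = X - U0 U0' X`. Afterwards `U0' X'` is zero to numerical
#' tolerance, and the residual carries only case-specific structure plus
#' noise.
#'
#' @param X centered case matrix (m x n1).
#' @param basis a `shared_basis` from [fit_shared_cca()] with matching `m`.
#' @return the residual matrix, same dimensions and dimnames as `X`.
#' @export
remove_shared <- function(X, basis) {
  stopifnot(inherits(basis, "shared_basis"))
  if (nrow(basis$U0) != nrow(X)) {
    .stopf("basis has %d features but X has %d rows", nrow(basis$U0), nrow(X))
  }
  if (basis$r == 0L) return(X)
  X - basis$U0 %*% crossprod(basis$U0, X)
}
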