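#' Contrastive PCA baseline
#'
#' Eigendecomposes the contrast `C_X - alpha * C_Y` of the per-group
#' feature covariance matrices (1/(n-1) normalization, groups centered
#' internally). With `alpha = 0` this is plain PCA of the cases; large
#' `alpha` aggressively discounts any direction with control variance.
#' Unlike PACA, the contrastive hyperparameter must be tuned — a single
#' fixed `alpha` trades off background removal against signal retention,
#' which is the weakness the benchmark comparisons probe.
#'
#' When `m` exceeds the total sample count the eigendecomposition is done
#' through the n-dimensional dual (the contrast has rank at most
#' `n1 + n0 - 2`), so only the top `min(k, rank)` directions are
#' available in that regime.
#'
#' @param pair a [case_control_pair()].
#' @param alpha non-negative contrastive hyperparameter.
#' @param k number of components (`k <= m`).
#' @return a `cpca_result`: list with `alpha`, `loadings` (m x k,
#'   orthonormal), `case_scores` (n1 x k), `eigenvalues` (descending; may
#'   be negative), `k`.
#' @export
fit_cpca <- function(pair, alpha, k) {
  stopifnot(inherits(pair, "case_control_pair"))
  if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) || alpha < 0) {
    .stopf("alpha must be a single non-negative number")
  }
  d <- .pair_dims(pair)
  m <- d[["m"]]; n1 <- d[["n1"]]; n0 <- d[["n0"]]
  k <- .assert_count(k, "k", 1L)
  if (k > m) .stopf("k = %d exceeds the number of features m = %d", k, m)
  Xc <- unclass(pair$X) - rowMeans(pair$X)
  Yc <- unclass(pair$Y) - rowMeans(pair$Y)

  if (m <= n1 + n0) {
    M <- tcrossprod(Xc) / (n1 - 1L) - alpha * tcrossprod(Yc) / (n0 - 1L)
    e <- eigen((M + t(M)) / 2, symmetric = TRUE)
    loadings <- e$vectors[, seq_len(k), drop = FALSE]
    values <- e$values[seq_len(k)]
  } else {
    # dual: C_X - alpha*C_Y = Z D Z' with Z = [Xc, Yc]; eigenpairs from the
    # n x n symmetric problem B^(1/2) D B^(1/2), B = Z'Z, v = Z B^(-1/2) q
    Z <- cbind(Xc, Yc)
    dd <- c(rep(1 / (n1 - 1L), n1), rep(-alpha / (n0 - 1L), n0))
    B <- crossprod(Z)
    eB <- eigen((B + t(B)) / 2, symmetric = TRUE)
    pos <- eB$values > max(eB$values, 0) * 1e-12
    rank_B <- sum(pos)
    if (k > rank_B) {
      .stopf("k = %d exceeds the contrast rank %d in the dual regime", k, rank_B)
    }
    V <- eB$vectors[, pos, drop = FALSE]
    s <- sqrt(eB$values[pos])
    Bh <- sweep(V, 2L, s, `*`)              # B^(1/2) factor: Z'Z = (Bh)(Bh)' on range
    Mn <- crossprod(Bh, dd * Bh)            # B^(1/2) D B^(1/2) restricted to range(B)
    eM <- eigen((Mn + t(Mn)) / 2, symmetric = TRUE)
    idx <- seq_len(k)
    Q <- eM$vectors[, idx, drop = FALSE]
    values <- eM$values[idx]
    W <- V %*% (Q / s)                      # B^(-1/2) q in sample space
    loadings <- Z %*% W
  }
  scores <- crossprod(Xc, loadings)
  fixed <- .fix_signs(loadings, list(scores))
  loadings <- fixed[[1L]]; scores <- fixed[[2L]]
  rownames(loadings) <- rownames(pair$X)
  rownames(scores) <- colnames(pair$X)
  colnames(loadings) <- colnames(scores) <- paste0("cPC", seq_len(k))
  structure(list(alpha = alpha, loadings = loadings, case_scores = scores,
                 eigenvalues = values, k = k), class = "cpca_result")
}

#' @export
print.cpca_result <- function(x, ...) {
  cat(sprintf("<cpca_result> alpha = %g, k = %d components over %d features\n",
              x$alpha, x$k, nrow(x$loadings)))
  cat("eigenvalues:", paste(sprintf("%.3g", utils::head(x$eigenvalues, 6L)),
                            collapse = " "), "\n")
  invisible(x)
}
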