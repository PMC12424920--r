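#' Choose the number of shared directions by permutation
#'
#' Removing too few shared canonical directions leaves background variation
#' masquerading as case-specific signal; removing too many costs power. This
#' scheme scans `r = 0, 1, ..., r_max` and picks the minimal `r` at which
#' significant case-specific variation remains in the case residual.
#'
#' For each `r` the observed statistic is the top-eigenvalue share of the
#' case residual Gram matrix, `T_r = lambda_1 / sum(lambda)`, after removing
#' `r` CCA directions — the standard signal-detection statistic for a
#' low-rank-vs-noise alternative. The null distribution is built by pooling
#' all samples, randomly relabeling them into pseudo-case/pseudo-control
#' groups of the original sizes (labels are exchangeable when cases carry no
#' extra structure), and recomputing `T_r`. P-values use the add-one
#' permutation estimator `p_r = (1 + #{null >= observed}) / (1 + B)`, so the
#' smallest attainable p-value is `1/(B+1)`.
#'
#' Because `r_max + 1` correlated tests are scanned, declaring signal
#' whenever any single `p_r` clears `alpha` would inflate the family-wise
#' error well beyond `alpha`. Signal is therefore gated by a single
#' Westfall–Young-style max-statistic test: each scanned depth's statistic
#' is standardized against its own permutation distribution, and the
#' observed maximum standardized statistic is ranked within the
#' exchangeable ensemble of observed-plus-permuted maxima, giving one
#' calibrated global p-value `p_global`. If `p_global < alpha`, `chosen_r`
#' is the first `r` (scanned in increasing order) at which significance
#' persists — `p_r < alpha` at `r` and at `r + 1` (or at `r_max` alone) —
#' the minimal number of shared directions whose removal exposes
#' case-specific variation that remains visible as more directions are
#' removed. Requiring persistence keeps an isolated noise dip at an
#' intermediate `r` from truncating the scan early. If the gate fails, the
#' result is the no-signal sentinel (`chosen_r = NA`).
#'
#' The whole permutation loop runs in sample space from a single pooled
#' Gram matrix (group centering applied as a Gram-space correction), so its
#' cost per permutation is independent of the number of features.
#'
#' @param pair a [case_control_pair()], raw (uncentered) values.
#' @param r_max deepest `r` scanned; must satisfy
#'   `r_max <= min(n0, n1) - 2`. Default `min(min(n0, n1) - 2, 50)`.
#' @param n_permutations number of relabelings (minimum 19, for p-value
#'   resolution at alpha = 0.05). Default 100.
#' @param alpha significance level in (0, 1). Default 0.05.
#' @param seed integer seed for the relabelings; auto-drawn (and recorded)
#'   when `NULL`. Identical seeds give bit-identical results.
#' @param scale logical; per-group unit-variance scaling (slower: the
#'   Gram-space shortcut does not apply).
#' @param ridge see [fit_shared_cca()].
#' @return a `dim_selection`: list with `chosen_r` (integer, or `NA` for
#'   no-signal), `per_r_statistic`, `per_r_pvalue` (each of length
#'   `r_max + 1`, indexed `r0..`), `p_global` (family-wise min-p p-value),
#'   `r_max`, `n_permutations`, `alpha`, `seed`.
#' @export
select_shared_dim <- function(pair, r_max = NULL, n_permutations = 100L,
                              alpha = 0.05, seed = NULL, scale = FALSE,
                              ridge = NULL) {
  stopifnot(inherits(pair, "case_control_pair"))
  d <- .pair_dims(pair)
  n1 <- as.integer(d["n1"]); n0 <- as.integer(d["n0"])
  hard_max <- min(n0, n1) - 2L
  if (is.null(r_max)) r_max <- min(hard_max, 50L)
  r_max <- .assert_count(r_max, "r_max")
  if (r_max > hard_max) {
    .stopf("r_max = %d exceeds min(n0, n1) - 2 = %d", r_max, hard_max)
  }
  n_permutations <- .assert_count(n_permutations, "n_permutations")
  if (n_permutations < 19L) {
    .stopf("n_permutations must be >= 19 (p-value resolution); got %d",
           n_permutations)
  }
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    .stopf("alpha must be in (0, 1)")
  }
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1L)
  seed <- as.integer(seed)

  Z <- cbind(unclass(pair$X), unclass(pair$Y))
  N <- n1 + n0
  obs_idx <- seq_len(n1)

  if (isTRUE(scale)) {
    stat_fun <- function(I) .perm_stat_explicit(Z, I, r_max, ridge)
  } else {
    G <- crossprod(Z)
    stat_fun <- function(I) .perm_stat_gram(G, I, N, r_max, ridge)
  }

  observed <- stat_fun(obs_idx)
  null_stats <- .with_seed(seed, {
    vapply(seq_len(n_permutations), function(b) {
      stat_fun(sample.int(N, n1))
    }, numeric(r_max + 1L))
  })
  null_stats <- matrix(null_stats, nrow = r_max + 1L)

  # Per-r add-one p-values (self-inclusive rank of the observed statistic
  # within the exchangeable ensemble {observed, permutations}).
  ensemble <- cbind(observed, null_stats)
  pvals <- (1 + rowSums(null_stats >= observed)) / (1 + n_permutations)

  # Family-wise gate: max over r of the column-standardized statistic,
  # compared by rank within the ensemble (Westfall-Young style, with a
  # continuous standardization so the decision is not limited by the
  # 1/(B+1) p-value floor when several r's are scanned). Exact level under
  # exchangeability: the standardization treats all members symmetrically.
  mu <- rowMeans(ensemble)
  sdev <- apply(ensemble, 1L, stats::sd)
  sdev[sdev == 0] <- Inf  # constant column carries no evidence
  zmax <- apply((ensemble - mu) / sdev, 2L, max)
  p_global <- sum(zmax >= zmax[1L]) / (1 + n_permutations)

  # Minimal r at which significance *persists*: genuine case-specific
  # structure stays visible as further directions are removed, so we ask
  # for p_r < alpha at r and at r+1 (or at r_max alone); an isolated
  # spurious dip at an intermediate r cannot hijack the choice.
  chosen_r <- NA_integer_
  if (p_global < alpha) {
    sig <- pvals < alpha
    run_start <- which(sig & c(sig[-1L], TRUE))
    chosen_r <- if (length(run_start)) as.integer(run_start[1L] - 1L)
                else as.integer(which.min(pvals) - 1L)
  }

  names(observed) <- names(pvals) <- paste0("r", 0:r_max)
  structure(list(
    chosen_r = chosen_r,
    per_r_statistic = observed,
    per_r_pvalue = pvals,
    p_global = p_global,
    r_max = r_max,
    n_permutations = n_permutations,
    alpha = alpha,
    seed = seed
  ), class = "dim_selection")
}

#' @export
print.dim_selection <- function(x, ...) {
  if (is.na(x$chosen_r)) {
    cat(sprintf("<dim_selection> no-signal (family-wise p = %.4g)\n", x$p_global))
  } else {
    cat(sprintf("<dim_selection> chosen_r = %d (p = %.4g, family-wise p = %.4g)\n",
                x$chosen_r, x$per_r_pvalue[x$chosen_r + 1L], x$p_global))
  }
  cat(sprintf("scanned r = 0..%d, %d permutations, alpha = %g, seed = %d\n",
              x$r_max, x$n_permutations, x$alpha, x$seed))
  invisible(x)
}

# ---- internal statistic paths ---------------------------------------------

# T_r for r = 0..r_max from the pooled raw Gram matrix, with per-group
# centering applied in Gram space: for Xc = Xp - mu 1',
# Xc'Xc = G_II - d 1' - 1 d' + (mu'mu) 11' with d = rowSums(G_II)/n1, and
# the cross-Gram analogously.
.perm_stat_gram <- function(G, I, N, r_max, ridge) {
  J <- setdiff(seq_len(N), I)
  Gxx <- .center_gram(G[I, I, drop = FALSE])
  Gyy <- .center_gram(G[J, J, drop = FALSE])
  Gxy <- .center_gram_cross(G[I, J, drop = FALSE])
  .stat_scan(Gxx, Gyy, Gxy, r_max, ridge)
}

.center_gram <- function(Gii) {
  n <- nrow(Gii)
  dvec <- rowSums(Gii) / n
  mm <- sum(dvec) / n
  Gc <- Gii - dvec            # subtract d 1' (column recycling)
  Gc <- sweep(Gc, 2L, dvec)   # subtract 1 d'
  Gc + mm
}

.center_gram_cross <- function(Gij) {
  n1 <- nrow(Gij); n0 <- ncol(Gij)
  dvec <- rowSums(Gij) / n0
  evec <- colSums(Gij) / n1
  mn <- sum(Gij) / (n1 * n0)
  Gc <- Gij - dvec
  Gc <- sweep(Gc, 2L, evec)
  Gc + mn
}

# Explicit path used when per-group scaling is requested.
.perm_stat_explicit <- function(Z, I, r_max, ridge) {
  J <- setdiff(seq_len(ncol(Z)), I)
  Xc <- .scale_rows(Z[, I, drop = FALSE])
  Yc <- .scale_rows(Z[, J, drop = FALSE])
  .stat_scan(crossprod(Xc), crossprod(Yc), crossprod(Xc, Yc), r_max, ridge)
}

.scale_rows <- function(M) {
  M <- M - rowMeans(M)
  s <- sqrt(rowSums(M^2) / (ncol(M) - 1L))
  if (any(s == 0)) {
    .stopf("zero-variance feature within a permuted group; rerun with scale = FALSE")
  }
  M / s
}

# Scan the statistic over r = 0..r_max with one CCA solve: the residual
# Gram after removing r directions is G_0 minus rank-one updates p_j p_j'
# with p_j = (u_j' X)' computable as Gxx a_j.
.stat_scan <- function(Gxx, Gyy, Gxy, r_max, ridge) {
  ridge_x <- if (is.null(ridge)) .default_ridge(Gxx) else ridge
  ridge_y <- if (is.null(ridge)) .default_ridge(Gyy) else ridge
  core <- .cca_core(Gxx, Gyy, Gxy, r_max, ridge_x, ridge_y)
  stats <- numeric(r_max + 1L)
  Gres <- Gxx
  tr <- sum(diag(Gres))
  stats[1L] <- .top_eig_share(Gres, tr)
  if (r_max > 0L) {
    P <- crossprod(core$A, Gxx)  # r_max x n1; row j = u_j' X
    for (r in seq_len(r_max)) {
      p <- P[r, ]
      Gres <- Gres - tcrossprod(p)
      tr <- tr - sum(p * p)
      stats[r + 1L] <- .top_eig_share(Gres, tr)
    }
  }
  stats
}

.top_eig_share <- function(G, tr) {
  if (tr <= .Machine$double.eps) return(0)
  lam <- eigen(G, symmetric = TRUE, only.values = TRUE)$values[1L]
  max(lam, 0) / tr
}
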