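#' Fit PACA: phenotype-aware component analysis
#'
#' Both groups are modeled as sharing low-rank sources of variation
#' (`W0`), with the cases carrying an additional, typically subtler,
#' case-specific signal (`W1 Z_X1`) assumed orthogonal to the shared
#' directions. The fit (i) centers each group, (ii) estimates the top `r`
#' shared feature-space directions by sample-space CCA
#' ([fit_shared_cca()]), (iii) projects them out of the case matrix
#' ([remove_shared()]), and (iv) extracts the leading `k1` principal
#' components of the residual. The component scores are the estimate of
#' the case-specific individual-level variation.
#'
#' With `r = 0` the result is plain PCA of the centered case matrix. With
#' `r = "auto"` the number of shared directions is chosen by the
#' permutation scheme of [select_shared_dim()] (pass `seed` and other
#' settings through `dim_args`).
#'
#' @param pair a [case_control_pair()] with more features than samples in
#'   either group.
#' @param r number of shared canonical directions to remove
#'   (`0 <= r <= min(n0, n1) - 1`), or `"auto"`.
#' @param k1 number of case-specific components to retain
#'   (`1 <= k1 <= n1 - 1`).
#' @param scale logical; per-group unit-variance scaling of features
#'   (default `FALSE`).
#' @param ridge Gram-matrix regularizer; see [fit_shared_cca()].
#' @param normalize_scores logical; if `TRUE`, component scores are
#'   unit-norm columns instead of carrying the singular-value scale.
#' @param dim_args list of arguments forwarded to [select_shared_dim()]
#'   when `r = "auto"` (e.g. `r_max`, `n_permutations`, `alpha`, `seed`).
#' @return a `paca_fit`: list with `shared_basis`, `case_scores`
#'   (n1 x k1), `feature_loadings` (m x k1, orthonormal columns),
#'   `singular_values`, `k1`, `r`, `preprocess` (centering record),
#'   `feature_ids`, `case_sample_ids`, and — when `r = "auto"` — the
#'   `dim_selection` result.
#' @examples
#' sim <- simulate_case_control(simulation_config(
#'   m = 300, n1 = 40, n0 = 40, k0 = 2, k1 = 1, seed = 1))
#' fit <- fit_paca(sim$pair, r = 2, k1 = 1)
#' fit
#' @export
fit_paca <- function(pair, r, k1 = 1L, scale = FALSE, ridge = NULL,
                     normalize_scores = FALSE, dim_args = list()) {
  stopifnot(inherits(pair, "case_control_pair"))
  d <- .pair_dims(pair)
  if (d["m"] <= max(d["n0"], d["n1"])) {
    .stopf(paste0("fit_paca() needs more features than samples ",
                  "(m = %d <= max group size %d); use fit_rpaca()"),
           d["m"], max(d["n0"], d["n1"]))
  }
  k1 <- .assert_count(k1, "k1", min = 1L)
  if (k1 > d["n1"] - 1L) .stopf("k1 = %d exceeds n1 - 1 = %d", k1, d["n1"] - 1L)

  centered <- center_pair(pair, scale = scale)
  Xc <- unclass(centered$pair$X)
  Yc <- unclass(centered$pair$Y)

  dim_selection <- NULL
  if (identical(r, "auto")) {
    dim_selection <- do.call(select_shared_dim,
                             c(list(pair = pair, scale = scale, ridge = ridge),
                               dim_args))
    r <- dim_selection$chosen_r
    if (is.na(r)) {
      warning("no significant case-specific variation detected; ",
              "removing 0 shared directions", call. = FALSE)
      r <- 0L
    }
  }
  r <- .assert_count(r, "r")

  basis <- fit_shared_cca(Xc, Yc, r, ridge = ridge)
  resid <- remove_shared(Xc, basis)

  sv <- svd(resid, nu = k1, nv = k1)
  d_top <- sv$d[seq_len(k1)]
  if (any(d_top < 1e-12)) {
    warning("degenerate fit: residual singular value(s) below 1e-12 ",
            "(rank-deficient case matrix?)", call. = FALSE)
  }
  loadings <- sv$u
  scores <- sv$v %*% diag(d_top, nrow = k1)
  if (isTRUE(normalize_scores)) scores <- sv$v
  fixed <- .fix_signs(loadings, list(scores))
  loadings <- fixed[[1L]]
  scores <- fixed[[2L]]
  rownames(loadings) <- rownames(pair$X)
  rownames(scores) <- colnames(pair$X)
  colnames(loadings) <- colnames(scores) <- paste0("PACA", seq_len(k1))

  structure(list(
    shared_basis = basis,
    case_scores = scores,
    feature_loadings = loadings,
    singular_values = d_top,
    k1 = k1,
    r = r,
    scores_normalized = isTRUE(normalize_scores),
    preprocess = centered$record,
    feature_ids = rownames(pair$X),
    case_sample_ids = colnames(pair$X),
    dim_selection = dim_selection,
    version = as.character(utils::packageVersion("paca"))
  ), class = "paca_fit")
}

#' @export
print.paca_fit <- function(x, ...) {
  cat(sprintf("<paca_fit> %d features, %d cases; removed r = %d shared direction(s), kept k1 = %d component(s)\n",
              length(x$feature_ids), length(x$case_sample_ids), x$r, x$k1))
  cat("residual singular values:",
      paste(sprintf("%.3g", x$singular_values), collapse = " "), "\n")
  if (!is.null(x$dim_selection)) {
    cat(sprintf("r chosen by permutation scheme (alpha = %g, %d permutations)\n",
                x$dim_selection$alpha, x$dim_selection$n_permutations))
  }
  invisible(x)
}
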