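#' Configuration for randomized PACA
#'
#' @param n_subsamples number of random subsamples to aggregate (>= 2).
#' @param r shared directions to remove (per subsample and in consensus).
#' @param k1 case components to retain.
#' @param subsample_case_size,subsample_control_size samples drawn per
#'   group in each round; must be smaller than the number of features and
#'   at most the group size. Default (`NULL`): `floor(0.8 * m)`, capped at
#'   the group size, which preserves the core method's
#'   features-exceed-samples requirement with maximal per-draw
#'   information.
#' @param seed integer; identical seeds give bit-identical fits.
#' @return a validated `rpaca_config` list.
#' @export
rpaca_config <- function(n_subsamples, r, k1 = 1L,
                         subsample_case_size = NULL,
                         subsample_control_size = NULL, seed = NULL) {
  n_subsamples <- .assert_count(n_subsamples, "n_subsamples", 2L)
  r <- .assert_count(r, "r")
  k1 <- .assert_count(k1, "k1", 1L)
  structure(list(
    n_subsamples = n_subsamples, r = r, k1 = k1,
    subsample_case_size = if (is.null(subsample_case_size)) NULL
                          else .assert_count(subsample_case_size, "subsample_case_size", 2L),
    subsample_control_size = if (is.null(subsample_control_size)) NULL
                             else .assert_count(subsample_control_size, "subsample_control_size", 2L),
    seed = if (is.null(seed)) NULL else as.integer(seed)
  ), class = "rpaca_config")
}

#' Randomized PACA for the more-samples-than-features regime
#'
#' Sample-space CCA requires more features than samples, so when samples
#' outnumber features the shared subspace is estimated by repeated random
#' subsampling: each round draws (without replacement) case/control subsets
#' small enough for the core fit, and the per-round shared-direction
#' estimates are aggregated by averaging their projection operators
#' `U0 U0'` and taking the top-`r` eigenvectors of the average (a chordal
#' mean of subspaces, immune to per-round sign/rotation ambiguity). The
#' consensus shared variation is then removed from the *full* case matrix
#' and the residual principal components give scores for every case sample.
#'
#' When the input already has more features than samples a notice is
#' emitted and the direct [fit_paca()] is used.
#'
#' @param pair a [case_control_pair()].
#' @param config an [rpaca_config()].
#' @param scale,ridge as in [fit_paca()].
#' @return a `paca_fit` (see [fit_paca()]); its `shared_basis` holds the
#'   consensus `U0` with the eigenvalues of the mean projection operator
#'   (each in `[0, 1]`, measuring how consistently the direction recurred
#'   across subsamples) in place of canonical correlations, and the fit
#'   records `n_subsamples` and the subsample sizes.
#' @export
fit_rpaca <- function(pair, config, scale = FALSE, ridge = NULL) {
  stopifnot(inherits(pair, "case_control_pair"),
            inherits(config, "rpaca_config"))
  d <- .pair_dims(pair)
  m <- d[["m"]]; n1 <- d[["n1"]]; n0 <- d[["n0"]]
  if (m > max(n0, n1)) {
    message("features exceed samples; using the direct fit_paca()")
    return(fit_paca(pair, r = config$r, k1 = config$k1,
                    scale = scale, ridge = ridge))
  }
  s1 <- if (is.null(config$subsample_case_size)) min(floor(0.8 * m), n1)
        else config$subsample_case_size
  s0 <- if (is.null(config$subsample_control_size)) min(floor(0.8 * m), n0)
        else config$subsample_control_size
  if (s1 >= m || s0 >= m) {
    .stopf("subsample sizes (%d, %d) must be smaller than m = %d", s1, s0, m)
  }
  if (s1 > n1 || s0 > n0) {
    .stopf("subsample sizes (%d, %d) exceed group sizes (%d, %d)", s1, s0, n1, n0)
  }
  if (config$r > min(s0, s1) - 1L) {
    .stopf("r = %d too large for subsample sizes (%d, %d)", config$r, s1, s0)
  }
  if (config$k1 > n1 - 1L) .stopf("k1 = %d exceeds n1 - 1 = %d", config$k1, n1 - 1L)

  centered <- center_pair(pair, scale = scale)
  Xc <- unclass(centered$pair$X)
  Yc <- unclass(centered$pair$Y)

  consensus <- .with_seed(config$seed, {
    Pbar <- matrix(0, m, m)
    for (b in seq_len(config$n_subsamples)) {
      I <- sample.int(n1, s1)
      J <- sample.int(n0, s0)
      # re-center within the subsample so each round satisfies the core
      # model's mean-free form
      Xs <- Xc[, I, drop = FALSE]; Xs <- Xs - rowMeans(Xs)
      Ys <- Yc[, J, drop = FALSE]; Ys <- Ys - rowMeans(Ys)
      basis_b <- fit_shared_cca(Xs, Ys, config$r, ridge = ridge)
      if (config$r > 0L) Pbar <- Pbar + tcrossprod(basis_b$U0)
    }
    Pbar / config$n_subsamples
  })

  if (config$r > 0L) {
    e <- eigen(consensus, symmetric = TRUE)
    U0 <- .fix_signs(e$vectors[, seq_len(config$r), drop = FALSE])[[1L]]
    weight <- pmin(pmax(e$values[seq_len(config$r)], 0), 1)
  } else {
    U0 <- matrix(0, m, 0L)
    weight <- numeric(0)
  }
  basis <- structure(list(
    U0 = U0, canonical_correlations = weight, r = config$r,
    a_coeffs = NULL, b_coeffs = NULL
  ), class = "shared_basis")

  resid <- remove_shared(Xc, basis)
  k1 <- config$k1
  sv <- svd(resid, nu = k1, nv = k1)
  d_top <- sv$d[seq_len(k1)]
  fixed <- .fix_signs(sv$u, list(sv$v %*% diag(d_top, nrow = k1)))
  loadings <- fixed[[1L]]; scores <- fixed[[2L]]
  rownames(loadings) <- rownames(pair$X)
  rownames(scores) <- colnames(pair$X)
  colnames(loadings) <- colnames(scores) <- paste0("PACA", seq_len(k1))

  structure(list(
    shared_basis = basis,
    case_scores = scores,
    feature_loadings = loadings,
    singular_values = d_top,
    k1 = k1,
    r = config$r,
    scores_normalized = FALSE,
    preprocess = centered$record,
    feature_ids = rownames(pair$X),
    case_sample_ids = colnames(pair$X),
    dim_selection = NULL,
    randomized = list(n_subsamples = config$n_subsamples,
                      subsample_case_size = s1,
                      subsample_control_size = s0,
                      seed = config$seed),
    version = as.character(utils::packageVersion("paca"))
  ), class = "paca_fit")
}
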