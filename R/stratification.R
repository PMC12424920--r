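#' Export one PACA component as a portable stratification score
#'
#' Turns the selected component into feature weights plus the training
#' centering vector, so the score can be computed for any new cohort that
#' shares the feature set ("multiply the coefficients by the same
#' features"). Weights are the pure loading direction (not scaled by the
#' singular value); projected scores are z-scaled against the training
#' cases, making discovery and replication score distributions comparable.
#'
#' @param fit a `paca_fit`.
#' @param component_index which component to export (`1..k1`).
#' @return a `stratification_model`: list with `feature_ids`, `weights`,
#'   `centering` (training case feature means), `scaling` (training sds
#'   when the fit scaled features, else `NULL`), `component_index`, and
#'   `normalization` (training score mean/sd).
#' @seealso [project_score()], [rank_features()]
#' @export
export_score <- function(fit, component_index) {
  stopifnot(inherits(fit, "paca_fit"))
  component_index <- .assert_count(component_index, "component_index", 1L)
  if (component_index > fit$k1) {
    .stopf("component_index = %d out of range (fit has k1 = %d components)",
           component_index, fit$k1)
  }
  w <- fit$feature_loadings[, component_index]
  if (all(w == 0)) .stopf("component %d has all-zero loadings", component_index)
  train_scores <- fit$case_scores[, component_index]
  if (isTRUE(fit$scores_normalized)) {
    train_scores <- train_scores * fit$singular_values[component_index]
  }
  mu <- mean(train_scores)
  sd_ <- stats::sd(train_scores)
  if (!is.finite(sd_) || sd_ == 0) {
    warning("degenerate training scores (zero variance); scores will not be z-scaled",
            call. = FALSE)
    sd_ <- 1
  }
  structure(list(
    feature_ids = fit$feature_ids,
    weights = stats::setNames(w, fit$feature_ids),
    centering = fit$preprocess$case_feature_means,
    scaling = fit$preprocess$case_feature_sds,
    component_index = component_index,
    normalization = list(mean = mu, sd = sd_),
    version = as.character(utils::packageVersion("paca"))
  ), class = "stratification_model")
}

#' @export
print.stratification_model <- function(x, ...) {
  cat(sprintf("<stratification_model> component %d, %d feature weights\n",
              x$component_index, length(x$weights)))
  invisible(x)
}

#' Project a stratification score onto a new cohort
#'
#' Computes `score_j = w' (x_j - centering)` for every sample of the
#' cohort (features matched by identifier, reordered internally), then
#' z-scales by the training normalization so scores live on the discovery
#' cohort's scale.
#'
#' @param model a [export_score()] result.
#' @param cohort an [omics_matrix()] (or matrix with feature rownames)
#'   containing at least all model features.
#' @return named numeric vector of per-sample scores.
#' @export
project_score <- function(model, cohort) {
  stopifnot(inherits(model, "stratification_model"))
  if (is.null(rownames(cohort))) .stopf("cohort must carry feature rownames")
  idx <- match(model$feature_ids, rownames(cohort))
  miss <- model$feature_ids[is.na(idx)]
  if (length(miss)) {
    .stopf("cohort is missing %d model feature(s): %s%s",
           length(miss), paste(utils::head(miss, 20L), collapse = ", "),
           if (length(miss) > 20L) ", ..." else "")
  }
  Zc <- unclass(cohort)[idx, , drop = FALSE] - model$centering
  if (!is.null(model$scaling)) Zc <- Zc / model$scaling
  raw <- drop(crossprod(Zc, model$weights))
  scores <- (raw - model$normalization$mean) / model$normalization$sd
  stats::setNames(scores, colnames(cohort))
}

#' Rank features by score weight
#'
#' @param model a [export_score()] result.
#' @param top_k how many features to return (default all).
#' @return data.frame with `feature_id` and `weight`, ordered by
#'   decreasing absolute weight; ties broken by feature id (C-locale
#'   lexicographic).
#' @export
rank_features <- function(model, top_k = length(model$weights)) {
  stopifnot(inherits(model, "stratification_model"))
  top_k <- .assert_count(top_k, "top_k", 1L)
  if (top_k > length(model$weights)) {
    .stopf("top_k = %d exceeds the number of features (%d)",
           top_k, length(model$weights))
  }
  ord <- order(-abs(model$weights), model$feature_ids, method = "radix")
  out <- data.frame(feature_id = model$feature_ids[ord],
                    weight = unname(model$weights[ord]))
  utils::head(out, top_k)
}

#' Cross-cohort phenotype-correlation consistency of a score
#'
#' A component that captures real, portable disease heterogeneity should
#' correlate with external phenotypes the same way in independent cohorts.
#' For every phenotype present in both cohorts' tables this computes the
#' Pearson correlation between score and phenotype within each cohort
#' (pairwise-complete over samples), then summarizes cross-cohort
#' consistency as the fraction of phenotypes with sign-agreeing
#' correlations and the correlation between the two correlation vectors.
#' Use it to screen components: keep the one whose phenotype correlations
#' replicate.
#'
#' @param scores_a,scores_b named per-sample score vectors (names =
#'   sample ids) for cohorts A and B, e.g. from [project_score()].
#' @param phenos_a,phenos_b numeric matrices or data.frames of phenotypes
#'   (rownames = sample ids, columns = phenotypes); missing cells allowed.
#' @param min_obs minimum paired non-missing observations per phenotype
#'   per cohort (default 3); phenotypes below it are skipped with a
#'   warning.
#' @return list with `per_phenotype` (data.frame: `phenotype`, `cor_a`,
#'   `cor_b`, `n_a`, `n_b`), `sign_agreement` (fraction in `[0, 1]`), and
#'   `correlation_of_correlations`.
#' @export
phenotype_consistency <- function(scores_a, scores_b, phenos_a, phenos_b,
                                  min_obs = 3L) {
  phenos_a <- .as_pheno_matrix(phenos_a, "phenos_a")
  phenos_b <- .as_pheno_matrix(phenos_b, "phenos_b")
  shared <- intersect(colnames(phenos_a), colnames(phenos_b))
  if (!length(shared)) .stopf("no phenotype shared between the two tables")
  rows <- lapply(shared, function(ph) {
    ca <- .score_pheno_cor(scores_a, phenos_a[, ph], min_obs)
    cb <- .score_pheno_cor(scores_b, phenos_b[, ph], min_obs)
    if (is.null(ca) || is.null(cb)) {
      warning(sprintf("phenotype '%s' skipped: fewer than %d paired observations",
                      ph, min_obs), call. = FALSE)
      return(NULL)
    }
    data.frame(phenotype = ph, cor_a = ca$r, cor_b = cb$r,
               n_a = ca$n, n_b = cb$n)
  })
  rows <- do.call(rbind, rows)
  if (is.null(rows) || !nrow(rows)) .stopf("no usable phenotypes")
  ok <- is.finite(rows$cor_a) & is.finite(rows$cor_b)
  sign_agreement <- mean(sign(rows$cor_a[ok]) == sign(rows$cor_b[ok]))
  coc <- NA_real_
  if (sum(ok) >= 2L && stats::sd(rows$cor_a[ok]) > 0 && stats::sd(rows$cor_b[ok]) > 0) {
    coc <- stats::cor(rows$cor_a[ok], rows$cor_b[ok])
  }
  list(per_phenotype = rows, sign_agreement = sign_agreement,
       correlation_of_correlations = coc)
}

.as_pheno_matrix <- function(tab, name) {
  if (is.data.frame(tab)) tab <- as.matrix(tab)
  if (!is.matrix(tab) || !is.numeric(tab)) {
    .stopf("`%s` must be a numeric matrix/data.frame (samples x phenotypes)", name)
  }
  if (is.null(rownames(tab)) || anyDuplicated(rownames(tab))) {
    .stopf("`%s` must carry unique sample-id rownames", name)
  }
  if (ncol(tab) > 0L && is.null(colnames(tab))) {
    .stopf("`%s` must carry phenotype colnames", name)
  }
  tab
}

.score_pheno_cor <- function(scores, pheno, min_obs) {
  ids <- intersect(names(scores), names(pheno))
  s <- scores[ids]; p <- pheno[ids]
  keep <- is.finite(s) & is.finite(p)
  if (sum(keep) < min_obs) return(NULL)
  if (stats::sd(s[keep]) == 0 || stats::sd(p[keep]) == 0) return(NULL)
  list(r = stats::cor(s[keep], p[keep]), n = sum(keep))
}

#' Univariate case/control association filter
#'
#' A simple per-feature screen that keeps features differing in mean
#' between cases and controls by a two-sample Welch t-test. This is a
#' generic stand-in for study-specific feature pre-selection (such as a
#' covariate-adjusted, cell-type-aware EWAS) — deliberately simplified:
#' no covariates, no deconvolution.
#'
#' @param pair a [case_control_pair()] with at least 3 samples per group.
#' @param p_threshold keep features with `p <= p_threshold`; must be in
#'   (0, 1]. Features with no variance in either group get `p = 1` when
#'   the group means agree, `p = 0` when they differ.
#' @return list with `pair` (both matrices subset to the surviving
#'   features, original order preserved) and `p_values` (named, full
#'   length).
#' @export
filter_features_by_association <- function(pair, p_threshold) {
  stopifnot(inherits(pair, "case_control_pair"))
  if (!is.numeric(p_threshold) || length(p_threshold) != 1L ||
      p_threshold <= 0 || p_threshold > 1) {
    .stopf("p_threshold must be in (0, 1]")
  }
  d <- .pair_dims(pair)
  if (d["n1"] < 3L || d["n0"] < 3L) .stopf("need at least 3 samples per group")
  X <- unclass(pair$X); Y <- unclass(pair$Y)
  n1 <- ncol(X); n0 <- ncol(Y)
  m1 <- rowMeans(X); m0 <- rowMeans(Y)
  v1 <- rowSums((X - m1)^2) / (n1 - 1L)
  v0 <- rowSums((Y - m0)^2) / (n0 - 1L)
  se2 <- v1 / n1 + v0 / n0
  tstat <- (m1 - m0) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1L) + (v0 / n0)^2 / (n0 - 1L))
  p <- 2 * stats::pt(-abs(tstat), df)
  p[se2 == 0] <- ifelse(m1[se2 == 0] == m0[se2 == 0], 1, 0)
  names(p) <- rownames(X)
  keep <- which(p <= p_threshold)
  if (length(keep) < 2L) {
    .stopf("fewer than 2 features pass p <= %g (got %d); relax the threshold",
           p_threshold, length(keep))
  }
  reduced <- case_control_pair(X[keep, , drop = FALSE], Y[keep, , drop = FALSE])
  list(pair = reduced, p_values = p)
}
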