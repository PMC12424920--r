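#' Labeled feature-by-sample matrix
#'
#' The universal input unit: a numeric matrix of `m` features (rows) by `n`
#' samples (columns) for one group, with unique feature and sample
#' identifiers. This is the orientation methylation beta matrices ship in
#' (CpG probes as rows). Values must be finite; missing data are rejected —
#' impute upstream during array QC if needed.
#'
#' @param values numeric matrix, features as rows. Dimnames are used as
#'   identifiers when `feature_ids`/`sample_ids` are not given.
#' @param feature_ids character vector of unique row identifiers.
#' @param sample_ids character vector of unique column identifiers.
#' @return a numeric matrix with class `"omics_matrix"`, rownames set to the
#'   feature ids and colnames to the sample ids.
#' @examples
#' m <- omics_matrix(matrix(rnorm(12), 4, 3),
#'                   feature_ids = paste0("cg", 1:4),
#'                   sample_ids  = paste0("s", 1:3))
#' @export
omics_matrix <- function(values, feature_ids = rownames(values),
                         sample_ids = colnames(values)) {
  if (!is.matrix(values) || !is.numeric(values)) {
    .stopf("`values` must be a numeric matrix (features x samples)")
  }
  if (nrow(values) < 2L || ncol(values) < 2L) {
    .stopf("need at least 2 features and 2 samples; got %d x %d",
           nrow(values), ncol(values))
  }
  if (is.null(feature_ids)) feature_ids <- paste0("feature_", seq_len(nrow(values)))
  if (is.null(sample_ids)) sample_ids <- paste0("sample_", seq_len(ncol(values)))
  feature_ids <- as.character(feature_ids)
  sample_ids <- as.character(sample_ids)
  if (length(feature_ids) != nrow(values)) {
    .stopf("feature_ids length (%d) != number of rows (%d)",
           length(feature_ids), nrow(values))
  }
  if (length(sample_ids) != ncol(values)) {
    .stopf("sample_ids length (%d) != number of columns (%d)",
           length(sample_ids), ncol(values))
  }
  dup <- feature_ids[duplicated(feature_ids)]
  if (length(dup)) .stopf("duplicated feature_ids: %s",
                          paste(utils::head(unique(dup), 5L), collapse = ", "))
  dup <- sample_ids[duplicated(sample_ids)]
  if (length(dup)) .stopf("duplicated sample_ids: %s",
                          paste(utils::head(unique(dup), 5L), collapse = ", "))
  bad <- which(!is.finite(values))
  if (length(bad)) {
    ij <- arrayInd(bad[1L], dim(values))
    .stopf("non-finite value at feature '%s' (row %d), sample '%s' (column %d)%s",
           feature_ids[ij[1L]], ij[1L], sample_ids[ij[2L]], ij[2L],
           if (length(bad) > 1L) sprintf(" (and %d more)", length(bad) - 1L) else "")
  }
  dimnames(values) <- list(feature_ids, sample_ids)
  class(values) <- c("omics_matrix", class(values))
  values
}

#' @export
print.omics_matrix <- function(x, ...) {
  cat(sprintf("<omics_matrix> %d features x %d samples\n", nrow(x), ncol(x)))
  cat("features:", paste(utils::head(rownames(x), 3L), collapse = ", "),
      if (nrow(x) > 3L) "..." else "", "\n")
  cat("samples: ", paste(utils::head(colnames(x), 3L), collapse = ", "),
      if (ncol(x) > 3L) "..." else "", "\n")
  invisible(x)
}

# Coerce to a validated omics_matrix; plain matrices pass through validation.
as_omics_matrix <- function(x) {
  if (inherits(x, "omics_matrix")) x else omics_matrix(x)
}

#' Aligned case/control matrix pair
#'
#' Bundles a case matrix `X` (n1 samples) and a control matrix `Y`
#' (n0 samples) measured over an identical ordered feature set. All
#' fitting functions consume this pair.
#'
#' @param X cases, an [omics_matrix()] or numeric matrix (m x n1).
#' @param Y controls, over the same features in the same order (m x n0).
#' @return an object of class `"case_control_pair"`: a list with elements
#'   `X` and `Y`.
#' @export
case_control_pair <- function(X, Y) {
  X <- as_omics_matrix(X)
  Y <- as_omics_matrix(Y)
  if (nrow(X) != nrow(Y) || !identical(rownames(X), rownames(Y))) {
    .stopf("X and Y must share an identical ordered feature set")
  }
  both <- intersect(colnames(X), colnames(Y))
  if (length(both)) {
    .stopf("sample ids present in both groups: %s",
           paste(utils::head(both, 5L), collapse = ", "))
  }
  structure(list(X = X, Y = Y), class = "case_control_pair")
}

#' @export
print.case_control_pair <- function(x, ...) {
  cat(sprintf("<case_control_pair> %d features; %d cases, %d controls\n",
              nrow(x$X), ncol(x$X), ncol(x$Y)))
  invisible(x)
}

# Dimensions helpers (m, n1, n0).
.pair_dims <- function(pair) {
  c(m = nrow(pair$X), n1 = ncol(pair$X), n0 = ncol(pair$Y))
}
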