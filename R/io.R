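#' Read a delimited feature-by-sample matrix
#'
#' Canonical layout: first column feature identifiers, header row sample
#' identifiers, features as rows (the methylation-array convention). The
#' delimiter is sniffed (TSV/CSV) unless given. Files laid out
#' samples-as-rows are handled with `transpose = TRUE`.
#'
#' @param path file path.
#' @param transpose logical; the file has samples as rows.
#' @param sep field delimiter; default `"auto"` sniffs.
#' @return an [omics_matrix()].
#' @export
read_omics_matrix <- function(path, transpose = FALSE, sep = "auto") {
  if (!file.exists(path)) .stopf("input file not found: %s", path)
  dt <- data.table::fread(path, sep = sep, header = TRUE,
                          data.table = FALSE, colClasses = NULL)
  if (ncol(dt) < 2L) .stopf("%s: expected an id column plus data columns", path)
  hdr <- colnames(dt)[-1L]
  dup <- unique(hdr[duplicated(hdr)])
  if (length(dup)) {
    .stopf("%s: duplicated %s: %s", path,
           if (isTRUE(transpose)) "feature_ids" else "sample_ids",
           paste(utils::head(dup, 5L), collapse = ", "))
  }
  ids <- as.character(dt[[1L]])
  vals <- dt[, -1L, drop = FALSE]
  for (j in seq_along(vals)) {
    col <- vals[[j]]
    if (!is.numeric(col)) {
      num <- suppressWarnings(as.numeric(col))
      bad <- which(is.na(num) & !is.na(col))
      if (length(bad)) {
        .stopf("%s: non-numeric value '%s' at row %d, column '%s'",
               path, col[bad[1L]], bad[1L], colnames(vals)[j])
      }
      vals[[j]] <- num
    }
    nas <- which(is.na(vals[[j]]))
    if (length(nas)) {
      .stopf("%s: missing value at row %d (id '%s'), column '%s'",
             path, nas[1L], ids[nas[1L]], colnames(vals)[j])
    }
  }
  mat <- as.matrix(vals)
  rownames(mat) <- ids
  if (isTRUE(transpose)) mat <- t(mat)
  omics_matrix(mat)
}

#' Write a feature-by-sample matrix as TSV
#'
#' @param mat an [omics_matrix()] (or matrix with dimnames).
#' @param path output path.
#' @param sep delimiter (default tab).
#' @export
write_omics_matrix <- function(mat, path, sep = "\t") {
  df <- data.frame(feature_id = rownames(mat), unclass(mat),
                   check.names = FALSE)
  data.table::fwrite(df, path, sep = sep)
  invisible(path)
}

# ---- fit serialization ----------------------------------------------------

# Matrices are flattened column-major with explicit dims; doubles are
# written with 17 significant digits, which round-trips IEEE doubles
# exactly, so write/read reproduces every array bit-identically.
.pack_matrix <- function(M) {
  if (is.null(M)) return(NULL)
  list(dim = dim(M), data = as.vector(M))
}

.unpack_matrix <- function(p, rn = NULL, cn = NULL) {
  if (is.null(p)) return(NULL)
  M <- matrix(p$data, p$dim[1L], p$dim[2L])
  if (!is.null(rn)) rownames(M) <- rn
  if (!is.null(cn)) colnames(M) <- cn
  M
}

#' Serialize / load a fitted PACA model
#'
#' Writes a single JSON document holding the preprocessing record, shared
#' basis, loadings, scores, singular values and software version; the
#' round trip reproduces every numeric array bit-identically. A version
#' mismatch on load warns and proceeds best-effort.
#'
#' @param fit a `paca_fit`.
#' @param path output (input) path.
#' @return `write_paca_fit` returns `path` invisibly; `read_paca_fit`
#'   returns the `paca_fit`.
#' @export
write_paca_fit <- function(fit, path) {
  stopifnot(inherits(fit, "paca_fit"))
  doc <- list(
    format = "paca_fit",
    version = fit$version,
    r = fit$r,
    k1 = fit$k1,
    scores_normalized = fit$scores_normalized,
    feature_ids = fit$feature_ids,
    case_sample_ids = fit$case_sample_ids,
    preprocess = list(
      case_feature_means = unname(fit$preprocess$case_feature_means),
      control_feature_means = unname(fit$preprocess$control_feature_means),
      scaled = fit$preprocess$scaled,
      case_feature_sds = unname(fit$preprocess$case_feature_sds),
      control_feature_sds = unname(fit$preprocess$control_feature_sds)
    ),
    shared_basis = list(
      U0 = .pack_matrix(fit$shared_basis$U0),
      canonical_correlations = fit$shared_basis$canonical_correlations,
      r = fit$shared_basis$r,
      a_coeffs = .pack_matrix(fit$shared_basis$a_coeffs),
      b_coeffs = .pack_matrix(fit$shared_basis$b_coeffs)
    ),
    feature_loadings = .pack_matrix(unname(fit$feature_loadings)),
    case_scores = .pack_matrix(unname(fit$case_scores)),
    singular_values = fit$singular_values,
    randomized = fit$randomized
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17),
                       null = "null", pretty = FALSE)
  invisible(path)
}

#' @rdname write_paca_fit
#' @export
read_paca_fit <- function(path) {
  if (!file.exists(path)) .stopf("fit file not found: %s", path)
  doc <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e) {
                    .stopf("cannot parse fit file %s: %s", path, conditionMessage(e))
                  })
  if (!identical(doc$format, "paca_fit")) {
    .stopf("%s is not a serialized paca_fit", path)
  }
  current <- as.character(utils::packageVersion("paca"))
  if (!identical(doc$version, current)) {
    warning(sprintf("fit was written by paca %s (this is %s); loading best-effort",
                    doc$version, current), call. = FALSE)
  }
  fid <- doc$feature_ids
  sid <- doc$case_sample_ids
  k1 <- as.integer(doc$k1)
  pp <- doc$preprocess
  basis <- structure(list(
    U0 = .unpack_matrix(doc$shared_basis$U0, rn = fid),
    canonical_correlations = as.numeric(doc$shared_basis$canonical_correlations),
    r = as.integer(doc$shared_basis$r),
    a_coeffs = .unpack_matrix(doc$shared_basis$a_coeffs),
    b_coeffs = .unpack_matrix(doc$shared_basis$b_coeffs)
  ), class = "shared_basis")
  loadings <- .unpack_matrix(doc$feature_loadings, rn = fid,
                             cn = paste0("PACA", seq_len(k1)))
  scores <- .unpack_matrix(doc$case_scores, rn = sid,
                           cn = paste0("PACA", seq_len(k1)))
  structure(list(
    shared_basis = basis,
    case_scores = scores,
    feature_loadings = loadings,
    singular_values = as.numeric(doc$singular_values),
    k1 = k1,
    r = as.integer(doc$r),
    scores_normalized = isTRUE(doc$scores_normalized),
    preprocess = structure(list(
      case_feature_means = stats::setNames(as.numeric(pp$case_feature_means), fid),
      control_feature_means = stats::setNames(as.numeric(pp$control_feature_means), fid),
      scaled = isTRUE(pp$scaled),
      case_feature_sds = if (is.null(pp$case_feature_sds)) NULL
                         else stats::setNames(as.numeric(pp$case_feature_sds), fid),
      control_feature_sds = if (is.null(pp$control_feature_sds)) NULL
                            else stats::setNames(as.numeric(pp$control_feature_sds), fid)
    ), class = "preprocess_record"),
    feature_ids = fid,
    case_sample_ids = sid,
    dim_selection = NULL,
    randomized = doc$randomized,
    version = doc$version
  ), class = "paca_fit")
}

#' Serialize / load a stratification model
#'
#' @param model a [export_score()] result.
#' @param path output (input) path.
#' @export
write_stratification_model <- function(model, path) {
  stopifnot(inherits(model, "stratification_model"))
  doc <- list(
    format = "paca_stratification_model",
    version = model$version,
    feature_ids = model$feature_ids,
    weights = unname(model$weights),
    centering = unname(model$centering),
    scaling = if (is.null(model$scaling)) NULL else unname(model$scaling),
    component_index = model$component_index,
    normalization = model$normalization
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17), null = "null")
  invisible(path)
}

#' @rdname write_stratification_model
#' @export
read_stratification_model <- function(path) {
  if (!file.exists(path)) .stopf("model file not found: %s", path)
  doc <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e) {
                    .stopf("cannot parse model file %s: %s", path, conditionMessage(e))
                  })
  if (!identical(doc$format, "paca_stratification_model")) {
    .stopf("%s is not a serialized stratification model", path)
  }
  fid <- doc$feature_ids
  structure(list(
    feature_ids = fid,
    weights = stats::setNames(as.numeric(doc$weights), fid),
    centering = stats::setNames(as.numeric(doc$centering), fid),
    scaling = if (is.null(doc$scaling)) NULL
              else stats::setNames(as.numeric(doc$scaling), fid),
    component_index = as.integer(doc$component_index),
    normalization = list(mean = as.numeric(doc$normalization$mean),
                         sd = as.numeric(doc$normalization$sd)),
    version = doc$version
  ), class = "stratification_model")
}
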