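#' Center (and optionally scale) a case/control pair per group
#'
#' Each feature row is brought to mean zero within cases and within controls
#' separately; with `scale = TRUE` each row is additionally brought to unit
#' standard deviation per group. Per-group centering prevents a case/control
#' mean shift from masquerading as shared or case-specific variance. The
#' removed means (and sds) are recorded so fitted models can later project
#' raw cohorts.
#'
#' @param pair a [case_control_pair()].
#' @param scale logical; divide each row by its per-group standard
#'   deviation (default `FALSE`). Requires every feature to have nonzero
#'   variance in both groups.
#' @return a list with elements `pair` (the centered [case_control_pair()])
#'   and `record`, a `preprocess_record` holding `case_feature_means`,
#'   `control_feature_means`, `scaled`, and (when scaling)
#'   `case_feature_sds`, `control_feature_sds`.
#' @export
center_pair <- function(pair, scale = FALSE) {
  stopifnot(inherits(pair, "case_control_pair"))
  cx <- .center_group(pair$X, scale, "case")
  cy <- .center_group(pair$Y, scale, "control")
  record <- structure(list(
    case_feature_means = cx$means,
    control_feature_means = cy$means,
    scaled = isTRUE(scale),
    case_feature_sds = cx$sds,
    control_feature_sds = cy$sds
  ), class = "preprocess_record")
  out <- pair
  out$X[] <- cx$values
  out$Y[] <- cy$values
  list(pair = out, record = record)
}

.center_group <- function(mat, scale, label) {
  means <- rowMeans(mat)
  values <- mat - means
  sds <- NULL
  if (isTRUE(scale)) {
    sds <- sqrt(rowSums(values^2) / (ncol(mat) - 1L))
    zero <- which(sds == 0)
    if (length(zero)) {
      .stopf("cannot scale: zero-variance %s feature '%s'%s",
             label, rownames(mat)[zero[1L]],
             if (length(zero) > 1L) sprintf(" (and %d more)", length(zero) - 1L) else "")
    }
    values <- values / sds
    names(sds) <- rownames(mat)
  }
  names(means) <- rownames(mat)
  list(values = unclass(values), means = means, sds = sds)
}

#' @export
print.preprocess_record <- function(x, ...) {
  cat(sprintf("<preprocess_record> %d features; scaled: %s\n",
              length(x$case_feature_means), x$scaled))
  invisible(x)
}
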