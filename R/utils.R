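# Internal numerical helpers shared across modules.

# Fix the sign of each column of `loadings` so the entry of largest absolute
# value is positive; ties broken by the lowest row index. `companions` is a
# list of matrices whose corresponding columns must flip together (scores,
# coefficient vectors) so the factorization is unchanged.
.fix_signs <- function(loadings, companions = list()) {
  if (ncol(loadings) == 0L) {
    return(c(list(loadings), companions))
  }
  flip <- vapply(seq_len(ncol(loadings)), function(j) {
    v <- loadings[, j]
    a <- abs(v)
    i <- which(a == max(a))[1L]  # which.max already takes the first max
    v[i] < 0
  }, logical(1L))
  if (any(flip)) {
    loadings[, flip] <- -loadings[, flip]
    companions <- lapply(companions, function(mat) {
      mat[, flip] <- -mat[, flip]
      mat
    })
  }
  c(list(loadings), companions)
}

# Principal angles (radians) between the column spans of two matrices with
# orthonormal columns, via the SVD of the cross-product.
.principal_angles <- function(A, B) {
  if (ncol(A) == 0L || ncol(B) == 0L) return(numeric(0))
  s <- svd(crossprod(A, B), nu = 0, nv = 0)$d
  acos(pmin(pmax(s, -1), 1))
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards so library calls don't clobber
# user-level reproducibility.
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Draw an m x k matrix with orthonormal columns from the Haar-ish measure
# induced by QR of a standard Gaussian matrix, with the R factor's diagonal
# signs fixed so the draw is a deterministic function of the Gaussians.
.random_orthonormal <- function(m, k) {
  if (k == 0L) return(matrix(0, m, 0L))
  G <- matrix(stats::rnorm(m * k), m, k)
  qr_G <- qr(G)
  Q <- qr.Q(qr_G)
  d <- sign(diag(qr.R(qr_G)))
  d[d == 0] <- 1
  sweep(Q, 2L, d, `*`)
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

.assert_count <- function(x, name, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != round(x) || x < min) {
    .stopf("`%s` must be a single integer >= %d", name, min)
  }
  as.integer(x)
}
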