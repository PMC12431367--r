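#' @importFrom stats rnorm runif sd
NULL

# Run `expr` under a temporary RNG state seeded with `seed`; restores the
# caller's .Random.seed afterwards so library code never clobbers user RNG.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
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
  set.seed(as.integer(seed))
  force(expr)
}

# Moore-Penrose pseudo-inverse via SVD; used only as the fallback for a
# singular attention system.
pinv <- function(M, tol = NULL) {
  s <- svd(M)
  if (is.null(tol)) tol <- max(dim(M)) * max(s$d) * .Machine$double.eps
  keep <- s$d > tol
  if (!any(keep)) return(matrix(0, ncol(M), nrow(M)))
  s$v[, keep, drop = FALSE] %*%
    (t(s$u[, keep, drop = FALSE]) / s$d[keep])
}

stop_if_not_finite <- function(M, what) {
  if (!all(is.finite(M))) {
    stop(sprintf("non-finite values produced by the %s sub-problem", what),
         call. = FALSE)
  }
  invisible(M)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
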