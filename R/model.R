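#' Hyperparameters for the dual-level CMF model
#'
#' Weights follow the recommended operating point: the two embedding weights
#' and the regularization weight at 1, the two projection weights at 0.01.
#'
#' @param alpha,beta Embedding weights for the 1D and 2D views.
#' @param eta,gamma Projection weights for the 1D and 2D views.
#' @param zeta Ridge regularization weight (must be > 0 for the closed-form
#'   updates to exist).
#' @param r Latent dimension, `1 <= r < n`.
#' @param T Maximum number of alternating iterations.
#' @param tol Relative objective-change tolerance for early stopping.
#' @param seed Integer RNG seed for initialization and the random orthogonal
#'   complement of the V step.
#' @return A list of class `cmf_params`.
#' @export
cmf_params <- function(alpha = 1, beta = 1, eta = 0.01, gamma = 0.01,
                       zeta = 1, r = 16L, T = 50L, tol = 1e-4, seed = 1L) {
  stopifnot(alpha >= 0, beta >= 0, eta >= 0, gamma >= 0, zeta >= 0,
            r >= 1, T >= 1, tol >= 0)
  structure(list(alpha = alpha, beta = beta, eta = eta, gamma = gamma,
                 zeta = zeta, r = as.integer(r), T = as.integer(T),
                 tol = tol, seed = as.integer(seed)),
            class = "cmf_params")
}

#' Closed-form update of a feature loading matrix (U step)
#'
#' Solves `min_U w * ||X - U V||_F^2 + zeta * ||U||_F^2`, whose normal
#' equations give `U = w X V' (w V V' + zeta I)^{-1}`.
#'
#' @param X `d x n` feature matrix.
#' @param V `r x n` latent codes.
#' @param w Nonnegative view weight.
#' @param zeta Ridge weight (> 0 unless `w V V'` is itself invertible).
#' @return The `d x r` minimizer.
#' @export
update_feature_loading <- function(X, V, w, zeta) {
  stopifnot(ncol(X) == ncol(V), w >= 0, zeta >= 0)
  r <- nrow(V)
  if (w == 0) return(matrix(0, nrow(X), r))
  M <- w * tcrossprod(V) + diag(zeta, r)
  U <- tryCatch(t(solve(M, t(w * X %*% t(V)))),
                error = function(e) {
                  stop("singular system in the U update; use zeta > 0",
                       call. = FALSE)
                })
  U
}

#' Closed-form update of a latent projection matrix (W step)
#'
#' Solves `min_W w * ||W X - V||_F^2 + zeta * ||W||_F^2`, whose normal
#' equations give `W = w V X' (w X X' + zeta I)^{-1}`.
#'
#' @inheritParams update_feature_loading
#' @return The `r x d` minimizer.
#' @export
update_latent_loading <- function(X, V, w, zeta) {
  stopifnot(ncol(X) == ncol(V), w >= 0, zeta >= 0)
  d <- nrow(X)
  if (w == 0) return(matrix(0, nrow(V), d))
  M <- w * tcrossprod(X) + diag(zeta, d)
  W <- tryCatch(t(solve(M, t(w * V %*% t(X)))),
                error = function(e) {
                  stop("singular system in the W update; use zeta > 0",
                       call. = FALSE)
                })
  W
}

#' Update the dimensional attention weights (A step)
#'
#' Minimizes `||S - V' A V||_F^2` over diagonal `A`, where the label
#' similarity `S = G'G` is never materialized. The exact stationarity
#' condition is the linear system `M a = b` with
#' `M = (V V') \odot (V V')` and `b = diag((V G')(V G')')`; under the
#' orthogonality constraint `V V' = n I` this reduces to
#' `a = diag(V S V') / n^2`. A singular `M` falls back to the minimum-norm
#' pseudo-inverse solution.
#'
#' @param V `r x n` latent codes.
#' @param G `c x n` normalized label factor.
#' @return Length-`r` attention weight vector (the diagonal of `A`).
#' @export
update_attention <- function(V, G) {
  stopifnot(ncol(V) == ncol(G))
  VVt <- tcrossprod(V)
  M <- VVt * VVt
  H <- tcrossprod(V, G)          # V G', r x c
  b <- rowSums(H^2)              # diag(V S V')
  a <- tryCatch(as.numeric(solve(M, b)),
                error = function(e) {
                  message("attention system singular; using pseudo-inverse")
                  as.numeric(pinv(M) %*% b)
                })
  a
}

#' Assemble the V-step score matrix
#'
#' `Z = alpha U1' X1 + beta U2' X2 + eta W1 X1 + gamma W2 X2`, the linear
#' coefficient of the trace objective maximized by the constrained V step.
#'
#' @param model A fitted or in-progress `dlcmf` model (uses `U1`, `U2`,
#'   `W1`, `W2`).
#' @param X1,X2 Feature matrices.
#' @param params A [cmf_params()].
#' @return The `r x n` score matrix.
#' @export
assemble_score <- function(model, X1, X2, params) {
  params$alpha * crossprod(model$U1, X1) +
    params$beta  * crossprod(model$U2, X2) +
    params$eta   * model$W1 %*% X1 +
    params$gamma * model$W2 %*% X2
}

#' Constrained latent update (V step)
#'
#' Maximizes `Tr(Z V')` subject to `V V' = n I_r` and `V 1_n = 0_r`. With
#' the centering matrix `J = I - (1/n) 11'` (never materialized; centering is
#' done by subtracting row means), the solution is built from the
#' eigendecomposition of the symmetrized `Z J Z'`: eigenvectors with positive
#' eigenvalues form `Q`, the remaining (already orthonormal) eigenvectors
#' form `Qbar`, `Ueig = J Z' Q Omega^{-1/2}`, and `Ubar` is a random
#' orthonormal block drawn inside the orthogonal complement of
#' `span{Ueig, 1}` so the balance constraint survives. Then
#' `V = sqrt(n) [Q Qbar] [Ueig Ubar]'`.
#'
#' @param Z `r x n` score matrix with `r < n`.
#' @param seed Optional seed for the random orthonormal complement (only
#'   consulted when the positive-eigenvalue rank is below `r`).
#' @return The `r x n` maximizer, satisfying both constraints to near
#'   machine precision.
#' @export
update_latent <- function(Z, seed = NULL) {
  r <- nrow(Z); n <- ncol(Z)
  if (r >= n) stop("latent dimension r must be smaller than n")
  if (!all(is.finite(Z))) stop("non-finite score matrix Z")
  Zc <- Z - rowMeans(Z)                    # Z J, centering without J
  M <- tcrossprod(Zc)                      # Z J Z'  (J idempotent)
  M <- (M + t(M)) / 2
  e <- eigen(M, symmetric = TRUE)
  ev_tol <- 1e-10 * max(e$values[1], 0)
  pos <- which(e$values > max(ev_tol, .Machine$double.eps))
  r_pos <- length(pos)
  Q <- e$vectors[, pos, drop = FALSE]
  Qbar <- e$vectors[, setdiff(seq_len(r), pos), drop = FALSE]
  if (r_pos > 0) {
    Ueig <- crossprod(Zc, Q) %*% diag(1 / sqrt(e$values[pos]), r_pos)
  } else {
    Ueig <- matrix(0, n, 0)
  }
  r_def <- r - r_pos
  if (r_def > 0) {
    if (r_pos == 0) {
      message("rank-0 score matrix in the V step: ",
              "returning a random feasible point")
    }
    Ubar <- with_seed(seed, {
      R <- matrix(rnorm(n * r_def), n, r_def)
      B <- cbind(Ueig, rep(1 / sqrt(n), n))
      R <- R - B %*% crossprod(B, R)       # project off span{Ueig, 1}
      Qr <- qr.Q(qr(R))[, seq_len(r_def), drop = FALSE]
      # second projection pass for numerical safety
      Qr <- Qr - B %*% crossprod(B, Qr)
      qr.Q(qr(Qr))[, seq_len(r_def), drop = FALSE]
    })
  } else {
    Ubar <- matrix(0, n, 0)
  }
  V <- sqrt(n) * tcrossprod(cbind(Q, Qbar), cbind(Ueig, Ubar))
  V
}

#' Evaluate the full objective loss
#'
#' Sum of the two embedding residuals, the two projection residuals, the
#' attention similarity term and the ridge penalty:
#' `alpha||X1 - U1 V||^2 + beta||X2 - U2 V||^2 + eta||W1 X1 - V||^2 +
#'  gamma||W2 X2 - V||^2 + ||S - V'AV||^2 + zeta(||U1||^2 + ||U2||^2 +
#'  ||W1||^2 + ||W2||^2)` (all squared Frobenius norms). The similarity term
#' is expanded through the factor `G` so the `n x n` matrix `S` is never
#' formed: `||S - V'AV||^2 = ||G G'||^2 - 2 tr(A (VG')(VG')') +
#' tr(A VV' A VV')`.
#'
#' @param model A `dlcmf` model (uses `U1`, `U2`, `W1`, `W2`, `A`, `V`).
#' @param X1,X2 Feature matrices.
#' @param G `c x n` label factor.
#' @param params A [cmf_params()].
#' @return Scalar loss.
#' @export
cmf_objective <- function(model, X1, X2, G, params) {
  V <- model$V
  a <- model$A
  fit1 <- sum((X1 - model$U1 %*% V)^2)
  fit2 <- sum((X2 - model$U2 %*% V)^2)
  proj1 <- sum((model$W1 %*% X1 - V)^2)
  proj2 <- sum((model$W2 %*% X2 - V)^2)
  GGt <- tcrossprod(G)                     # c x c
  H <- tcrossprod(V, G)                    # r x c
  VVt <- tcrossprod(V)
  s_term <- sum(GGt^2) - 2 * sum(a * rowSums(H^2)) +
    as.numeric(t(a) %*% (VVt * VVt) %*% a)
  reg <- sum(model$U1^2) + sum(model$U2^2) + sum(model$W1^2) + sum(model$W2^2)
  params$alpha * fit1 + params$beta * fit2 +
    params$eta * proj1 + params$gamma * proj2 +
    s_term + params$zeta * reg
}

#' Fit the dual-level collective matrix factorization model
#'
#' Alternating optimization over six sub-problems per iteration, in order:
#' `U1`, `U2`, `A`, `W1`, `W2`, `V`. The `U`/`W` steps are closed-form ridge
#' solutions, the `A` step solves its diagonal stationarity system, and the
#' `V` step is the constrained trace maximization of [update_latent()].
#' Iterations stop after `params$T` rounds or when the relative change of
#' the full objective drops below `params$tol`.
#'
#' @param X1 `d1 x n` 1D feature matrix (beats in columns).
#' @param X2 `d2 x n` 2D feature matrix, column-aligned with `X1`.
#' @param y Integer subject labels in `1..c`, one per column.
#' @param params A [cmf_params()]; `params$r` must be `< n`.
#' @param attention If `FALSE`, the attention weights are frozen at 1
#'   (ablation of dimensional attention learning).
#' @return An object of class `dlcmf` with elements `U1`, `U2`, `W1`, `W2`,
#'   `A` (length-`r` vector), `V`, `objective_trace`, `params`, `m`
#'   (RPM side if known) and `label_info`.
#' @export
cmf_fit <- function(X1, X2, y, params = cmf_params(), attention = TRUE) {
  stopifnot(ncol(X1) == ncol(X2), ncol(X1) == length(y))
  n <- ncol(X1)
  r <- params$r
  if (r >= n) stop("latent dimension r must be smaller than n")
  li <- build_label_factor(y)
  G <- li$G
  model <- with_seed(params$seed, {
    m0 <- list(
      U1 = matrix(rnorm(nrow(X1) * r), nrow(X1), r) / sqrt(r),
      U2 = matrix(rnorm(nrow(X2) * r), nrow(X2), r) / sqrt(r),
      W1 = matrix(rnorm(r * nrow(X1)), r, nrow(X1)) / sqrt(r),
      W2 = matrix(rnorm(r * nrow(X2)), r, nrow(X2)) / sqrt(r),
      A = rep(1, r),
      V = update_latent(matrix(rnorm(r * n), r, n))
    )
    # the W-step system matrix (w X X' + zeta I) is constant across
    # iterations; factor it once so each pass stays linear in n
    solve_w <- function(X, w) {
      if (w == 0) return(function(V) matrix(0, nrow(V), nrow(X)))
      ch <- chol(w * tcrossprod(X) + diag(params$zeta, nrow(X)))
      function(V) t(backsolve(ch, backsolve(ch, t(w * tcrossprod(V, X)),
                                            transpose = TRUE)))
    }
    w1_solve <- solve_w(X1, params$eta)
    w2_solve <- solve_w(X2, params$gamma)
    trace <- numeric(0)
    prev <- Inf
    for (it in seq_len(params$T)) {
      m0$U1 <- stop_if_not_finite(
        update_feature_loading(X1, m0$V, params$alpha, params$zeta), "U1")
      m0$U2 <- stop_if_not_finite(
        update_feature_loading(X2, m0$V, params$beta, params$zeta), "U2")
      if (attention) {
        m0$A <- stop_if_not_finite(update_attention(m0$V, G), "A")
      }
      m0$W1 <- stop_if_not_finite(w1_solve(m0$V), "W1")
      m0$W2 <- stop_if_not_finite(w2_solve(m0$V), "W2")
      Z <- assemble_score(m0, X1, X2, params)
      m0$V <- stop_if_not_finite(update_latent(Z), "V")
      obj <- cmf_objective(m0, X1, X2, G, params)
      trace <- c(trace, obj)
      if (is.finite(prev) && prev > 0 &&
          abs(prev - obj) / abs(prev) < params$tol) {
        prev <- obj
        break
      }
      prev <- obj
    }
    m0$objective_trace <- trace
    m0
  })
  model$params <- params
  model$attention <- attention
  model$label_info <- li
  class(model) <- "dlcmf"
  model
}

#' @export
print.dlcmf <- function(x, ...) {
  cat(sprintf(paste0(
    "<dlcmf> r = %d latent dimensions, n = %d training beats, c = %d ",
    "subjects\n  d1 = %d, d2 = %d; %d iterations, final objective %.6g\n"),
    nrow(x$V), ncol(x$V), x$label_info$c, nrow(x$U1), nrow(x$U2),
    length(x$objective_trace),
    x$objective_trace[length(x$objective_trace)]))
  invisible(x)
}
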