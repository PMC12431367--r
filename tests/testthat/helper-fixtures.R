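# Random feasible point of the V-step constraint set:
# rows orthogonal with VV' = nI and V1 = 0.
rand_feasible <- function(r, n) {
  M <- matrix(rnorm(n * r), n, r)
  M <- sweep(M, 2, colMeans(M))            # columns centered -> V1 = 0
  sqrt(n) * t(qr.Q(qr(M))[, seq_len(r), drop = FALSE])
}

# Naive objective that materializes the n x n similarity S explicitly;
# the independent oracle for the G-factored evaluation.
naive_objective <- function(model, X1, X2, G, params) {
  V <- model$V
  S <- crossprod(G)
  params$alpha * sum((X1 - model$U1 %*% V)^2) +
    params$beta  * sum((X2 - model$U2 %*% V)^2) +
    params$eta   * sum((model$W1 %*% X1 - V)^2) +
    params$gamma * sum((model$W2 %*% X2 - V)^2) +
    sum((S - t(V) %*% diag(model$A, nrow(V)) %*% V)^2) +
    params$zeta * (sum(model$U1^2) + sum(model$U2^2) +
                     sum(model$W1^2) + sum(model$W2^2))
}

# Column-by-column ridge solution through the augmented least-squares
# system, independent of the closed-form normal-equation path.
ridge_oracle_U <- function(X, V, w, zeta) {
  r <- nrow(V)
  design <- rbind(sqrt(w) * t(V), diag(sqrt(zeta), r))
  t(apply(X, 1, function(xi) {
    stats::lm.fit(design, c(sqrt(w) * xi, rep(0, r)))$coefficients
  }))
}

ridge_oracle_W <- function(X, V, w, zeta) {
  d <- nrow(X)
  design <- rbind(sqrt(w) * t(X), diag(sqrt(zeta), d))
  t(apply(V, 1, function(vi) {
    stats::lm.fit(design, c(sqrt(w) * vi, rep(0, d)))$coefficients
  }))
}

# Small labelled beat set for pipeline-level tests.
tiny_dataset <- function(seed = 3L, c = 4L, beats = 12L, L = 120L) {
  synth_dataset(synth_config(c = c, beats_per_subject = beats, L = L,
                             fs = 360, seed = seed))
}
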