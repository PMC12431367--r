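#' Project out-of-sample features into the latent space
#'
#' Representations of query or enrollment beats are the exact matrix
#' products `W1 X1` and `W2 X2` -- no normalization is applied.
#'
#' @param model A fitted [cmf_fit()] model.
#' @param X1q,X2q Feature matrices of the out-of-sample beats (columns).
#' @return A list with `rep_1d` and `rep_2d`, both `r x m` matrices.
#' @export
project <- function(model, X1q, X2q) {
  if (nrow(X1q) != ncol(model$W1)) {
    stop(sprintf("X1 has %d rows but W1 expects %d", nrow(X1q),
                 ncol(model$W1)), call. = FALSE)
  }
  if (nrow(X2q) != ncol(model$W2)) {
    stop(sprintf("X2 has %d rows but W2 expects %d", nrow(X2q),
                 ncol(model$W2)), call. = FALSE)
  }
  list(rep_1d = model$W1 %*% X1q, rep_2d = model$W2 %*% X2q)
}

#' Gallery/probe container
#'
#' Holds latent representations (both domains) and subject labels for the
#' enrolled gallery and the probe set.
#'
#' @param enroll Projection list (from [project()]) for enrolled beats.
#' @param enroll_labels Integer subject labels of the enrolled beats.
#' @param probe Projection list for probe beats.
#' @param probe_labels Integer subject labels of the probe beats.
#' @return A list of class `gallery_probe`.
#' @export
gallery_probe <- function(enroll, enroll_labels, probe, probe_labels) {
  stopifnot(ncol(enroll$rep_1d) == length(enroll_labels),
            ncol(probe$rep_1d) == length(probe_labels),
            nrow(enroll$rep_1d) == nrow(probe$rep_1d),
            nrow(enroll$rep_2d) == nrow(probe$rep_2d))
  structure(list(enroll_reps_1d = enroll$rep_1d,
                 enroll_reps_2d = enroll$rep_2d,
                 probe_reps_1d = probe$rep_1d,
                 probe_reps_2d = probe$rep_2d,
                 enroll_labels = as.integer(enroll_labels),
                 probe_labels = as.integer(probe_labels)),
            class = "gallery_probe")
}

# Probe x enroll distance matrices for each domain (Euclidean).
.domain_dists <- function(gp) {
  list(d1 = .euclid(gp$probe_reps_1d, gp$enroll_reps_1d),
       d2 = .euclid(gp$probe_reps_2d, gp$enroll_reps_2d))
}

.euclid <- function(P, E) {
  d2 <- outer(colSums(P^2), colSums(E^2), "+") - 2 * crossprod(P, E)
  sqrt(pmax(d2, 0))
}

#' Fused probe-enroll distance
#'
#' Distance between probe `i` and enrolled sample `j`: the Euclidean
#' distances in the 1D and 2D representation domains, fused by summation
#' (default), or a single domain under the `"1d"` / `"2d"` fusion modes.
#'
#' @param gp A [gallery_probe()].
#' @param i Probe column index.
#' @param j Enroll column index.
#' @param fusion One of `"sum"`, `"1d"`, `"2d"`.
#' @return Nonnegative scalar.
#' @export
pair_distance <- function(gp, i, j, fusion = "sum") {
  d1 <- sqrt(sum((gp$probe_reps_1d[, i] - gp$enroll_reps_1d[, j])^2))
  d2 <- sqrt(sum((gp$probe_reps_2d[, i] - gp$enroll_reps_2d[, j])^2))
  switch(fusion, sum = d1 + d2, `1d` = d1, `2d` = d2,
         stop("unknown fusion mode: ", fusion))
}

# Full fused distance matrix (probe x enroll); vectorized pair_distance.
fused_distances <- function(gp, fusion = "sum") {
  dd <- .domain_dists(gp)
  switch(fusion,
         sum = dd$d1 + dd$d2,
         `1d` = dd$d1,
         `2d` = dd$d2,
         stop("unknown fusion mode: ", fusion))
}

#' Closed-set identification
#'
#' Each probe is assigned the subject of its nearest enrolled sample under
#' the fused distance; ties go to the smallest enrolled index.
#'
#' @inheritParams pair_distance
#' @return Integer vector of predicted subject labels, one per probe.
#' @export
identify <- function(gp, fusion = "sum") {
  if (length(gp$enroll_labels) < 1) stop("empty gallery")
  D <- fused_distances(gp, fusion)
  gp$enroll_labels[apply(D, 1, which.min)]
}

#' Verification scores (genuine and impostor)
#'
#' For each probe and each claimed subject, the score is minus the smallest
#' fused distance to that subject's enrolled samples (higher = more similar).
#' Claims matching the probe's true subject are genuine, all others
#' impostor.
#'
#' @inheritParams pair_distance
#' @return A list with numeric vectors `genuine` and `impostor`.
#' @export
verification_scores <- function(gp, fusion = "sum") {
  D <- fused_distances(gp, fusion)
  subjects <- sort(unique(gp$enroll_labels))
  n_p <- nrow(D)
  score <- matrix(0, n_p, length(subjects))
  for (k in seq_along(subjects)) {
    cols <- gp$enroll_labels == subjects[k]
    score[, k] <- -apply(D[, cols, drop = FALSE], 1, min)
  }
  truth <- outer(gp$probe_labels, subjects, "==")
  list(genuine = score[truth], impostor = score[!truth])
}

#' Equal error rate and FAR/FRR curves
#'
#' Sweeps the acceptance threshold over the pooled score set. At threshold
#' `t`, `FAR(t)` is the fraction of impostor scores `>= t` and `FRR(t)` the
#' fraction of genuine scores `< t`. The EER is the common rate where the
#' curves cross, linearly interpolated between adjacent thresholds.
#'
#' @param genuine,impostor Numeric score vectors (higher = more similar).
#' @return A list with `eer` (percent), `threshold`, and a data frame
#'   `curve` with columns `threshold`, `far`, `frr` (fractions in `[0,1]`).
#' @export
eer <- function(genuine, impostor) {
  if (length(genuine) == 0 || length(impostor) == 0) {
    stop("need non-empty genuine and impostor score lists")
  }
  thr <- sort(unique(c(genuine, impostor)))
  # sentinel above every score so FAR can reach 0 and FRR can reach 1
  thr <- c(thr, thr[length(thr)] + 1)
  far <- vapply(thr, function(t) mean(impostor >= t), numeric(1))
  frr <- vapply(thr, function(t) mean(genuine < t), numeric(1))
  diff_fr <- far - frr                     # non-increasing in t
  k <- which(diff_fr <= 0)[1]
  if (is.na(k)) {                          # curves never cross in range
    eer_val <- far[length(far)]
    t_star <- thr[length(thr)]
  } else if (k == 1 || diff_fr[k] == 0) {
    eer_val <- (far[k] + frr[k]) / 2
    t_star <- thr[k]
  } else {
    d1 <- diff_fr[k - 1]; d2 <- diff_fr[k]
    wgt <- d1 / (d1 - d2)
    eer_far <- far[k - 1] + wgt * (far[k] - far[k - 1])
    eer_frr <- frr[k - 1] + wgt * (frr[k] - frr[k - 1])
    eer_val <- (eer_far + eer_frr) / 2
    t_star <- thr[k - 1] + wgt * (thr[k] - thr[k - 1])
  }
  list(eer = 100 * eer_val, threshold = t_star,
       curve = data.frame(threshold = thr, far = far, frr = frr))
}

#' ROC area under the curve
#'
#' The probability that a random genuine score exceeds a random impostor
#' score, ties counted one half; identical to trapezoidal integration of the
#' ROC curve. Computed by the rank statistic.
#'
#' @inheritParams eer
#' @return Scalar AUC in `[0, 1]`.
#' @export
roc_auc <- function(genuine, impostor) {
  if (length(genuine) == 0 || length(impostor) == 0) {
    stop("need non-empty genuine and impostor score lists")
  }
  ng <- length(genuine); ni <- length(impostor)
  rk <- rank(c(genuine, impostor), ties.method = "average")
  (sum(rk[seq_len(ng)]) - ng * (ng + 1) / 2) / (ng * ni)
}

#' ROC curve points
#'
#' True-positive rate (1 - FRR) against false-positive rate (FAR) over the
#' pooled threshold sweep, for plotting.
#'
#' @inheritParams eer
#' @return A data frame with columns `fpr` and `tpr`.
#' @export
roc_curve <- function(genuine, impostor) {
  e <- eer(genuine, impostor)
  data.frame(fpr = c(1, e$curve$far, 0), tpr = c(1, 1 - e$curve$frr, 0))
}
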