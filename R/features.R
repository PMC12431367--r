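#' Extract 1D amplitude features
#'
#' The 1D feature of a heartbeat is its raw amplitude series: column `i` of
#' the returned matrix is beat `i` verbatim. For 260-sample beats the feature
#' dimension is 260; for 460-sample beats it is 460.
#'
#' @param beats A [beat_matrix()].
#' @return A `L x n` numeric matrix `X1` (features in rows, beats in columns).
#' @export
extract_1d <- function(beats) {
  stopifnot(inherits(beats, "beat_matrix"))
  t(beats$beats)
}

#' Piecewise aggregate approximation (PAA)
#'
#' Downsamples a series of length `L` to length `m` by frame means. When `m`
#' divides `L` the frames are equal blocks; otherwise boundary samples are
#' split between adjacent frames with fractional weights so every input
#' sample contributes total weight 1.
#'
#' @param series Numeric vector of length `L`.
#' @param m Target length, `1 <= m <= L`.
#' @return Numeric vector of length `m`.
#' @export
paa <- function(series, m) {
  L <- length(series)
  m <- as.integer(m)
  if (m < 1 || m > L) stop("paa: need 1 <= m <= L (m = ", m, ", L = ", L, ")")
  if (m == L) return(as.numeric(series))
  out <- numeric(m)
  step <- L / m
  for (j in seq_len(m)) {
    a <- (j - 1) * step            # frame on the continuous axis [0, L)
    b <- j * step
    lo <- floor(a) + 1L            # first sample touching the frame
    hi <- ceiling(b)               # last sample touching the frame
    w <- pmin(seq(lo, hi), b) - pmax(seq(lo, hi) - 1, a)
    out[j] <- sum(series[lo:hi] * w) / step
  }
  out
}

#' Relative position matrix of a series
#'
#' The 2D "image" encoding of a (downsampled) time series: entry `(i, j)` is
#' the signed difference `x_i - x_j`. The matrix is antisymmetric with a zero
#' diagonal; the raw differences are kept unscaled.
#'
#' @param series Numeric vector of length `m`.
#' @return An `m x m` numeric matrix.
#' @export
relative_position_matrix <- function(series) {
  series <- as.numeric(series)
  if (length(series) < 1) stop("series must be non-empty")
  outer(series, series, "-")
}

# Default RPM side length for a beat of length L. Presets reproduce the
# standard dataset configurations (260 -> 26, so d2 = 676; 460 -> 39, so
# d2 = 1521); otherwise fall back to roughly a tenth of the window.
rpm_side_default <- function(L) {
  if (L == 260L) return(26L)
  if (L == 460L) return(39L)
  max(2L, as.integer(floor(L / 10)))
}

#' Extract 2D relative-position features
#'
#' Each beat is PAA-downsampled to length `m`, converted to its `m x m`
#' relative position matrix, and flattened row-major into a `d2 = m^2`
#' column, aligned column-for-column with the 1D features.
#'
#' @param beats A [beat_matrix()].
#' @param m Side length of the relative position matrix; defaults to 26 for
#'   260-sample beats and 39 for 460-sample beats.
#' @return A `m^2 x n` numeric matrix `X2`.
#' @export
extract_2d <- function(beats, m = NULL) {
  stopifnot(inherits(beats, "beat_matrix"))
  L <- ncol(beats$beats)
  m <- as.integer(m %||% rpm_side_default(L))
  n <- nrow(beats$beats)
  X2 <- matrix(0, m * m, n)
  for (i in seq_len(n)) {
    R <- relative_position_matrix(paa(beats$beats[i, ], m))
    X2[, i] <- as.vector(t(R))   # row-major flatten, fixed order
  }
  attr(X2, "m") <- m
  X2
}

#' Dual-level feature pair
#'
#' Convenience wrapper producing aligned `X1` (1D) and `X2` (2D) feature
#' matrices from one beat matrix.
#'
#' @inheritParams extract_2d
#' @return A list of class `feature_pair` with elements `X1`, `X2`, `d1`,
#'   `d2`, `n`, `m`.
#' @export
extract_features <- function(beats, m = NULL) {
  X1 <- extract_1d(beats)
  X2 <- extract_2d(beats, m)
  structure(list(X1 = X1, X2 = X2, d1 = nrow(X1), d2 = nrow(X2),
                 n = ncol(X1), m = attr(X2, "m")),
            class = "feature_pair")
}

#' @export
print.feature_pair <- function(x, ...) {
  cat(sprintf("<feature_pair> n = %d beats; d1 = %d, d2 = %d (m = %d)\n",
              x$n, x$d1, x$d2, x$m))
  invisible(x)
}

#' Build the normalized label factor G
#'
#' From subject labels `y` builds the binary label matrix `L` (`n x c`) and
#' its column-normalized factor `G` (`c x n`) such that the pairwise
#' similarity `S = G'G` is block structured -- `1/n_j` for two samples of the
#' same subject `j` (with `n_j` samples), `0` across subjects -- without ever
#' materializing the `n x n` matrix `S`.
#'
#' @param y Integer subject labels in `1..c`.
#' @param c Number of subjects; defaults to `max(y)`. Every subject in
#'   `1..c` must occur at least once.
#' @return A list of class `label_info` with `L` (`n x c` binary), `G`
#'   (`c x n`), `c`, `y`, and per-subject counts `n_j`.
#' @export
build_label_factor <- function(y, c = max(y)) {
  y <- as.integer(y)
  c <- as.integer(c)
  if (any(y < 1L | y > c)) stop("labels must lie in 1..c")
  n_j <- tabulate(y, nbins = c)
  if (any(n_j == 0L)) {
    stop("empty class: subject(s) ", paste(which(n_j == 0L), collapse = ", "),
         " have no samples; normalization undefined")
  }
  n <- length(y)
  L <- matrix(0L, n, c)
  L[cbind(seq_len(n), y)] <- 1L
  G <- matrix(0, c, n)
  G[cbind(y, seq_len(n))] <- 1 / sqrt(n_j[y])
  structure(list(L = L, G = G, c = c, y = y, n_j = n_j),
            class = "label_info")
}
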