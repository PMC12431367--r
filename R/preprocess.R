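#' Single-lead ECG record
#'
#' A light container for a continuous voltage series with its sampling rate.
#'
#' @param samples Numeric voltage series (mV), length at least 2.
#' @param fs Sampling rate in Hz, positive.
#' @param lead Free-text lead label.
#' @return An object of class `ecg_record`.
#' @export
ecg_record <- function(samples, fs, lead = "I") {
  samples <- as.numeric(samples)
  if (length(samples) < 2) stop("an ECG record needs at least 2 samples")
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 0) stop("fs must be > 0")
  structure(list(samples = samples, fs = fs, lead = as.character(lead)),
            class = "ecg_record")
}

#' @export
print.ecg_record <- function(x, ...) {
  cat(sprintf("<ecg_record> lead %s: %d samples at %g Hz (%.1f s)\n",
              x$lead, length(x$samples), x$fs, length(x$samples) / x$fs))
  invisible(x)
}

#' Fixed-length heartbeat matrix
#'
#' Rows are heartbeats of identical length `L`; the unit of all downstream
#' feature extraction.
#'
#' @param beats Numeric matrix, one row per beat (may have 0 rows).
#' @param fs Sampling rate in Hz.
#' @param r_index Optional per-beat R-peak sample index in the source record.
#' @return An object of class `beat_matrix`.
#' @export
beat_matrix <- function(beats, fs, r_index = NULL) {
  beats <- as.matrix(beats)
  if (ncol(beats) < 1) stop("beat length L must be positive")
  if (!is.null(r_index) && length(r_index) != nrow(beats)) {
    stop("r_index length must match the number of beats")
  }
  structure(list(beats = beats, fs = fs,
                 r_index = if (is.null(r_index)) integer(0) else
                   as.integer(r_index)),
            class = "beat_matrix")
}

#' @export
print.beat_matrix <- function(x, ...) {
  cat(sprintf("<beat_matrix> %d beats x %d samples at %g Hz\n",
              nrow(x$beats), ncol(x$beats), x$fs))
  invisible(x)
}

#' @export
dim.beat_matrix <- function(x) dim(x$beats)

#' Detect R peaks with the Pan-Tompkins algorithm
#'
#' Classic parameterization: 5-15 Hz Butterworth band-pass, five-point
#' derivative, squaring, 150 ms moving-window integration, adaptive dual
#' thresholds with a 200 ms refractory period. All linear stages are applied
#' zero-phase so the integrated envelope stays aligned with the QRS; each
#' detection is then refined to the raw-signal maximum within +/- 25 ms.
#'
#' @param record An [ecg_record()].
#' @return Strictly increasing integer vector of R-peak sample indices
#'   (1-based); empty for a flat signal.
#' @export
detect_r_peaks <- function(record) {
  stopifnot(inherits(record, "ecg_record"))
  x <- record$samples
  fs <- record$fs
  n <- length(x)
  win <- max(round(0.150 * fs), 3L)          # integration window
  if (n < max(2L * win, round(0.5 * fs), 24L)) {
    stop("record shorter than the detector warm-up; need at least ",
         max(2L * win, round(0.5 * fs), 24L), " samples", call. = FALSE)
  }
  if (stats::sd(x) == 0) return(integer(0))

  # band-pass 5-15 Hz (2nd order Butterworth, zero phase)
  bp <- signal::butter(2, c(5, 15) / (fs / 2), type = "pass")
  xf <- signal::filtfilt(bp, x)
  # centred five-point derivative (zero phase variant of the classic kernel)
  d <- stats::filter(xf, c(1, 2, 0, -2, -1) / 8, sides = 2)
  d[is.na(d)] <- 0
  sq <- as.numeric(d)^2
  # centred moving-window integration, 150 ms
  mwi <- stats::filter(sq, rep(1 / win, win), sides = 2)
  mwi[is.na(mwi)] <- 0
  mwi <- as.numeric(mwi)

  refractory <- round(0.200 * fs)
  cand <- local_maxima(mwi, min_dist = refractory)
  if (length(cand) == 0) return(integer(0))

  # adaptive dual thresholds (signal/noise running estimates)
  warm <- cand[cand <= min(n, round(2 * fs))]
  spki <- if (length(warm)) max(mwi[warm]) * 0.5 else max(mwi[cand]) * 0.5
  npki <- if (length(warm)) mean(mwi[warm]) * 0.5 else 0
  accepted <- integer(0)
  for (p in cand) {
    thr <- npki + 0.25 * (spki - npki)
    if (mwi[p] > thr) {
      accepted <- c(accepted, p)
      spki <- 0.125 * mwi[p] + 0.875 * spki
    } else {
      npki <- 0.125 * mwi[p] + 0.875 * npki
    }
  }
  if (length(accepted) == 0) return(integer(0))

  # refine to the raw-signal apex within +/- 25 ms
  half <- round(0.025 * fs)
  peaks <- vapply(accepted, function(p) {
    lo <- max(1L, p - half); hi <- min(n, p + half)
    as.integer(lo + which.max(x[lo:hi]) - 1L)
  }, integer(1))
  peaks <- sort(unique(peaks))
  # enforce the refractory period after refinement
  if (length(peaks) > 1) {
    keep <- c(TRUE, diff(peaks) >= refractory)
    while (!all(keep)) {
      peaks <- peaks[keep]
      keep <- c(TRUE, diff(peaks) >= refractory)
    }
  }
  as.integer(peaks)
}

# Local maxima separated by at least `min_dist` samples (greedy by height).
local_maxima <- function(v, min_dist) {
  n <- length(v)
  if (n < 3) return(integer(0))
  idx <- which(v[2:(n - 1)] > v[1:(n - 2)] & v[2:(n - 1)] >= v[3:n]) + 1L
  idx <- idx[v[idx] > 0]
  if (length(idx) <= 1) return(idx)
  ord <- idx[order(v[idx], decreasing = TRUE)]
  taken <- integer(0)
  for (p in ord) {
    if (all(abs(taken - p) >= min_dist)) taken <- c(taken, p)
  }
  sort(taken)
}

#' Segment a record into fixed-length beats around detected R peaks
#'
#' Each retained beat is the half-open window `[p - left, p + right)` of the
#' raw record (no filtering is applied to the stored amplitudes); beats whose
#' window crosses a record boundary are dropped.
#'
#' @param record An [ecg_record()].
#' @param peaks Integer R-peak indices (1-based), e.g. from
#'   [detect_r_peaks()].
#' @param left,right Samples kept to the left/right of each peak;
#'   `L = left + right`.
#' @return A [beat_matrix()] with `L = left + right` columns.
#' @export
segment_beats <- function(record, peaks, left = 130L, right = 130L) {
  stopifnot(inherits(record, "ecg_record"), left >= 0, right >= 1)
  L <- as.integer(left + right)
  n_rec <- length(record$samples)
  peaks <- as.integer(peaks)
  keep <- peaks - left >= 1L & peaks + right - 1L <= n_rec
  kept <- peaks[keep]
  B <- matrix(0, length(kept), L)
  for (i in seq_along(kept)) {
    B[i, ] <- record$samples[(kept[i] - left):(kept[i] + right - 1L)]
  }
  beat_matrix(B, fs = record$fs, r_index = kept)
}
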