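#' Configuration for the synthetic ECG generator
#'
#' Defines a population of synthetic subjects, each with a stable heartbeat
#' morphology (P, Q, R, S, T waves as Gaussian bumps) that is distinct across
#' subjects. The defaults mirror a 360 Hz single-lead setting with 260-sample
#' beat windows: 10 subjects, 40 beats per subject, additive Gaussian noise of
#' 0.02 mV and beat-to-beat jitter of 0.5% of the window.
#'
#' @param c Number of subjects.
#' @param beats_per_subject Beats generated per subject.
#' @param L Samples per beat window.
#' @param fs Sampling rate in Hz.
#' @param noise_sd Additive white-noise standard deviation (mV).
#' @param jitter_sd Beat-to-beat jitter of wave centers, as a fraction of the
#'   beat window.
#' @param separation Scale of between-subject morphology dispersion; 0 makes
#'   all subjects identical.
#' @param seed Integer seed; all generator randomness flows from it.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(c = 10, beats_per_subject = 40, L = 260, fs = 360,
                         noise_sd = 0.02, jitter_sd = 0.005,
                         separation = 1.0, seed = 1L) {
  stopifnot(c >= 1, beats_per_subject >= 1, L >= 1, fs > 0,
            noise_sd >= 0, jitter_sd >= 0, separation >= 0)
  structure(list(c = as.integer(c),
                 beats_per_subject = as.integer(beats_per_subject),
                 L = as.integer(L), fs = fs, noise_sd = noise_sd,
                 jitter_sd = jitter_sd, separation = separation,
                 seed = as.integer(seed)),
            class = "synth_config")
}

# Canonical wave parameters: center and width as fractions of the beat
# window (R apex at the midpoint), amplitude in mV.
.wave_canon <- function() {
  data.frame(
    wave   = c("P", "Q", "R", "S", "T"),
    center = c(0.28, 0.465, 0.50, 0.535, 0.72),
    width  = c(0.030, 0.009, 0.012, 0.010, 0.055),
    amp    = c(0.15, -0.12, 1.00, -0.25, 0.35)
  )
}

#' Draw a population of subject heartbeat templates
#'
#' Each template perturbs the canonical P/Q/R/S/T wave parameters by an amount
#' proportional to `separation`, keeping the R wave dominant, centers ordered
#' P < Q < R < S < T, and widths positive.
#'
#' @param cfg A [synth_config()].
#' @return A list of `c` subject templates (class `subject_template`), each a
#'   data frame of wave parameters plus a `subject` attribute.
#' @export
make_population <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  with_seed(cfg$seed, {
    lapply(seq_len(cfg$c), function(j) .draw_template(j, cfg$separation))
  })
}

.draw_template <- function(subject, separation) {
  w <- .wave_canon()
  k <- separation
  # relative amplitude scatter on non-R waves, small center/width scatter;
  # bounds keep the morphology invariants whatever `separation` is.
  for (i in seq_len(nrow(w))) {
    if (w$wave[i] == "R") {
      w$amp[i] <- w$amp[i] * (1 + 0.05 * k * max(min(rnorm(1), 1.5), -1.5))
    } else {
      w$amp[i] <- w$amp[i] * (1 + 0.35 * k * max(min(rnorm(1), 1.8), -1.8))
      if (abs(w$amp[i]) > 0.8 * abs(w$amp[w$wave == "R"])) {
        w$amp[i] <- sign(w$amp[i]) * 0.8 * abs(w$amp[w$wave == "R"])
      }
    }
    w$width[i] <- w$width[i] * exp(0.25 * k * max(min(rnorm(1), 1.5), -1.5))
    shift <- if (w$wave[i] %in% c("P", "T")) 0.035 else 0.006
    w$center[i] <- w$center[i] + shift * k * max(min(rnorm(1), 1.5), -1.5)
  }
  # enforce strict center ordering by projecting onto the ordered cone
  w$center <- cummax_strict(w$center, gap = 0.012)
  structure(w, subject = subject, class = c("subject_template", class(w)))
}

# Monotone projection with a minimum gap; keeps P<Q<R<S<T strictly ordered.
cummax_strict <- function(x, gap) {
  for (i in seq_along(x)[-1]) x[i] <- max(x[i], x[i - 1] + gap)
  x
}

#' Synthesize a single heartbeat from a subject template
#'
#' The beat is a sum of Gaussian bumps, one per wave component, with wave
#' centers jittered by `jitter_sd` and i.i.d. Gaussian noise of `noise_sd`
#' added. The R apex lands within the jitter of the window midpoint.
#'
#' @param template A `subject_template` from [make_population()].
#' @param cfg A [synth_config()] (only `L`, `noise_sd`, `jitter_sd` are used).
#' @return Numeric vector of length `cfg$L` (mV).
#' @export
synth_beat <- function(template, cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  .synth_beat_core(template, cfg)$beat
}

# Shared kernel: returns the beat and the apex sample index of its noiseless
# version, so continuous records can report exact R ground truth.
.synth_beat_core <- function(template, cfg) {
  L <- cfg$L
  t <- (seq_len(L) - 0.5) / L
  clean <- numeric(L)
  for (i in seq_len(nrow(template))) {
    ci <- template$center[i] + rnorm(1, sd = cfg$jitter_sd)
    clean <- clean + template$amp[i] *
      exp(-0.5 * ((t - ci) / template$width[i])^2)
  }
  beat <- clean + rnorm(L, sd = cfg$noise_sd)
  list(beat = beat, apex = which.max(clean))
}

#' Generate a labelled synthetic heartbeat dataset
#'
#' @param cfg A [synth_config()].
#' @return A list with `beats` (a [beat_matrix()] of
#'   `c * beats_per_subject` rows) and `y` (integer subject labels in
#'   `1..c`, grouped by subject).
#' @export
synth_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  with_seed(cfg$seed, {
    templates <- lapply(seq_len(cfg$c), function(j)
      .draw_template(j, cfg$separation))
    n <- cfg$c * cfg$beats_per_subject
    B <- matrix(0, n, cfg$L)
    y <- integer(n)
    row <- 1L
    for (j in seq_len(cfg$c)) {
      for (b in seq_len(cfg$beats_per_subject)) {
        B[row, ] <- .synth_beat_core(templates[[j]], cfg)$beat
        y[row] <- j
        row <- row + 1L
      }
    }
    list(beats = beat_matrix(B, fs = cfg$fs), y = y)
  })
}

#' Generate a continuous synthetic ECG record with known R peaks
#'
#' Beats from one subject are placed at successive RR intervals (Gaussian
#' around `rr_mean`) on a zero baseline, then record-wide noise is added.
#' The exact R-apex sample indices of the noiseless beats are returned as
#' ground truth.
#'
#' @param template A `subject_template`.
#' @param n_beats Number of beats to place.
#' @param rr_mean,rr_sd RR-interval mean and standard deviation in seconds.
#' @param cfg A [synth_config()]; `rr_mean` must exceed the beat duration
#'   `L / fs`.
#' @return A list with `record` (an [ecg_record()]) and `r_true`
#'   (integer sample indices, 1-based).
#' @export
synth_record <- function(template, n_beats, rr_mean = 0.8, rr_sd = 0.04,
                         cfg = synth_config()) {
  stopifnot(inherits(cfg, "synth_config"), n_beats >= 1)
  if (rr_mean <= cfg$L / cfg$fs) {
    stop("rr_mean must exceed the beat duration L/fs", call. = FALSE)
  }
  with_seed(cfg$seed, {
    # truncated-Gaussian RR: jitter never shrinks an interval below the
    # beat window, so windows cannot overlap unless rr_mean itself is bad
    rr <- pmax(rnorm(n_beats - 1L, mean = rr_mean, sd = rr_sd),
               (cfg$L + 1) / cfg$fs)
    pad <- round(0.25 * cfg$fs)              # lead-in/out so windows fit
    starts <- round(c(0, cumsum(rr)) * cfg$fs) + 1L + pad
    if (n_beats > 1L && any(diff(starts) < cfg$L)) {
      stop("RR intervals too small: beat windows overlap", call. = FALSE)
    }
    len <- starts[n_beats] + cfg$L - 1L + pad
    sig <- numeric(len)
    r_true <- integer(n_beats)
    noise_cfg <- cfg
    noise_cfg$noise_sd <- 0  # noise is added record-wide below
    for (b in seq_len(n_beats)) {
      bb <- .synth_beat_core(template, noise_cfg)
      idx <- starts[b]:(starts[b] + cfg$L - 1L)
      sig[idx] <- sig[idx] + bb$beat
      r_true[b] <- starts[b] + bb$apex - 1L
    }
    sig <- sig + rnorm(len, sd = cfg$noise_sd)
    list(record = ecg_record(sig, fs = cfg$fs, lead = "synthetic"),
         r_true = r_true)
  })
}

#' Nearest-template classification oracle
#'
#' Classifies each beat to the subject whose mean training beat (template)
#' is nearest in Euclidean distance. Beats are aligned on their R apex
#' (largest sample shifted to the window midpoint) before averaging and
#' matching, as in classical ECG template matching, so beat-to-beat jitter
#' does not blur the sharp QRS. Used as an independent check that a
#' synthetic dataset is solvable, not as part of the learned pipeline.
#'
#' @param train_beats,train_y Training beat matrix (rows = beats) and labels.
#' @param test_beats Beats to classify.
#' @return Integer vector of predicted subject labels.
#' @export
nearest_template_classify <- function(train_beats, train_y, test_beats) {
  train_beats <- align_apex(unclass_beats(train_beats))
  test_beats <- align_apex(unclass_beats(test_beats))
  classes <- sort(unique(train_y))
  centroids <- t(vapply(classes, function(j)
    colMeans(train_beats[train_y == j, , drop = FALSE]),
    numeric(ncol(train_beats))))
  d2 <- outer(rowSums(test_beats^2), rowSums(centroids^2), "+") -
    2 * test_beats %*% t(centroids)
  classes[max.col(-d2, ties.method = "first")]
}

# Circularly shift each beat so its maximum sits at the window midpoint.
align_apex <- function(B) {
  L <- ncol(B)
  mid <- ceiling(L / 2)
  t(apply(B, 1, function(b) {
    k <- (which.max(b) - mid) %% L
    if (k == 0) b else c(b[(k + 1):L], b[1:k])
  }))
}

unclass_beats <- function(b) if (inherits(b, "beat_matrix")) b$beats else b
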