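#' Per-subject train/enroll/probe split
#'
#' Splits beat indices per subject into training, enrollment and probe sets
#' (default 60/30/10) with floor rounding, guaranteeing at least one enroll
#' and one probe beat per subject. Seeded and deterministic.
#'
#' @param y Integer subject labels.
#' @param fractions Length-3 positive fractions summing to 1.
#' @param seed Integer seed for the per-subject shuffles.
#' @return A list of integer index vectors `train`, `enroll`, `probe`.
#' @export
split_indices <- function(y, fractions = c(0.6, 0.3, 0.1), seed = 1L) {
  stopifnot(length(fractions) == 3, all(fractions > 0),
            abs(sum(fractions) - 1) < 1e-9)
  y <- as.integer(y)
  with_seed(seed, {
    train <- enroll <- probe <- integer(0)
    for (j in sort(unique(y))) {
      idx <- sample(which(y == j))
      nj <- length(idx)
      if (nj < 3) stop("subject ", j, " has fewer than 3 beats; ",
                       "cannot form train/enroll/probe sets")
      n_tr <- max(1L, floor(fractions[1] * nj))
      n_en <- max(1L, floor(fractions[2] * nj))
      if (n_tr + n_en >= nj) n_tr <- nj - n_en - 1L   # keep >= 1 probe
      train <- c(train, idx[seq_len(n_tr)])
      enroll <- c(enroll, idx[n_tr + seq_len(n_en)])
      probe <- c(probe, idx[(n_tr + n_en + 1L):nj])
    }
    list(train = train, enroll = enroll, probe = probe)
  })
}

#' Evaluate a fitted model on a gallery/probe protocol
#'
#' Projects enrollment and probe features with the learned `W1`, `W2`,
#' identifies each probe by nearest fused distance, and computes
#' verification metrics (FAR/FRR curve, EER, ROC/AUC).
#'
#' @param model A fitted [cmf_fit()] model.
#' @param features_enroll,features_probe `feature_pair` objects (or lists
#'   with `X1`, `X2`) for the enrollment and probe beats.
#' @param y_enroll,y_probe Subject labels.
#' @param fusion Distance fusion mode, see [pair_distance()].
#' @return An object of class `ecg_eval` with fields `accuracy` (percent),
#'   `eer` (percent), `auc`, `threshold`, `curve` (FAR/FRR by threshold),
#'   `predicted`, `n_probe`, `n_enroll`, `c`, `fusion`.
#' @export
evaluate_model <- function(model, features_enroll, y_enroll,
                           features_probe, y_probe, fusion = "sum") {
  gp <- gallery_probe(
    project(model, features_enroll$X1, features_enroll$X2), y_enroll,
    project(model, features_probe$X1, features_probe$X2), y_probe)
  pred <- identify(gp, fusion)
  vs <- verification_scores(gp, fusion)
  e <- eer(vs$genuine, vs$impostor)
  structure(list(
    accuracy = 100 * mean(pred == gp$probe_labels),
    eer = e$eer,
    auc = roc_auc(vs$genuine, vs$impostor),
    threshold = e$threshold,
    curve = e$curve,
    roc = roc_curve(vs$genuine, vs$impostor),
    predicted = pred,
    truth = gp$probe_labels,
    n_probe = length(y_probe), n_enroll = length(y_enroll),
    c = length(unique(y_enroll)), fusion = fusion),
    class = "ecg_eval")
}

#' @export
print.ecg_eval <- function(x, ...) {
  cat(sprintf(paste0(
    "<ecg_eval> %d probes vs %d enrolled beats (%d subjects, fusion ",
    "'%s')\n  accuracy %.2f%%  EER %.2f%%  AUC %.4f\n"),
    x$n_probe, x$n_enroll, x$c, x$fusion, x$accuracy, x$eer, x$auc))
  invisible(x)
}

#' Pipeline configuration
#'
#' Bundles the synthetic-data configuration, model hyperparameters and
#' evaluation protocol for [run_pipeline()].
#'
#' @param synth A [synth_config()] (used when no beats are supplied).
#' @param params A [cmf_params()].
#' @param m RPM side length; `NULL` uses the per-window default.
#' @param fractions Train/enroll/probe split fractions.
#' @param fusion Distance fusion mode.
#' @param features `"both"`, `"1d"` or `"2d"` -- the single-level settings
#'   are the collaborative-embedding ablations.
#' @param attention `FALSE` disables dimensional attention learning.
#' @param projection `FALSE` removes projection learning from the training
#'   objective (the projections used for matching are then fitted post hoc).
#' @param seed Master seed; synth/model/split seeds are derived from it.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(synth = synth_config(), params = cmf_params(),
                            m = NULL, fractions = c(0.6, 0.3, 0.1),
                            fusion = "sum", features = c("both", "1d", "2d"),
                            attention = TRUE, projection = TRUE,
                            seed = 1L) {
  features <- match.arg(features)
  structure(list(synth = synth, params = params, m = m,
                 fractions = fractions, fusion = fusion,
                 features = features, attention = attention,
                 projection = projection, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full identification pipeline
#'
#' Generates (or accepts) a labelled beat set, extracts dual-level features,
#' splits per subject into train/enroll/probe, fits the factorization model
#' on the training beats, and evaluates identification and verification on
#' the held-out sets. Fully reproducible given the configuration seed.
#'
#' Ablation switches: `features = "1d"`/`"2d"` zero out the other view's
#' embedding and projection weights and match in the remaining domain;
#' `attention = FALSE` freezes the attention weights at 1;
#' `projection = FALSE` drops the projection terms from training and fits
#' `W1`, `W2` post hoc by the same ridge formula so matching stays defined.
#'
#' @param cfg A [pipeline_config()].
#' @param beats Optional [beat_matrix()]; when `NULL`, synthetic beats are
#'   generated from `cfg$synth` (with the seed derived from `cfg$seed`).
#' @param y Subject labels, required when `beats` is given.
#' @return An `ecg_eval` report with the fitted `model` and the `config`
#'   attached.
#' @export
run_pipeline <- function(cfg = pipeline_config(), beats = NULL, y = NULL) {
  stopifnot(inherits(cfg, "pipeline_config"))
  if (is.null(beats)) {
    sc <- cfg$synth
    sc$seed <- cfg$seed
    ds <- synth_dataset(sc)
    beats <- ds$beats
    y <- ds$y
  } else if (is.null(y)) {
    stop("labels y are required when beats are supplied")
  }
  fp <- extract_features(beats, cfg$m)
  params <- cfg$params
  params$seed <- cfg$seed + 1L
  # single-level ablations: zero the other view's weights
  if (cfg$features == "1d") { params$beta <- 0; params$gamma <- 0 }
  if (cfg$features == "2d") { params$alpha <- 0; params$eta <- 0 }
  fusion <- switch(cfg$features, both = cfg$fusion, `1d` = "1d", `2d` = "2d")
  train_params <- params
  if (!cfg$projection) { train_params$eta <- 0; train_params$gamma <- 0 }

  sp <- split_indices(y, cfg$fractions, seed = cfg$seed + 2L)
  model <- cmf_fit(fp$X1[, sp$train, drop = FALSE],
                   fp$X2[, sp$train, drop = FALSE],
                   y[sp$train], train_params, attention = cfg$attention)
  if (!cfg$projection) {
    # post-hoc projections with the un-ablated weights, for matching only
    if (params$eta > 0) {
      model$W1 <- update_latent_loading(fp$X1[, sp$train, drop = FALSE],
                                        model$V, params$eta, params$zeta)
    }
    if (params$gamma > 0) {
      model$W2 <- update_latent_loading(fp$X2[, sp$train, drop = FALSE],
                                        model$V, params$gamma, params$zeta)
    }
  }
  sub <- function(ix) list(X1 = fp$X1[, ix, drop = FALSE],
                           X2 = fp$X2[, ix, drop = FALSE])
  report <- evaluate_model(model, sub(sp$enroll), y[sp$enroll],
                           sub(sp$probe), y[sp$probe], fusion = fusion)
  report$model <- model
  report$config <- cfg
  report$split_sizes <- vapply(sp, length, integer(1))
  report
}
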