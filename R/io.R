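SCHEMA_VERSION <- 1L

#' Write a beat matrix artifact
#'
#' The canonical interchange format is a JSON document carrying the beat
#' matrix, sampling rate, optional labels and R indices, plus a
#' `schema_version` and provenance echo (seed/config when supplied).
#'
#' @param beats A [beat_matrix()].
#' @param path Output file path (`.json`).
#' @param y Optional subject labels.
#' @param provenance Optional list echoed verbatim into the artifact.
#' @return `path`, invisibly.
#' @export
write_beats <- function(beats, path, y = NULL, provenance = NULL) {
  stopifnot(inherits(beats, "beat_matrix"))
  obj <- list(schema_version = SCHEMA_VERSION, fs = beats$fs,
              beats = beats$beats, r_index = beats$r_index,
              y = y, provenance = provenance)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Load a beat matrix artifact
#'
#' Reads either the canonical JSON artifact written by [write_beats()] or a
#' plain numeric CSV with one beat per row (header-less; `fs` must then be
#' supplied). Schema violations are reported with the offending field.
#'
#' @param path Input file (`.json` or `.csv`).
#' @param fs Sampling rate, required for CSV input.
#' @return A list with `beats` (a [beat_matrix()]) and `y` (labels or
#'   `NULL`).
#' @export
load_beats <- function(path, fs = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    if (is.null(fs)) stop("fs is required when loading beats from CSV")
    B <- as.matrix(utils::read.csv(path, header = FALSE))
    storage.mode(B) <- "double"
    if (anyNA(B)) stop("ragged or non-numeric rows in ", path)
    return(list(beats = beat_matrix(B, fs = fs), y = NULL))
  }
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- c("schema_version", "fs", "beats", "r_index", "y", "provenance")
  extra <- setdiff(names(obj), known)
  if (length(extra)) warning("unknown keys ignored: ",
                             paste(extra, collapse = ", "))
  for (key in c("fs", "beats")) {
    if (is.null(obj[[key]])) stop("beats artifact missing key '", key, "'")
  }
  B <- as.matrix(obj$beats)
  storage.mode(B) <- "double"
  if (anyNA(B)) stop("field 'beats' contains ragged or non-numeric rows")
  ri <- if (length(obj$r_index)) as.integer(obj$r_index) else NULL
  list(beats = beat_matrix(B, fs = obj$fs, r_index = ri),
       y = if (length(obj$y)) as.integer(obj$y) else NULL)
}

#' Write an evaluation report artifact
#'
#' @param report An `ecg_eval` report.
#' @param path Output `.json` path.
#' @param seed Seed echoed for provenance.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, seed = NULL) {
  stopifnot(inherits(report, "ecg_eval"))
  cfg <- report$config
  obj <- list(schema_version = SCHEMA_VERSION,
              accuracy = report$accuracy, eer = report$eer,
              auc = report$auc, threshold = report$threshold,
              n_probe = report$n_probe, n_enroll = report$n_enroll,
              c = report$c, fusion = report$fusion,
              far = report$curve$far, frr = report$curve$frr,
              curve_threshold = report$curve$threshold,
              provenance = list(
                seed = seed %||% if (!is.null(cfg)) cfg$seed,
                features = if (!is.null(cfg)) cfg$features,
                attention = if (!is.null(cfg)) cfg$attention,
                projection = if (!is.null(cfg)) cfg$projection))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Read a PhysioNet-style WFDB record
#'
#' WFDB ingestion needs a WFDB reader, which this package does not bundle;
#' the core pipeline is unaffected (use [load_beats()] / [synth_dataset()]).
#'
#' @param record Record path or name.
#' @param channel Channel index.
#' @export
load_wfdb_record <- function(record, channel = 1L) {
  stop("reading WFDB records requires a WFDB reader ",
       "(e.g. the Python 'wfdb' package via a CSV export); ",
       "convert the record to CSV and use load_beats()/ecg_record() instead",
       call. = FALSE)
}
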