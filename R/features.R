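#' Distance and amplitude feature extraction
#'
#' Assembles the per-beat biometric feature vectors from detected
#' fiducial points. ECG beats yield 21 features: 15 distance features
#' (inter-landmark intervals in seconds, divided by the recording's mean
#' RR interval so heart rate cancels) and 6 signed amplitude features
#' (sample value at the first-named point minus the second, mV). PPG
#' beats yield 12 features: 8 distances (normalized by the mean
#' peak-to-peak interval) and 4 amplitudes.
#'
#' @name features
NULL

ECG_DISTANCE_PAIRS <- list(
  c("R", "Q"), c("R", "S"), c("R", "P"), c("R", "PB"), c("R", "PE"),
  c("R", "T"), c("R", "TB"), c("R", "TE"), c("PB", "PE"), c("TB", "TE"),
  c("Q", "P"), c("S", "T"), c("P", "T"), c("Q", "PB"), c("S", "TE"))
ECG_AMPLITUDE_PAIRS <- list(
  c("Q", "R"), c("S", "R"), c("PB", "P"), c("P", "Q"), c("T", "TB"),
  c("T", "S"))
PPG_DISTANCE_PAIRS <- list(
  c("P", "PS"), c("P", "PD"), c("P", "V"), c("P", "VS"), c("P", "VD"),
  c("VS", "VD"), c("PD", "V"), c("PD", "VD"))
PPG_AMPLITUDE_PAIRS <- list(
  c("PS", "P"), c("P", "PD"), c("V", "VS"), c("PD", "V"))

pair_names <- function(pairs, prefix) {
  vapply(pairs, function(p) paste0(prefix, p[1L], "-", p[2L]), character(1L))
}

#' Names of the ECG / PPG feature columns
#'
#' Distance features are prefixed `d.`, amplitude features `a.`.
#'
#' @param kind `"ecg"` (21 names) or `"ppg"` (12 names).
#' @return character vector of feature names in canonical order.
#' @export
feature_names <- function(kind = c("ecg", "ppg")) {
  kind <- match.arg(kind)
  if (kind == "ecg")
    c(pair_names(ECG_DISTANCE_PAIRS, "d."), pair_names(ECG_AMPLITUDE_PAIRS, "a."))
  else
    c(pair_names(PPG_DISTANCE_PAIRS, "d."), pair_names(PPG_AMPLITUDE_PAIRS, "a."))
}

#' Extract per-beat feature vectors
#'
#' @param fiducials fiducial table from [detect_ecg_fiducials()] or
#'   [detect_ppg_fiducials()] (or the ground-truth table from the
#'   generators, plus a `kind` hint).
#' @param sig the [signal()] the fiducials index into.
#' @param kind `"ecg"` or `"ppg"`; defaults to the table's `kind`
#'   attribute, else the signal's.
#' @param aggregate `"per_beat"` (one row per complete beat) or `"mean"`
#'   (a single averaged row).
#' @return data frame of features (21 columns for ECG, 12 for PPG) plus
#'   leading `subject` and `beat` columns. Beats with a missing landmark
#'   are excluded; the number excluded is reported in attribute
#'   `"n_excluded"`.
#' @export
extract_features <- function(fiducials, sig, kind = NULL,
                             aggregate = c("per_beat", "mean")) {
  stopifnot(inherits(sig, "heartcs_signal"))
  aggregate <- match.arg(aggregate)
  if (is.null(kind))
    kind <- if (!is.null(attr(fiducials, "kind"))) attr(fiducials, "kind")
            else sig$kind
  kind <- match.arg(kind, c("ecg", "ppg"))
  fs <- sig$fs
  x <- sig$samples
  dist_pairs <- if (kind == "ecg") ECG_DISTANCE_PAIRS else PPG_DISTANCE_PAIRS
  amp_pairs <- if (kind == "ecg") ECG_AMPLITUDE_PAIRS else PPG_AMPLITUDE_PAIRS
  anchor <- if (kind == "ecg") "R" else "P"
  required <- unique(c(unlist(dist_pairs), unlist(amp_pairs), anchor))

  anchors <- fiducials$index[fiducials$name == anchor]
  mean_rr <- if (length(anchors) >= 2L)
    mean(diff(sort(anchors))) / fs
  else {
    warning("fewer than two ", anchor,
            " peaks; distance features left in plain seconds")
    1
  }

  beats <- sort(unique(fiducials$beat))
  rows <- list()
  excluded <- 0L
  for (b in beats) {
    fb <- fiducials[fiducials$beat == b, ]
    idx <- stats::setNames(fb$index, fb$name)
    if (!all(required %in% names(idx)) || anyNA(idx[required]) ||
        any(idx[required] < 1L | idx[required] > length(x))) {
      excluded <- excluded + 1L
      next
    }
    d <- vapply(dist_pairs, function(p)
      abs(idx[[p[1L]]] - idx[[p[2L]]]) / fs / mean_rr, numeric(1L))
    a <- vapply(amp_pairs, function(p)
      x[idx[[p[1L]]]] - x[idx[[p[2L]]]], numeric(1L))
    rows[[length(rows) + 1L]] <-
      c(stats::setNames(d, pair_names(dist_pairs, "d.")),
        stats::setNames(a, pair_names(amp_pairs, "a.")))
  }
  if (excluded > 0L)
    message(excluded, " beat(s) excluded for incomplete fiducials")
  if (length(rows) == 0L)
    stop("no complete beat available for feature extraction")
  feat <- as.data.frame(do.call(rbind, rows), check.names = FALSE)
  if (aggregate == "mean") {
    feat <- as.data.frame(as.list(colMeans(feat)), check.names = FALSE)
    beat_ids <- NA_integer_
  } else {
    beat_ids <- seq_len(nrow(feat))
  }
  out <- cbind(data.frame(subject = sig$subject_id, beat = beat_ids,
                          stringsAsFactors = FALSE), feat)
  attr(out, "n_excluded") <- excluded
  attr(out, "kind") <- kind
  out
}
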