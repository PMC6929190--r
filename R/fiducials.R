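#' Fiducial point detection
#'
#' Wavelet-based landmark detection for ECG and PPG beats. The QRS
#' complex is located from the mid-scale detail bands of a discrete
#' wavelet decomposition (where QRS energy concentrates), with an
#' adaptive threshold expressed as a fraction of the band maximum and a
#' refractory window, so detection is invariant to amplitude scaling.
#' The remaining landmarks are found in physiology-motivated search
#' windows around each R peak; wave onsets and offsets are the points
#' where the wave falls below a fraction of its local amplitude relative
#' to the adjacent baseline.
#'
#' @name fiducials
NULL

#' Fiducial detection tuning parameters
#'
#' All windows in seconds, thresholds as fractions; defaults are standard
#' physiological choices (the algorithm itself prescribes none).
#'
#' @param qrs_threshold fraction of the wavelet-band maximum a QRS burst
#'   must reach.
#' @param refractory minimum spacing between detected beats (s).
#' @param qs_window half-width of the Q/S search around R (s).
#' @param p_window,t_window search windows relative to R (s, two values:
#'   nearest and farthest edge).
#' @param onset_fraction wave height fraction (relative to the local
#'   baseline) defining onsets/offsets.
#' @return a `heartcs_fiducial_config` list.
#' @export
fiducial_config <- function(qrs_threshold = 0.4, refractory = 0.25,
                            qs_window = 0.06, p_window = c(0.08, 0.28),
                            t_window = c(0.08, 0.45),
                            onset_fraction = 0.10) {
  structure(list(qrs_threshold = qrs_threshold, refractory = refractory,
                 qs_window = qs_window, p_window = p_window,
                 t_window = t_window, onset_fraction = onset_fraction),
            class = "heartcs_fiducial_config")
}

# Cluster above-threshold indices separated by more than `gap` samples
# into bursts; returns a list of index vectors.
cluster_indices <- function(idx, gap) {
  if (length(idx) == 0L) return(list())
  breaks <- which(diff(idx) > gap)
  starts <- c(1L, breaks + 1L)
  ends <- c(breaks, length(idx))
  mapply(function(s, e) idx[s:e], starts, ends, SIMPLIFY = FALSE)
}

# Walk outward from a peak until the wave drops below
# base + frac * (peak - base); `dir` is -1 (onset) or +1 (offset), and
# the walk is confined to [lo, hi]. Works for negative waves too via the
# sign of (peak - base).
walk_to_bound <- function(x, peak_idx, lo, hi, dir, frac) {
  base <- if (dir < 0) min_or_max_base(x, lo, peak_idx) else
    min_or_max_base(x, peak_idx, hi)
  height <- x[peak_idx] - base
  if (height == 0) return(peak_idx)
  i <- peak_idx
  repeat {
    nxt <- i + dir
    if (nxt < lo || nxt > hi) return(i)
    if ((x[nxt] - base) / height <= frac) return(nxt)
    i <- nxt
  }
}

# Local baseline: the extremum of the signal over the flank range,
# taken toward zero deviation (works for positive and negative waves
# because the flank settles near the isoelectric line).
min_or_max_base <- function(x, lo, hi) {
  seg <- x[lo:hi]
  # baseline = flank value with the smallest |value - median| tail
  stats::median(c(seg[1L], seg[length(seg)]))
}

#' Detect ECG fiducial points
#'
#' R peaks are found as bursts of the QRS wavelet band (detail levels
#' 3-4 of a coif3 decomposition, roughly 8-60 Hz at 500 Hz sampling)
#' exceeding `qrs_threshold` of the band maximum, with a refractory
#' window; each burst is refined to the local signal maximum. Q and S
#' are the nearest minima within `qs_window` of R; P is the maximum in
#' the `p_window` before R and T the maximum in the `t_window` after R;
#' PB/PE and TB/TE are the points where the wave falls below
#' `onset_fraction` of its local amplitude. Beats whose search windows
#' leave the signal are dropped.
#'
#' @param sig a [signal()], ideally denoised.
#' @param config a [fiducial_config()].
#' @return data frame with columns `beat`, `name`
#'   (PB/P/PE/Q/R/S/TB/T/TE) and `index` (1-based sample index), with the
#'   sampling rate in attribute `"fs"`.
#' @export
detect_ecg_fiducials <- function(sig, config = fiducial_config()) {
  stopifnot(inherits(sig, "heartcs_signal"))
  x <- sig$samples
  fs <- sig$fs
  n <- length(x)
  if (diff(range(x)) < 1e-12 * max(1, max(abs(x))))
    stop("no R peak found: signal is flat")
  dec_levels <- min(5L, max(1L, floor(log2(n))))
  band <- wavelet_band(x, dec_levels, keep = intersect(3:5, seq_len(dec_levels)))
  # moving-RMS energy envelope (~80 ms): robust to the decimated
  # transform's translation variance across beats
  w <- max(1L, round(0.08 * fs))
  env <- sqrt(as.numeric(stats::filter(band^2, rep(1 / w, w), sides = 2)))
  env[is.na(env)] <- 0
  thr <- config$qrs_threshold * max(env)
  refr <- round(config$refractory * fs)
  clusters <- cluster_indices(which(env >= thr), refr)
  if (length(clusters) == 0L)
    stop("no R peak found in signal",
         if (!is.na(sig$subject_id)) paste0(" (subject ", sig$subject_id, ")"))
  w50 <- round(0.05 * fs)
  r_peaks <- vapply(clusters, function(cl) {
    lo <- max(1L, min(cl) - w50)
    hi <- min(n, max(cl) + w50)
    as.integer(lo + which.max(x[lo:hi]) - 1L)
  }, integer(1L))
  r_peaks <- sort(unique(r_peaks))
  # enforce refractory after refinement
  if (length(r_peaks) > 1L)
    r_peaks <- r_peaks[c(TRUE, diff(r_peaks) > refr)]

  qsw <- round(config$qs_window * fs)
  pw <- round(config$p_window * fs)
  tw <- round(config$t_window * fs)
  rows <- list()
  beat <- 0L
  for (r in r_peaks) {
    p_lo <- r - pw[2L]; p_hi <- r - pw[1L]
    t_lo <- r + tw[1L]; t_hi <- r + tw[2L]
    if (p_lo < 1L || t_hi > n) next        # incomplete beat at an edge
    q_idx <- (r - qsw) + which.min(x[(r - qsw):(r - 1L)]) - 1L
    s_idx <- r + which.min(x[(r + 1L):(r + qsw)])
    p_idx <- p_lo + which.max(x[p_lo:p_hi]) - 1L
    t_idx <- t_lo + which.max(x[t_lo:t_hi]) - 1L
    frac <- config$onset_fraction
    pb <- walk_to_bound(x, p_idx, max(1L, p_lo - pw[1L]), p_idx, -1L, frac)
    pe <- walk_to_bound(x, p_idx, p_idx, q_idx - 1L, +1L, frac)
    tb <- walk_to_bound(x, t_idx, s_idx + 1L, t_idx, -1L, frac)
    te <- walk_to_bound(x, t_idx, t_idx, min(n, t_hi + tw[1L]), +1L, frac)
    beat <- beat + 1L
    rows[[beat]] <- data.frame(
      beat = beat,
      name = c("PB", "P", "PE", "Q", "R", "S", "TB", "T", "TE"),
      index = c(pb, p_idx, pe, q_idx, r, s_idx, tb, t_idx, te))
  }
  if (length(rows) == 0L)
    stop("no complete beat (with full P and T windows) in signal")
  out <- do.call(rbind, rows)
  attr(out, "fs") <- fs
  attr(out, "kind") <- "ecg"
  out
}

#' Detect PPG fiducial points
#'
#' Systolic peaks P are maxima above an adaptive threshold (fraction of
#' the signal's dynamic range) with a refractory window; the valley V is
#' the minimum between consecutive systolic peaks; PS/PD and VS/VD are
#' onset/offset threshold crossings analogous to the ECG rule. Only
#' complete beats (a P with a following valley and a following P) are
#' returned.
#'
#' @inheritParams detect_ecg_fiducials
#' @return data frame with columns `beat`, `name` (PS/P/PD/VS/V/VD) and
#'   `index`; sampling rate in attribute `"fs"`.
#' @export
detect_ppg_fiducials <- function(sig, config = fiducial_config()) {
  stopifnot(inherits(sig, "heartcs_signal"))
  x <- sig$samples
  fs <- sig$fs
  n <- length(x)
  rng <- range(x)
  thr <- rng[1L] + 0.5 * (rng[2L] - rng[1L])
  refr <- round(config$refractory * fs)
  clusters <- cluster_indices(which(x >= thr), refr)
  if (length(clusters) < 2L)
    stop("fewer than two systolic peaks found in PPG signal",
         if (!is.na(sig$subject_id)) paste0(" (subject ", sig$subject_id, ")"))
  p_peaks <- vapply(clusters, function(cl) as.integer(cl[which.max(x[cl])]),
                    integer(1L))
  p_peaks <- sort(p_peaks)

  frac <- config$onset_fraction
  rows <- list()
  beat <- 0L
  for (i in seq_len(length(p_peaks) - 1L)) {
    p <- p_peaks[i]
    p_next <- p_peaks[i + 1L]
    v <- p + which.min(x[p:p_next]) - 1L
    half <- round(0.5 * (p_next - p))
    ps <- walk_to_bound(x, p, max(1L, p - half), p, -1L, frac)
    pd <- walk_to_bound(x, p, p, v, +1L, frac)
    # valley bounds: walk outward until the signal rises back toward the
    # surrounding pulse by (1 - frac) of the valley depth
    vs <- valley_bound(x, v, pd, -1L, frac)
    vd <- valley_bound(x, v, p_next - 1L, +1L, frac)
    beat <- beat + 1L
    rows[[beat]] <- data.frame(
      beat = beat,
      name = c("PS", "P", "PD", "VS", "V", "VD"),
      index = c(ps, p, pd, vs, v, vd))
  }
  out <- do.call(rbind, rows)
  attr(out, "fs") <- fs
  attr(out, "kind") <- "ppg"
  out
}

# Walk outward from a valley until the signal has risen by `1 - frac` of
# the local depth (depth measured against the bound-side extreme).
valley_bound <- function(x, v_idx, bound, dir, frac) {
  lo <- min(v_idx, bound); hi <- max(v_idx, bound)
  top <- max(x[lo:hi])
  depth <- top - x[v_idx]
  if (depth == 0) return(v_idx)
  i <- v_idx
  repeat {
    nxt <- i + dir
    if (nxt < lo || nxt > hi) return(i)
    if ((x[nxt] - x[v_idx]) / depth >= 1 - frac) return(nxt)
    i <- nxt
  }
}
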