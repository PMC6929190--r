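#' Synthetic beat templates
#'
#' A beat is modelled as a sum of Gaussian bumps repeated at the heart
#' rate. For ECG there are five components (P, Q, R, S, T), each with a
#' center offset within the beat (seconds from beat onset), a width
#' (Gaussian sigma, seconds) and an amplitude (mV). For PPG there are two
#' components: the systolic peak P and the dicrotic wave; the
#' inter-systolic valley V and its bounds are derived from the clean
#' waveform. The default ECG morphology resembles a lead-I beat with a
#' 1.0 mV R peak; defaults for PPG give a systolic peak of unit amplitude
#' with a clear dicrotic notch.
#'
#' @param kind `"ecg"` or `"ppg"`.
#' @param heart_rate beats per minute, in \[30, 200\].
#' @param centers,widths,amplitudes optional named numeric vectors
#'   overriding per-component parameters. ECG components are
#'   `c("P","Q","R","S","T")`; PPG components are `c("P","D")` (systolic
#'   peak and dicrotic wave).
#' @return object of class `heartcs_template` with fields `kind`,
#'   `heart_rate`, `period` (s), `centers`, `widths`, `amplitudes`.
#' @export
#' @examples
#' tpl <- beat_template("ecg", heart_rate = 72)
#' tpl$amplitudes[["R"]]
beat_template <- function(kind = c("ecg", "ppg"), heart_rate = 60,
                          centers = NULL, widths = NULL, amplitudes = NULL) {
  kind <- match.arg(kind)
  if (!is.finite(heart_rate) || heart_rate < 30 || heart_rate > 200)
    stop("heart_rate must lie in [30, 200] bpm")
  if (kind == "ecg") {
    cen <- c(P = 0.13, Q = 0.270, R = 0.30, S = 0.330, T = 0.60)
    wid <- c(P = 0.025, Q = 0.008, R = 0.009, S = 0.007, T = 0.055)
    amp <- c(P = 0.15, Q = -0.10, R = 1.00, S = -0.15, T = 0.30)
  } else {
    cen <- c(P = 0.30, D = 0.55)
    wid <- c(P = 0.075, D = 0.090)
    amp <- c(P = 1.00, D = 0.42)
  }
  override <- function(base, user) {
    if (is.null(user)) return(base)
    if (is.null(names(user)) || !all(names(user) %in% names(base)))
      stop("component names must be among: ", paste(names(base), collapse = ", "))
    base[names(user)] <- user
    base
  }
  cen <- override(cen, centers)
  wid <- override(wid, widths)
  amp <- override(amp, amplitudes)
  if (any(wid <= 0)) stop("component widths must be positive")
  if (kind == "ecg" && is.unsorted(cen[c("P", "Q", "R", "S", "T")], strictly = TRUE))
    stop("ECG component centers must be strictly ordered P < Q < R < S < T")
  structure(
    list(kind = kind, heart_rate = heart_rate, period = 60 / heart_rate,
         centers = cen, widths = wid, amplitudes = amp),
    class = "heartcs_template"
  )
}

#' Additive noise specification
#'
#' Describes the noise mixed into synthetic signals: white Gaussian noise,
#' sinusoidal baseline wander (respiration-band drift) and sinusoidal
#' powerline interference — the two dominant ECG artifact classes.
#'
#' @param white_sd standard deviation of additive Gaussian noise.
#' @param baseline_amp,baseline_freq amplitude and frequency (Hz) of the
#'   baseline-wander sinusoid.
#' @param powerline_amp,powerline_freq amplitude and frequency (Hz) of the
#'   mains-interference sinusoid (50 Hz default).
#' @param seed RNG seed for the white-noise draw.
#' @return object of class `heartcs_noise`.
#' @export
noise_spec <- function(white_sd = 0, baseline_amp = 0, baseline_freq = 0.3,
                       powerline_amp = 0, powerline_freq = 50, seed = 1L) {
  amps <- c(white_sd, baseline_amp, powerline_amp)
  if (any(!is.finite(amps)) || any(amps < 0))
    stop("noise amplitudes must be finite and non-negative")
  if (baseline_freq < 0 || powerline_freq < 0)
    stop("noise frequencies must be non-negative")
  structure(
    list(white_sd = white_sd, baseline_amp = baseline_amp,
         baseline_freq = baseline_freq, powerline_amp = powerline_amp,
         powerline_freq = powerline_freq, seed = as.integer(seed)),
    class = "heartcs_noise"
  )
}

# Periodic sum-of-Gaussians waveform sampled at times t (seconds).
# Contributions from the two adjacent beat periods are added so that wave
# tails crossing a beat boundary are rendered correctly.
template_waveform <- function(template, t) {
  period <- template$period
  tau <- t %% period
  x <- numeric(length(t))
  for (comp in names(template$centers)) {
    c0 <- template$centers[[comp]]
    w <- template$widths[[comp]]
    a <- template$amplitudes[[comp]]
    for (shift in c(-period, 0, period))
      x <- x + a * exp(-((tau - c0 - shift)^2) / (2 * w^2))
  }
  x
}

noise_samples <- function(noise, n, fs) {
  t <- (seq_len(n) - 1L) / fs
  out <- numeric(n)
  if (noise$baseline_amp > 0)
    out <- out + noise$baseline_amp * sin(2 * pi * noise$baseline_freq * t)
  if (noise$powerline_amp > 0)
    out <- out + noise$powerline_amp * sin(2 * pi * noise$powerline_freq * t)
  if (noise$white_sd > 0)
    out <- out + with_seed(noise$seed, stats::rnorm(n, sd = noise$white_sd))
  out
}

# Ground-truth fiducial table for the Gaussian beat model: component
# centers plus onsets/offsets at center +/- 3 sigma (covering >99% of each
# wave's energy), one row per (beat, landmark), 1-based sample indices.
ecg_ground_truth <- function(template, n_beats, fs) {
  period <- template$period
  rows <- list()
  for (b in seq_len(n_beats)) {
    t0 <- (b - 1L) * period
    cen <- template$centers
    wid <- template$widths
    add <- function(name, tsec) {
      idx <- round(tsec * fs) + 1L
      data.frame(beat = b, name = name, index = idx)
    }
    rows[[length(rows) + 1L]] <- do.call(rbind, list(
      add("PB", t0 + cen[["P"]] - 3 * wid[["P"]]),
      add("P",  t0 + cen[["P"]]),
      add("PE", t0 + cen[["P"]] + 3 * wid[["P"]]),
      add("Q",  t0 + cen[["Q"]]),
      add("R",  t0 + cen[["R"]]),
      add("S",  t0 + cen[["S"]]),
      add("TB", t0 + cen[["T"]] - 3 * wid[["T"]]),
      add("T",  t0 + cen[["T"]]),
      add("TE", t0 + cen[["T"]] + 3 * wid[["T"]])
    ))
  }
  do.call(rbind, rows)
}

#' Generate a synthetic ECG with analytic fiducial ground truth
#'
#' Renders the periodic five-Gaussian beat of an ECG [beat_template()] at
#' sampling rate `fs`, adds the requested noise, and returns both the
#' signal and the exact sample indices of every beat's P, Q, R, S, T
#' centers together with P/T onsets and offsets (PB, PE, TB, TE) at
#' center +/- 3 sigma.
#'
#' @param template an ECG [beat_template()].
#' @param duration length of the recording in seconds; must cover at least
#'   one beat period.
#' @param fs sampling rate in Hz (default 500).
#' @param noise a [noise_spec()]; default is noiseless.
#' @return list with `signal` (a [signal()]), `fiducials` (data frame
#'   `beat`, `name`, `index`) and `clean` (noise-free sample vector).
#' @export
#' @examples
#' ecg <- make_ecg(beat_template("ecg"), duration = 2)
#' subset(ecg$fiducials, name == "R")
make_ecg <- function(template, duration, fs = 500, noise = noise_spec()) {
  stopifnot(inherits(template, "heartcs_template"))
  if (template$kind != "ecg") stop("template kind must be 'ecg'")
  if (!is.finite(duration) || duration <= 0 || !is.finite(fs) || fs <= 0)
    stop("duration and fs must be positive")
  n <- round(duration * fs)
  if (n < round(template$period * fs))
    stop("duration must cover at least one beat period")
  t <- (seq_len(n) - 1L) / fs
  clean <- template_waveform(template, t)
  x <- clean + noise_samples(noise, n, fs)
  n_beats <- floor(n / (template$period * fs))
  fid <- ecg_ground_truth(template, n_beats, fs)
  fid <- fid[fid$index >= 1L & fid$index <= n, ]
  list(signal = signal(x, fs = fs, kind = "ecg"), fiducials = fid,
       clean = clean)
}

#' Generate a synthetic PPG with ground-truth fiducials
#'
#' Renders the two-Gaussian pulse waveform (systolic peak P plus dicrotic
#' wave) and returns per-beat ground truth for the systolic peak P, the
#' inter-beat valley V (minimum of the clean waveform between consecutive
#' systolic peaks), the P-wave bounds PS/PD at center +/- 3 sigma, and the
#' valley bounds VS/VD at V -/+ 3 dicrotic sigmas (clipped to the signal).
#'
#' @inheritParams make_ecg
#' @param template a PPG [beat_template()].
#' @return list with `signal`, `fiducials`, `clean` as in [make_ecg()].
#' @export
make_ppg <- function(template, duration, fs = 500, noise = noise_spec()) {
  stopifnot(inherits(template, "heartcs_template"))
  if (template$kind != "ppg") stop("template kind must be 'ppg'")
  if (!is.finite(duration) || duration <= 0 || !is.finite(fs) || fs <= 0)
    stop("duration and fs must be positive")
  n <- round(duration * fs)
  period <- template$period
  if (n < round(period * fs))
    stop("duration must cover at least one beat period")
  t <- (seq_len(n) - 1L) / fs
  clean <- template_waveform(template, t)
  x <- clean + noise_samples(noise, n, fs)
  n_beats <- floor(n / (period * fs))
  wP <- template$widths[["P"]]
  wD <- template$widths[["D"]]
  rows <- list()
  for (b in seq_len(n_beats)) {
    t0 <- (b - 1L) * period
    p_idx <- round((t0 + template$centers[["P"]]) * fs) + 1L
    ps <- round((t0 + template$centers[["P"]] - 3 * wP) * fs) + 1L
    pd <- round((t0 + template$centers[["P"]] + 3 * wP) * fs) + 1L
    # valley: clean-signal minimum between this systolic peak and the next
    next_p <- round((t0 + period + template$centers[["P"]]) * fs) + 1L
    hi <- min(next_p, n)
    v_idx <- if (hi > p_idx)
      p_idx + which.min(clean[p_idx:hi]) - 1L else NA_integer_
    rows[[b]] <- data.frame(
      beat = b,
      name = c("PS", "P", "PD", "VS", "V", "VD"),
      index = c(ps, p_idx, pd,
                if (is.na(v_idx)) NA_integer_ else v_idx - round(3 * wD * fs),
                v_idx,
                if (is.na(v_idx)) NA_integer_ else v_idx + round(3 * wD * fs))
    )
  }
  fid <- do.call(rbind, rows)
  fid <- fid[!is.na(fid$index) & fid$index >= 1L & fid$index <= n, ]
  list(signal = signal(x, fs = fs, kind = "ppg"), fiducials = fid,
       clean = clean)
}

#' Draw a population of per-subject beat templates
#'
#' Perturbs a base template with multiplicative jitter on component
#' amplitudes and center offsets (and heart rate), yielding `n_subjects`
#' distinct morphologies. This stands in for a cohort of recorded
#' subjects; with `jitter = 0` all templates are identical.
#'
#' @param n_subjects number of subjects.
#' @param base base [beat_template()] to perturb.
#' @param jitter relative standard deviation of the multiplicative
#'   perturbation (lognormal-free: factors are `1 + rnorm(sd = jitter)`,
#'   floored at 0.5).
#' @param seed RNG seed.
#' @return list of `n_subjects` templates, named `S01`, `S02`, ...
#' @export
#' @examples
#' pop <- make_population(23, jitter = 0.1, seed = 7)
#' length(pop)
make_population <- function(n_subjects, base = beat_template("ecg"),
                            jitter = 0.1, seed = 1L) {
  if (!is.finite(n_subjects) || n_subjects < 1)
    stop("n_subjects must be a positive count")
  if (jitter < 0) stop("jitter must be non-negative")
  with_seed(seed, {
    out <- vector("list", n_subjects)
    for (i in seq_len(n_subjects)) {
      amp <- base$amplitudes
      cen <- base$centers
      if (jitter > 0) {
        fa <- pmax(0.5, 1 + stats::rnorm(length(amp), sd = jitter))
        amp <- amp * fa
        # jitter the inter-component gaps; positive factors preserve the
        # strict center ordering
        fc <- pmax(0.5, 1 + stats::rnorm(length(cen), sd = jitter / 2))
        cen_new <- cumsum(c(cen[[1L]] * fc[1L], diff(cen) * fc[-1L]))
        names(cen_new) <- names(cen)
        cen <- cen_new
        hr <- max(30, min(200, base$heart_rate *
                            max(0.7, 1 + stats::rnorm(1, sd = jitter))))
      } else hr <- base$heart_rate
      out[[i]] <- beat_template(base$kind, heart_rate = hr,
                                centers = cen, widths = base$widths,
                                amplitudes = amp)
    }
    names(out) <- sprintf("S%02d", seq_len(n_subjects))
    out
  })
}

#' Draw an exactly k-sparse coefficient vector
#'
#' Support positions are drawn uniformly without replacement; magnitudes
#' are uniform in `amplitude_range` with random sign. Used to emulate the
#' exactly sparse regime of compressed-sensing reconstruction benchmarks
#' (e.g. sparsity 100 in a 1024-dimensional domain).
#'
#' @param n domain dimension.
#' @param k number of nonzeros, `1 <= k <= n`.
#' @param amplitude_range length-2 numeric, magnitude bounds.
#' @param seed RNG seed.
#' @return numeric vector of length `n` with exactly `k` nonzeros.
#' @export
#' @examples
#' theta <- make_ksparse(1024, 100, seed = 1)
#' sum(theta != 0)
make_ksparse <- function(n, k, amplitude_range = c(0.5, 1.5), seed = 1L) {
  if (!is.finite(k) || k < 1 || k > n)
    stop("sparsity k must satisfy 1 <= k <= n")
  with_seed(seed, {
    theta <- numeric(n)
    supp <- sample.int(n, k)
    mag <- stats::runif(k, amplitude_range[1L], amplitude_range[2L])
    sgn <- sample(c(-1, 1), k, replace = TRUE)
    theta[supp] <- mag * sgn
    theta
  })
}
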