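#' Reconstruction quality metrics
#'
#' Three standard figures of merit comparing an original signal `x` with
#' its reconstruction `x_hat`, all driven by the relative error ratio
#' `rho = ||x - x_hat|| / ||x||`:
#'
#' * SNR (dB): `-20 log10(rho)`; `+Inf` sentinel when the signals are
#'   identical.
#' * Matching rate: `MR = 1 - rho`, 1 for perfect reconstruction.
#' * RMSE: `sqrt(mean((x - x_hat)^2))` in signal units.
#'
#' The identities `SNR = -20 log10(1 - MR)` and
#' `RMSE = (1 - MR) ||x|| / sqrt(N)` hold exactly.
#'
#' @param x original signal vector (or [signal()]).
#' @param x_hat reconstruction, same length.
#' @name quality
NULL

as_samples <- function(x) {
  if (inherits(x, "heartcs_signal")) x$samples else as.numeric(x)
}

check_pair <- function(x, x_hat) {
  x <- as_samples(x); x_hat <- as_samples(x_hat)
  if (length(x) != length(x_hat))
    stop("x and x_hat must have equal length")
  list(x = x, x_hat = x_hat)
}

#' @rdname quality
#' @return `snr()`: the ratio in dB (`+Inf` when `x == x_hat`).
#' @export
#' @examples
#' snr(c(3, 4), c(3, 4.05))  # 40 dB
snr <- function(x, x_hat) {
  p <- check_pair(x, x_hat)
  xn <- sqrt(sum(p$x^2))
  if (xn == 0) stop("SNR undefined for an all-zero reference signal")
  en <- sqrt(sum((p$x - p$x_hat)^2))
  if (en == 0) return(Inf)
  -20 * log10(en / xn)
}

#' @rdname quality
#' @return `matching_rate()`: MR in (-Inf, 1].
#' @export
matching_rate <- function(x, x_hat) {
  p <- check_pair(x, x_hat)
  xn <- sqrt(sum(p$x^2))
  if (xn == 0) stop("matching rate undefined for an all-zero reference signal")
  1 - sqrt(sum((p$x - p$x_hat)^2)) / xn
}

#' @rdname quality
#' @return `rmse()`: root mean squared error, >= 0.
#' @export
rmse <- function(x, x_hat) {
  p <- check_pair(x, x_hat)
  sqrt(mean((p$x - p$x_hat)^2))
}

#' Full quality report for one reconstruction
#'
#' @inheritParams quality
#' @return a one-row data frame with `snr_db`, `mr`, `rmse`,
#'   `max_abs_residual`.
#' @export
quality_report <- function(x, x_hat) {
  p <- check_pair(x, x_hat)
  data.frame(snr_db = snr(p$x, p$x_hat),
             mr = matching_rate(p$x, p$x_hat),
             rmse = rmse(p$x, p$x_hat),
             max_abs_residual = max(abs(p$x - p$x_hat)))
}

#' Aggregate quality over repeated runs
#'
#' Benchmarks of stochastic ensembles are averaged over repetitions
#' (10 or 20 runs are typical); this returns mean and standard deviation
#' per metric.
#'
#' @param reports data frame of stacked [quality_report()] rows.
#' @return data frame with one row per metric: `metric`, `mean`, `sd`.
#' @export
quality_summary <- function(reports) {
  metrics <- c("snr_db", "mr", "rmse", "max_abs_residual")
  metrics <- intersect(metrics, names(reports))
  data.frame(
    metric = metrics,
    mean = vapply(metrics, function(m) mean(reports[[m]]), numeric(1)),
    sd = vapply(metrics, function(m) stats::sd(reports[[m]]), numeric(1)),
    row.names = NULL
  )
}
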