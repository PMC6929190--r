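#' Gaussian measurement ensemble
#'
#' Draws the M x N sensing matrix Phi with i.i.d. Gaussian entries. The
#' number of measurements is `M = round(compression_ratio * N)` (round
#' half away from zero), and the default entry variance is `1/M` so that
#' unit-norm vectors keep near-unit image norms (the restricted-isometry
#' normalization under which the initial-sparsity threshold of the
#' staged recovery algorithm is meaningful). The ensemble is fully
#' reproducible from `(N, compression_ratio, seed)` and is therefore
#' never persisted to disk.
#'
#' @param n signal dimension N.
#' @param compression_ratio M/N in (0, 1].
#' @param seed RNG seed.
#' @param variance entry variance, `"1/M"` (default) or `"unit"`.
#' @return a `heartcs_ensemble`: list with `phi` (M x N),
#'   `compression_ratio`, `seed`, `m`, `n`.
#' @export
#' @examples
#' ens <- gaussian_ensemble(1024, 0.7, seed = 1)
#' nrow(ens$phi)  # 717 measurements
gaussian_ensemble <- function(n, compression_ratio, seed = 1L,
                              variance = c("1/M", "unit")) {
  variance <- match.arg(variance)
  if (!is.finite(compression_ratio) || compression_ratio <= 0 ||
      compression_ratio > 1)
    stop("compression_ratio must lie in (0, 1]")
  n <- as.integer(n)
  if (n < 1L) stop("dimension n must be >= 1")
  m <- as.integer(floor(compression_ratio * n + 0.5))  # round half away from zero
  m <- max(1L, min(m, n))
  sd_entry <- if (variance == "1/M") 1 / sqrt(m) else 1
  phi <- with_seed(seed, matrix(stats::rnorm(m * n, sd = sd_entry), m, n))
  structure(
    list(phi = phi, compression_ratio = compression_ratio,
         seed = as.integer(seed), m = m, n = n, variance = variance),
    class = "heartcs_ensemble"
  )
}

#' @export
print.heartcs_ensemble <- function(x, ...) {
  cat(sprintf("<heartcs_ensemble> M=%d N=%d CR=%.3g seed=%d\n",
              x$m, x$n, x$compression_ratio, x$seed))
  invisible(x)
}

#' Compress a signal: y = Phi x
#'
#' @param ensemble a [gaussian_ensemble()].
#' @param x numeric signal vector of length N (or a [signal()]).
#' @return a `heartcs_observation`: list with `y` (length M) and the
#'   ensemble.
#' @export
sense <- function(ensemble, x) {
  stopifnot(inherits(ensemble, "heartcs_ensemble"))
  if (inherits(x, "heartcs_signal")) x <- x$samples
  x <- as.numeric(x)
  if (length(x) != ensemble$n)
    stop("signal length does not match the ensemble dimension N")
  structure(list(y = drop(ensemble$phi %*% x), ensemble = ensemble),
            class = "heartcs_observation")
}

#' Effective recovery matrix A = Phi D
#'
#' The greedy solvers correlate the residual against the columns of
#' `A = Phi %*% atoms`. With `normalize = TRUE` (default) columns are
#' rescaled to unit norm so threshold comparisons across atoms are fair;
#' the scaling factors are recorded so coefficient estimates can be
#' mapped back to the original dictionary scale.
#'
#' @param ensemble a [gaussian_ensemble()].
#' @param domain a `heartcs_domain`, or `NULL` for the identity domain
#'   (recover x directly).
#' @param normalize rescale columns to unit norm.
#' @return list with `A` (M x K), `col_scale` (length K; original column
#'   norms, 1 if `normalize = FALSE`), `normalized` flag.
#' @export
effective_matrix <- function(ensemble, domain = NULL, normalize = TRUE) {
  stopifnot(inherits(ensemble, "heartcs_ensemble"))
  A <- if (is.null(domain)) ensemble$phi else {
    stopifnot(inherits(domain, "heartcs_domain"))
    if (nrow(domain$atoms) != ensemble$n)
      stop("domain dimension does not match the ensemble dimension N")
    ensemble$phi %*% domain$atoms
  }
  col_scale <- rep(1, ncol(A))
  if (normalize) {
    nrm <- sqrt(colSums(A^2))
    nrm[nrm < 1e-12] <- 1
    A <- sweep(A, 2L, nrm, `/`)
    col_scale <- nrm
  }
  list(A = A, col_scale = col_scale, normalized = normalize)
}
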