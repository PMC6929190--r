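#' Greedy sparse recovery
#'
#' Three greedy solvers for the compressed-sensing recovery problem
#' `y = A theta` with sparse `theta`:
#'
#' * [omp()] — orthogonal matching pursuit: one atom (the most correlated
#'   with the residual) per iteration; needs the sparsity `k` a priori.
#' * [swomp()] — stagewise weak OMP: every atom whose correlation reaches
#'   a weak threshold `alpha * max` joins the support each iteration; no
#'   sparsity needed, but the threshold and iteration count are manual.
#' * [swamp()] — sparsity-adaptive staged variant: estimates an initial
#'   sparsity from a restricted-isometry bound, corrects the threshold so
#'   the first selection has at least that many atoms, then grows the
#'   support in stages of increasing step size, capped at half the number
#'   of measurements.
#'
#' All three re-fit the coefficients by least squares on the current
#' support after every selection, so the residual stays orthogonal to the
#' selected atoms and its norm never increases.
#'
#' @name recovery
NULL

# Least-squares fit of y on A[, support]. Returns the coefficient vector
# (length = |support|) and the residual. Falls back to the minimum-norm
# solution (SVD pseudoinverse) with a warning when the support matrix is
# rank deficient.
ls_fit <- function(y, A, support) {
  As <- A[, support, drop = FALSE]
  qr_d <- qr(As)
  if (qr_d$rank < length(support)) {
    warning("rank-deficient support matrix; using minimum-norm solution")
    sv <- svd(As)
    pos <- sv$d > max(sv$d) * 1e-12
    coef <- sv$v[, pos, drop = FALSE] %*%
      ((crossprod(sv$u[, pos, drop = FALSE], y)) / sv$d[pos])
    coef <- drop(coef)
  } else {
    coef <- qr.coef(qr_d, y)
  }
  list(coef = coef, residual = y - drop(As %*% coef))
}

new_recovery_result <- function(K, support, coef, residual, iterations,
                                stage_trace, terminated_by) {
  theta <- numeric(K)
  if (length(support)) theta[support] <- coef
  structure(
    list(theta_hat = theta, support = support,
         residual_norm = sqrt(sum(residual^2)), residual = residual,
         iterations = iterations,
         stage_trace = do.call(rbind, stage_trace),
         terminated_by = terminated_by),
    class = "heartcs_recovery"
  )
}

#' @export
print.heartcs_recovery <- function(x, ...) {
  cat(sprintf(
    "<heartcs_recovery> support=%d atoms, residual=%.4g, %d iterations (%s)\n",
    length(x$support), x$residual_norm, x$iterations, x$terminated_by))
  invisible(x)
}

trace_row <- function(stage, L, support_size, residual_norm) {
  data.frame(stage = stage, step = L, support_size = support_size,
             residual_norm = residual_norm)
}

#' Orthogonal matching pursuit
#'
#' @param y observation vector (length M).
#' @param A M x K recovery matrix (columns correlate against the
#'   residual; unit-norm columns recommended, see [effective_matrix()]).
#' @param sparsity number of atoms to select (at most M); one of
#'   `sparsity` / `tol` must be given.
#' @param tol stop early once the residual Euclidean norm falls to `tol`.
#' @return a `heartcs_recovery` with fields `theta_hat`, `support`
#'   (selection order), `residual_norm`, `iterations`, `stage_trace`,
#'   `terminated_by`.
#' @export
omp <- function(y, A, sparsity = NULL, tol = NULL) {
  y <- as.numeric(y)
  if (nrow(A) != length(y)) stop("A must have as many rows as length(y)")
  K <- ncol(A)
  M <- nrow(A)
  if (is.null(sparsity) && is.null(tol))
    stop("one of sparsity or tol must be supplied")
  kmax <- if (is.null(sparsity)) M else min(as.integer(sparsity), M)
  if (kmax < 1) stop("sparsity must be >= 1")
  rtol <- if (is.null(tol)) -1 else tol

  support <- integer(0)
  r <- y
  trace <- list(trace_row(0L, 0L, 0L, sqrt(sum(r^2))))
  coef <- numeric(0)
  terminated <- "max_iter"
  it <- 0L
  for (k in seq_len(kmax)) {
    if (sqrt(sum(r^2)) <= rtol) { terminated <- "residual_tol"; break }
    u <- abs(drop(crossprod(A, r)))
    u[support] <- -Inf
    j <- which.max(u)          # lowest index wins ties
    if (!is.finite(u[j]) || u[j] <= 0) { terminated <- "stagnation"; break }
    support <- c(support, j)
    fit <- ls_fit(y, A, support)
    coef <- fit$coef
    r <- fit$residual
    it <- k
    trace[[length(trace) + 1L]] <- trace_row(k, 1L, length(support),
                                             sqrt(sum(r^2)))
  }
  if (terminated == "max_iter" && sqrt(sum(r^2)) <= rtol)
    terminated <- "residual_tol"
  new_recovery_result(K, support, coef, r, it, trace, terminated)
}

#' Stagewise weak orthogonal matching pursuit (SWOMP)
#'
#' Each iteration computes the correlation vector `u = |t(A) r|` and
#' admits every not-yet-selected atom with `u >= alpha * max(u)` into the
#' support, then re-fits by least squares. Iteration stops when the index
#' set stagnates (no new atom admitted) or after `max_iterations` passes.
#'
#' @inheritParams omp
#' @param alpha weak-selection threshold in (0, 1]; `alpha = 1` with a
#'   unique maximum reproduces OMP's one-atom rule. Typical cardiac
#'   settings: 0.83 (ECG at compression ratio 0.7), 0.7 (PPG at 0.5).
#' @param max_iterations iteration budget S.
#' @param tol optional residual norm for early stop.
#' @return a `heartcs_recovery`.
#' @export
swomp <- function(y, A, alpha = 0.83, max_iterations = 20, tol = NULL) {
  y <- as.numeric(y)
  if (nrow(A) != length(y)) stop("A must have as many rows as length(y)")
  if (!is.finite(alpha) || alpha <= 0 || alpha > 1)
    stop("alpha must lie in (0, 1]")
  if (max_iterations < 1) stop("max_iterations must be >= 1")
  K <- ncol(A)
  rtol <- if (is.null(tol)) -1 else tol

  support <- integer(0)
  coef <- numeric(0)
  r <- y
  trace <- list(trace_row(0L, 0L, 0L, sqrt(sum(r^2))))
  if (sqrt(sum(r^2)) == 0)
    return(new_recovery_result(K, support, coef, r, 0L, trace, "stagnation"))

  terminated <- "max_iter"
  it <- 0L
  for (k in seq_len(max_iterations)) {
    u <- abs(drop(crossprod(A, r)))
    u[support] <- -Inf
    mx <- max(u)
    if (!is.finite(mx) || mx <= 1e-14) { terminated <- "stagnation"; break }
    J0 <- which(u >= alpha * mx)
    if (length(J0) == 0L) { terminated <- "stagnation"; break }
    support <- c(support, J0[order(-u[J0], J0)])
    fit <- ls_fit(y, A, support)
    coef <- fit$coef
    r <- fit$residual
    it <- k
    trace[[length(trace) + 1L]] <- trace_row(k, length(J0), length(support),
                                             sqrt(sum(r^2)))
    if (sqrt(sum(r^2)) <= rtol) { terminated <- "residual_tol"; break }
    if (length(support) >= nrow(A)) { terminated <- "support_cap"; break }
  }
  new_recovery_result(K, support, coef, r, it, trace, terminated)
}

#' Restricted-isometry initial sparsity estimate
#'
#' Starting from `k0 = 1`, let `Lambda0` hold the indices of the `k0`
#' largest entries of `|t(A) y|`. While
#' `||t(A[, Lambda0]) y|| <= sqrt((1 - delta_k) / (1 + delta_k)) * ||y||`
#' the candidate sparsity is too small and is advanced by `L0`; the first
#' `k0` passing the test (a lower bound on the true sparsity under the
#' restricted isometry property) is returned, capped at `cap`.
#'
#' @inheritParams omp
#' @param L0 increment step (>= 1).
#' @param delta_k restricted isometry constant in \[0, 1).
#' @param cap upper bound on the estimate (with a warning when reached).
#' @return integer `k0 >= 1` (0 for an all-zero observation).
#' @export
estimate_initial_sparsity <- function(y, A, L0 = 5, delta_k = 0.3,
                                      cap = floor(nrow(A) / 2)) {
  y <- as.numeric(y)
  if (delta_k < 0 || delta_k >= 1) stop("delta_k must lie in [0, 1)")
  if (L0 < 1) stop("initial step L0 must be >= 1")
  ynorm <- sqrt(sum(y^2))
  if (ynorm == 0) return(0L)
  u2 <- sort(drop(crossprod(A, y))^2, decreasing = TRUE)
  # ||t(A[,Lambda0]) y|| over the top-k0 correlations is the norm of that
  # subvector of t(A) y, so the test reduces to cumulative sums of u^2
  cum <- cumsum(u2)
  rhs2 <- (1 - delta_k) / (1 + delta_k) * ynorm^2
  k0 <- 1L
  while (k0 <= length(cum) && cum[min(k0, length(cum))] <= rhs2) {
    k0 <- k0 + as.integer(L0)
    if (k0 >= cap) {
      warning("initial sparsity estimate reached the support cap")
      return(as.integer(cap))
    }
  }
  min(as.integer(k0), as.integer(cap))
}

#' SWAMP solver configuration
#'
#' @param alpha weak-selection threshold in (0, 1] (default 0.83, the
#'   cardiac ECG setting at compression ratio 0.7).
#' @param L0 initial stage step size (atoms added per stage at stage 1).
#' @param delta_k restricted isometry constant for the initial sparsity
#'   estimate, in \[0, 1).
#' @param smax_fraction support cap as a fraction of M (default 1/2, the
#'   `Smax = M/2` rule).
#' @param eps1 residual-norm termination tolerance (default 1e-3,
#'   absolute; set `eps1_relative = TRUE` to scale by `||y||`).
#' @param eps1_relative interpret `eps1` relative to `||y||`.
#' @param alpha_adjust multiplicative threshold correction factor in
#'   (0, 1): `alpha <- alpha * alpha_adjust` to admit more atoms,
#'   `alpha <- min(1, alpha / alpha_adjust)` to admit fewer.
#' @param max_stages stage budget.
#' @param step_growth `"linear"` (stage s adds up to `s * L0` atoms) or
#'   `"compound"` (`L <- stage * L`).
#' @return a `heartcs_swamp_config` list.
#' @export
swamp_config <- function(alpha = 0.83, L0 = 5, delta_k = 0.3,
                         smax_fraction = 0.5, eps1 = 1e-3,
                         eps1_relative = FALSE, alpha_adjust = 0.95,
                         max_stages = 500, step_growth = c("linear", "compound")) {
  step_growth <- match.arg(step_growth)
  if (!is.finite(alpha) || alpha <= 0 || alpha > 1)
    stop("alpha must lie in (0, 1]")
  if (L0 < 1) stop("initial step L0 must be >= 1")
  if (delta_k < 0 || delta_k >= 1) stop("delta_k must lie in [0, 1)")
  if (smax_fraction <= 0 || smax_fraction > 1)
    stop("smax_fraction must lie in (0, 1]")
  if (alpha_adjust <= 0 || alpha_adjust >= 1)
    stop("alpha_adjust must lie in (0, 1)")
  structure(
    list(alpha = alpha, L0 = as.integer(L0), delta_k = delta_k,
         smax_fraction = smax_fraction, eps1 = eps1,
         eps1_relative = eps1_relative, alpha_adjust = alpha_adjust,
         max_stages = as.integer(max_stages), step_growth = step_growth),
    class = "heartcs_swamp_config"
  )
}

#' Sparsity-adaptive staged weak matching pursuit (SWAMP)
#'
#' The improved staged solver. The procedure:
#'
#' 1. Estimate an initial sparsity `k0` from the restricted-isometry
#'    bound ([estimate_initial_sparsity()]).
#' 2. Correct the weak threshold `alpha` until the number of atoms whose
#'    correlation with `y` reaches `alpha * max` lies in `[k0, Smax]`
#'    (decrease `alpha` when too few, increase when too many).
#' 3. Sort those atoms by correlation, descending, and seed the support
#'    with the strongest `k0`; fit by least squares.
#' 4. Staged growth: each stage recomputes correlations against the
#'    current residual, admits at most `L = stage * L0` new atoms above
#'    the threshold (strongest first), re-fits and updates the residual.
#' 5. Terminate when the residual norm reaches `eps1`, when admitting a
#'    stage's atoms would push the support past `Smax = floor(M/2)`
#'    (returning the previous support's estimate), when no admissible
#'    atom remains (stagnation), or at the stage budget.
#'
#' @inheritParams omp
#' @param config a [swamp_config()].
#' @return a `heartcs_recovery`; `stage_trace` records the support size
#'   and residual norm after every stage, and `terminated_by` is one of
#'   `"residual_tol"`, `"support_cap"`, `"stagnation"`, `"max_iter"`.
#' @export
swamp <- function(y, A, config = swamp_config()) {
  stopifnot(inherits(config, "heartcs_swamp_config"))
  y <- as.numeric(y)
  if (nrow(A) != length(y)) stop("A must have as many rows as length(y)")
  K <- ncol(A)
  M <- nrow(A)
  smax <- max(1L, floor(config$smax_fraction * M))
  trace <- list(trace_row(0L, 0L, 0L, sqrt(sum(y^2))))
  if (sqrt(sum(y^2)) == 0)
    return(new_recovery_result(K, integer(0), numeric(0), y, 0L, trace,
                               "stagnation"))
  eps <- if (config$eps1_relative) config$eps1 * sqrt(sum(y^2)) else config$eps1

  k0 <- estimate_initial_sparsity(y, A, L0 = config$L0,
                                  delta_k = config$delta_k, cap = smax)
  k0 <- max(1L, k0)

  # threshold correction: bracket the first-selection count into [k0, smax]
  u <- abs(drop(crossprod(A, y)))
  mx <- max(u)
  alpha <- config$alpha
  for (adj in seq_len(101L)) {
    n_sel <- sum(u >= alpha * mx)
    if (n_sel >= k0 && n_sel <= smax) break
    if (adj > 100L)
      stop(sprintf(
        "threshold correction failed to bracket [%d, %d] within 100 adjustments (alpha=%.4g)",
        k0, smax, alpha))
    if (n_sel < k0) alpha <- alpha * config$alpha_adjust
    else alpha <- min(1, alpha / config$alpha_adjust)
  }

  cand <- which(u >= alpha * mx)
  cand <- cand[order(-u[cand], cand)]
  support <- cand[seq_len(min(k0, length(cand)))]
  fit <- ls_fit(y, A, support)
  coef <- fit$coef
  r <- fit$residual
  trace[[length(trace) + 1L]] <- trace_row(1L, length(support),
                                           length(support), sqrt(sum(r^2)))
  if (sqrt(sum(r^2)) <= eps)
    return(new_recovery_result(K, support, coef, r, 1L, trace, "residual_tol"))

  stage <- 1L
  L <- config$L0
  terminated <- "max_iter"
  it <- 1L
  for (s in seq_len(config$max_stages)) {
    u <- abs(drop(crossprod(A, r)))
    u[support] <- -Inf
    mx <- max(u)
    if (!is.finite(mx) || mx <= 1e-14) { terminated <- "stagnation"; break }
    Jt <- which(u >= alpha * mx)
    if (length(Jt) == 0L) { terminated <- "stagnation"; break }
    Jt <- Jt[order(-u[Jt], Jt)]
    if (length(Jt) > L) Jt <- Jt[seq_len(L)]
    if (length(support) + length(Jt) > smax) {
      terminated <- "support_cap"
      break
    }
    support <- c(support, Jt)
    fit <- ls_fit(y, A, support)
    coef <- fit$coef
    r <- fit$residual
    it <- it + 1L
    trace[[length(trace) + 1L]] <- trace_row(stage + 1L, length(Jt),
                                             length(support), sqrt(sum(r^2)))
    if (sqrt(sum(r^2)) <= eps) { terminated <- "residual_tol"; break }
    stage <- stage + 1L
    L <- if (config$step_growth == "linear") stage * config$L0
         else stage * L
  }
  new_recovery_result(K, support, coef, r, it, trace, terminated)
}

#' Map recovered coefficients back to the signal domain
#'
#' Computes `x_hat = D theta_hat`. When recovery ran against a
#' column-normalized effective matrix, pass its `col_scale` so the
#' coefficients are rescaled to the original dictionary scale first.
#'
#' @param result a `heartcs_recovery`.
#' @param domain a `heartcs_domain`, or `NULL` for the identity domain.
#' @param col_scale optional length-K column norms from
#'   [effective_matrix()].
#' @return numeric reconstruction of length N.
#' @export
reconstruct_signal <- function(result, domain = NULL, col_scale = NULL) {
  stopifnot(inherits(result, "heartcs_recovery"))
  theta <- result$theta_hat
  if (!is.null(col_scale)) theta <- theta / col_scale
  if (is.null(domain)) return(theta)
  synthesize(domain, theta)
}

#' One-call compressed-sensing reconstruction
#'
#' Convenience wrapper: builds `A = Phi D` (column-normalized), runs the
#' requested solver, and maps the estimate back to the signal domain.
#'
#' @param observation a [sense()] result.
#' @param domain a `heartcs_domain` or `NULL` (identity).
#' @param algorithm `"swamp"`, `"swomp"` or `"omp"`.
#' @param ... solver arguments: `config` for swamp; `alpha`,
#'   `max_iterations` for swomp; `sparsity`, `tol` for omp.
#' @return list with `x_hat` (length N), `result` (the
#'   `heartcs_recovery`) and `theta` (domain-scale coefficients).
#' @export
cs_reconstruct <- function(observation, domain = NULL,
                           algorithm = c("swamp", "swomp", "omp"), ...) {
  stopifnot(inherits(observation, "heartcs_observation"))
  algorithm <- match.arg(algorithm)
  eff <- effective_matrix(observation$ensemble, domain)
  result <- switch(algorithm,
                   swamp = swamp(observation$y, eff$A, ...),
                   swomp = swomp(observation$y, eff$A, ...),
                   omp = omp(observation$y, eff$A, ...))
  theta <- result$theta_hat / eff$col_scale
  x_hat <- if (is.null(domain)) theta else synthesize(domain, theta)
  list(x_hat = x_hat, result = result, theta = theta)
}
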