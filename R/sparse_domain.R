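#' Sparse representation domains
#'
#' A `heartcs_domain` holds an N x K atom matrix whose columns are
#' unit-norm atoms: either the orthonormal type-II DCT basis (K = N) or a
#' redundant dictionary learned by K-SVD (typically K < N or K > N
#' depending on the design; the classic cardiac-signal setup uses
#' N = 1024 signal windows and K = 800 atoms).
#'
#' @name sparse-domain
NULL

new_domain <- function(atoms, kind, meta = list()) {
  structure(list(atoms = atoms, kind = kind, meta = meta),
            class = "heartcs_domain")
}

#' @export
print.heartcs_domain <- function(x, ...) {
  cat(sprintf("<heartcs_domain> kind=%s N=%d K=%d\n",
              x$kind, nrow(x$atoms), ncol(x$atoms)))
  invisible(x)
}

#' Orthonormal DCT-II basis
#'
#' Builds the N x N orthonormal type-II discrete cosine transform basis.
#' Column j is the atom `c_j * cos(pi * (2t + 1) * (j - 1) / (2N))` with
#' `c_1 = sqrt(1/N)` and `c_j = sqrt(2/N)` otherwise, so the atom matrix
#' satisfies `t(Psi) %*% Psi = I` to machine precision.
#'
#' @param n signal dimension, `n >= 1`.
#' @return a `heartcs_domain` of kind `"dct"`.
#' @export
#' @examples
#' d <- dct_domain(8)
#' max(abs(crossprod(d$atoms) - diag(8)))
dct_domain <- function(n) {
  if (!is.finite(n) || n < 1) stop("DCT dimension must be >= 1")
  n <- as.integer(n)
  t_idx <- seq_len(n) - 1L
  j_idx <- seq_len(n) - 1L
  atoms <- outer(t_idx, j_idx, function(t, j) cos(pi * (2 * t + 1) * j / (2 * n)))
  scale <- c(sqrt(1 / n), rep(sqrt(2 / n), n - 1L))
  atoms <- sweep(atoms, 2L, scale, `*`)
  new_domain(atoms, "dct", meta = list(N = n, K = n))
}

#' Cut a recording into fixed-length training windows
#'
#' Splits the sample vector into consecutive non-overlapping windows of
#' length `n`, dropping any trailing remainder. A corpus of 1,024,000
#' samples with `n = 1024` yields 1000 training segments.
#'
#' @param sig a [signal()] or numeric vector.
#' @param n window length.
#' @return a `heartcs_corpus`: list with `segments` (n x m matrix, one
#'   column per window) and `n`.
#' @export
segment_corpus <- function(sig, n) {
  x <- if (inherits(sig, "heartcs_signal")) sig$samples else as.numeric(sig)
  if (!is.finite(n) || n < 1) stop("window length must be >= 1")
  n <- as.integer(n)
  m <- floor(length(x) / n)
  if (m == 0L) {
    warning("signal shorter than one window; corpus is empty")
    segs <- matrix(numeric(0), nrow = n, ncol = 0)
  } else {
    segs <- matrix(x[seq_len(m * n)], nrow = n, ncol = m)
  }
  structure(list(segments = segs, n = n), class = "heartcs_corpus")
}

# Batch OMP sparse coding of corpus columns against the current atoms.
# Lean inner loop (no trace bookkeeping); returns a K x m coefficient
# matrix with at most `k` nonzeros per column.
code_corpus <- function(atoms, segs, k) {
  K <- ncol(atoms)
  m <- ncol(segs)
  codes <- matrix(0, nrow = K, ncol = m)
  for (j in seq_len(m)) {
    y <- segs[, j]
    r <- y
    support <- integer(0)
    coef <- numeric(0)
    for (step in seq_len(k)) {
      u <- abs(drop(crossprod(atoms, r)))
      if (length(support)) u[support] <- -Inf
      jj <- which.max(u)
      if (!is.finite(u[jj]) || u[jj] <= 1e-14) break
      support <- c(support, jj)
      As <- atoms[, support, drop = FALSE]
      coef <- tryCatch(qr.coef(qr(As), y), error = function(e) NULL)
      if (is.null(coef) || anyNA(coef)) { support <- support[-length(support)]; break }
      r <- y - drop(As %*% coef)
    }
    if (length(support)) codes[support, j] <- coef
  }
  codes
}

#' Train a redundant dictionary with K-SVD
#'
#' Alternates (a) OMP sparse coding of every training segment at
#' `coding_sparsity` nonzeros against the current atoms with (b) per-atom
#' updates by rank-1 SVD of the residual restricted to the segments using
#' that atom (updating both the atom and its coefficients). Atoms are
#' re-normalized after every update and their sign fixed so the first
#' nonzero entry is non-negative; an atom used by no segment is replaced
#' by the worst-represented segment, normalized. A segment's new code is
#' kept only if it does not increase that segment's residual, which makes
#' the mean squared representation error non-increasing across
#' iterations.
#'
#' @param corpus a [segment_corpus()] result with at least one segment.
#' @param K number of atoms (classic cardiac setup: 800 atoms for
#'   1024-sample windows). Initial atoms are `K` distinct training
#'   segments drawn by seeded sampling, normalized.
#' @param coding_sparsity nonzeros per segment during sparse coding;
#'   default `ceiling(n / 20)`.
#' @param iterations number of K-SVD sweeps (default 30).
#' @param seed RNG seed for initialization.
#' @return a `heartcs_domain` of kind `"ksvd"`; `meta$error_trace` holds
#'   the mean squared representation error after every iteration.
#' @export
ksvd_train <- function(corpus, K, coding_sparsity = NULL, iterations = 30,
                       seed = 1L) {
  stopifnot(inherits(corpus, "heartcs_corpus"))
  segs <- corpus$segments
  n <- corpus$n
  m <- ncol(segs)
  if (m == 0L) stop("cannot train a dictionary on an empty corpus")
  if (!is.finite(K) || K < 1) stop("atom count K must be >= 1")
  K <- as.integer(K)
  if (is.null(coding_sparsity)) coding_sparsity <- ceiling(n / 20)
  coding_sparsity <- max(1L, min(as.integer(coding_sparsity), n))

  atoms <- with_seed(seed, {
    init_idx <- if (K <= m) sample.int(m, K) else
      c(seq_len(m), sample.int(m, K - m, replace = TRUE))
    a <- segs[, init_idx, drop = FALSE]
    # guard against all-zero initial segments
    for (j in seq_len(K)) {
      nrm <- sqrt(sum(a[, j]^2))
      if (nrm < 1e-12) a[, j] <- stats::rnorm(n)
    }
    a
  })
  atoms <- normalize_atoms(atoms)

  codes <- matrix(0, nrow = K, ncol = m)
  err_trace <- numeric(iterations)
  for (it in seq_len(iterations)) {
    new_codes <- code_corpus(atoms, segs, coding_sparsity)
    # monotonicity guard: keep a segment's previous code if recoding hurt
    if (it > 1L) {
      old_err <- colSums((segs - atoms %*% codes)^2)
      new_err <- colSums((segs - atoms %*% new_codes)^2)
      keep_old <- new_err > old_err + 1e-12
      new_codes[, keep_old] <- codes[, keep_old]
    }
    codes <- new_codes

    resid <- segs - atoms %*% codes
    for (j in seq_len(K)) {
      users <- which(codes[j, ] != 0)
      if (length(users) == 0L) {
        # dead atom: replace by the worst-represented segment
        worst <- which.max(colSums(resid^2))
        a <- segs[, worst]
        nrm <- sqrt(sum(a^2))
        if (nrm > 1e-12) atoms[, j] <- a / nrm
        next
      }
      # restricted residual with atom j's contribution added back
      E <- resid[, users, drop = FALSE] +
        atoms[, j, drop = FALSE] %*% codes[j, users, drop = FALSE]
      sv <- svd(E, nu = 1L, nv = 1L)
      new_atom <- sv$u[, 1L]
      new_coef <- sv$d[1L] * sv$v[, 1L]
      atoms[, j] <- new_atom
      codes[j, users] <- new_coef
      resid[, users] <- E - new_atom %*% t(new_coef)
    }
    atoms_signed <- normalize_atoms(atoms)
    # carry sign flips into the codes so the representation is unchanged
    flips <- colSums(atoms_signed * atoms)
    codes <- codes * sign(ifelse(abs(flips) < 1e-12, 1, flips))
    atoms <- atoms_signed
    err_trace[it] <- mean(colSums((segs - atoms %*% codes)^2)) / n
  }
  new_domain(atoms, "ksvd",
             meta = list(N = n, K = K, iterations = iterations,
                         coding_sparsity = coding_sparsity, seed = seed,
                         error_trace = err_trace))
}

# Unit-normalize columns and fix sign: first entry of modulus > tol made
# non-negative to stabilize round-trip comparisons.
normalize_atoms <- function(atoms, tol = 1e-12) {
  nrm <- sqrt(colSums(atoms^2))
  nrm[nrm < tol] <- 1
  atoms <- sweep(atoms, 2L, nrm, `/`)
  for (j in seq_len(ncol(atoms))) {
    nz <- which(abs(atoms[, j]) > tol)
    if (length(nz) && atoms[nz[1L], j] < 0) atoms[, j] <- -atoms[, j]
  }
  atoms
}

#' Analyze a signal vector in a sparse domain
#'
#' For the orthonormal DCT domain this is the exact transform
#' `t(atoms) %*% x`. For a redundant K-SVD dictionary the coefficients
#' are computed by OMP at the requested sparsity, so only approximate
#' inversion is promised.
#'
#' @param domain a `heartcs_domain`.
#' @param x numeric signal vector of length N.
#' @param sparsity nonzeros for OMP coding (redundant dictionaries only;
#'   default the dictionary's training `coding_sparsity`).
#' @return length-K coefficient vector.
#' @export
analyze <- function(domain, x, sparsity = NULL) {
  stopifnot(inherits(domain, "heartcs_domain"))
  x <- as.numeric(x)
  if (length(x) != nrow(domain$atoms))
    stop("signal length does not match the domain dimension")
  if (domain$kind == "dct") return(drop(crossprod(domain$atoms, x)))
  if (is.null(sparsity)) sparsity <- domain$meta$coding_sparsity
  if (is.null(sparsity)) sparsity <- ceiling(nrow(domain$atoms) / 20)
  res <- omp(x, domain$atoms, sparsity = sparsity)
  res$theta_hat
}

#' Synthesize a signal from sparse coefficients
#'
#' @param domain a `heartcs_domain`.
#' @param theta length-K coefficient vector.
#' @return length-N signal vector `atoms %*% theta`.
#' @export
synthesize <- function(domain, theta) {
  stopifnot(inherits(domain, "heartcs_domain"))
  theta <- as.numeric(theta)
  if (length(theta) != ncol(domain$atoms))
    stop("coefficient length does not match the number of atoms")
  drop(domain$atoms %*% theta)
}

#' Persist / load a dictionary as delimited text
#'
#' The atom matrix is written as a whitespace-delimited table (rows =
#' signal dimension) with a JSON sidecar `<path>.json` recording kind, N,
#' K and training provenance.
#'
#' @param domain a `heartcs_domain`.
#' @param path destination path for the matrix.
#' @return `path` invisibly (`write_domain`); a `heartcs_domain`
#'   (`read_domain`).
#' @export
write_domain <- function(domain, path) {
  stopifnot(inherits(domain, "heartcs_domain"))
  utils::write.table(format(domain$atoms, digits = 17, trim = TRUE,
                            scientific = TRUE),
                     path, sep = " ", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  meta <- domain$meta
  meta$kind <- domain$kind
  meta$error_trace <- NULL
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_domain
#' @export
read_domain <- function(path) {
  atoms <- as.matrix(utils::read.table(path, header = FALSE))
  dimnames(atoms) <- NULL
  meta_path <- paste0(path, ".json")
  meta <- if (file.exists(meta_path))
    jsonlite::read_json(meta_path, simplifyVector = TRUE) else list()
  kind <- if (!is.null(meta$kind)) meta$kind else "ksvd"
  meta$kind <- NULL
  new_domain(atoms, kind, meta)
}
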