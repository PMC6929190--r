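#' Construct a sampled biosignal
#'
#' A `heartcs_signal` wraps a numeric sample vector with its sampling rate,
#' an optional subject label, and a kind tag (`"ecg"`, `"ppg"` or
#' `"generic"`). ECG samples are interpreted as millivolts; PPG samples are
#' in arbitrary units.
#'
#' @param samples numeric vector of samples, all finite, length >= 1.
#' @param fs sampling rate in Hz, positive scalar. Cardiac recordings are
#'   typically sampled at 500 Hz.
#' @param subject_id optional subject identifier (character scalar or `NA`).
#' @param kind one of `"ecg"`, `"ppg"`, `"generic"`.
#' @return an object of class `heartcs_signal` with fields `samples`, `fs`,
#'   `subject_id`, `kind`.
#' @export
#' @examples
#' s <- signal(sin(seq(0, 2 * pi, length.out = 100)), fs = 500)
#' length(s$samples)
signal <- function(samples, fs, subject_id = NA_character_, kind = "generic") {
  samples <- as.numeric(samples)
  if (length(samples) < 1L) stop("signal must contain at least one sample")
  if (!all(is.finite(samples))) stop("signal samples must all be finite")
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("sampling rate fs must be a positive finite scalar")
  kind <- match.arg(kind, c("ecg", "ppg", "generic"))
  structure(
    list(samples = samples, fs = as.numeric(fs),
         subject_id = as.character(subject_id), kind = kind),
    class = "heartcs_signal"
  )
}

#' @export
print.heartcs_signal <- function(x, ...) {
  cat(sprintf("<heartcs_signal> kind=%s fs=%g Hz n=%d (%.2f s)%s\n",
              x$kind, x$fs, length(x$samples), length(x$samples) / x$fs,
              if (!is.na(x$subject_id)) paste0(" subject=", x$subject_id) else ""))
  invisible(x)
}

#' Read a signal from delimited text
#'
#' The format is one header line `fs,<Hz>` followed by one sample per line.
#' Lines starting with `#` are ignored; both Unix and Windows line endings
#' are accepted.
#'
#' @param path file path.
#' @param kind signal kind tag to attach (`"ecg"`, `"ppg"`, `"generic"`).
#' @return a [signal()] object.
#' @export
read_signal <- function(path, kind = "generic") {
  if (!file.exists(path)) stop("signal file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (length(idx) == 0L) stop("format error in ", path, ": empty signal file")
  header <- lines[idx[1L]]
  m <- regmatches(header, regexec("^fs\\s*,\\s*([0-9.eE+-]+)\\s*$", header))[[1L]]
  if (length(m) < 2L)
    stop("format error in ", path, " line ", idx[1L],
         ": expected header 'fs,<Hz>', got '", header, "'")
  fs <- as.numeric(m[2L])
  body <- lines[idx[-1L]]
  if (length(body) == 0L) stop("format error in ", path, ": no samples after header")
  samples <- suppressWarnings(as.numeric(body))
  if (anyNA(samples)) {
    bad <- idx[-1L][which(is.na(samples))[1L]]
    stop("format error in ", path, " line ", bad, ": non-numeric sample")
  }
  signal(samples, fs = fs, kind = kind)
}

#' Write a signal as delimited text
#'
#' Emits the header `fs,<Hz>` and one sample per line, full double
#' precision, so that `read_signal(write_signal(s))` round-trips exactly.
#'
#' @param sig a [signal()] object.
#' @param path destination file path.
#' @return `path`, invisibly.
#' @export
write_signal <- function(sig, path) {
  stopifnot(inherits(sig, "heartcs_signal"))
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(sprintf("fs,%.17g", sig$fs), con)
  writeLines(sprintf("%.17g", sig$samples), con)
  invisible(path)
}

#' Write fiducial ground truth as a two-column table
#'
#' @param fiducials data frame with columns `name` and `index` (and
#'   optionally `beat`).
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_fiducials <- function(fiducials, path) {
  utils::write.table(fiducials, path, sep = ",", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

# Derive a per-stage RNG seed from a global seed and a stage name.
# Stable string hash keeps streams independent of stage ordering and
# below 2^31 so the value is a valid R integer seed.
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)) * 131L)
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}

# Evaluate `expr` under a local RNG seed without disturbing the caller's
# RNG state. All package randomness flows through this helper.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed %% 2147483647))
  }
  expr
}
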