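#' Derive a stage seed from a global seed and a tag
#'
#' All randomness in the package flows through seeds derived from one
#' user-facing integer seed, so that a single integer reproduces a whole
#' experiment. The derivation is a small multiplicative hash of the tag
#' string folded into the seed, kept strictly below 2^31 - 1 so the result
#' is always a valid R integer seed.
#'
#' @param seed integer global seed.
#' @param tag character scalar naming the consuming stage (e.g. "cohort",
#'   "split3", "train/fl/2400/7").
#' @return an integer in `[1, 2147483646]`.
#' @export
derive_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  stopifnot(is.character(tag), length(tag) == 1L)
  m <- 2147483647 # 2^31 - 1, prime
  h <- (abs(seed) %% m) * 48271 %% m
  for (c in utf8ToInt(tag)) {
    h <- (h * 31 + c) %% m
  }
  as.integer(h %% (m - 1)) + 1L
}

# internal: consistent parameter error with the offending field named
stop_param <- function(fmt, ...) {
  stop(sprintf(fmt, ...), call. = FALSE)
}

# internal: check a single non-negative finite scalar
check_scalar <- function(x, name, min = -Inf, max = Inf, integer = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_param("'%s' must be a finite numeric scalar", name)
  }
  if (x < min) stop_param("'%s' must be >= %s (got %s)", name, min, x)
  if (x > max) stop_param("'%s' must be <= %s (got %s)", name, max, x)
  if (integer && x != round(x)) stop_param("'%s' must be an integer", name)
  invisible(TRUE)
}

# internal: run code with a local RNG seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# internal: full-precision decimal formatting that round-trips doubles
format_full <- function(x) {
  sprintf("%.17g", x)
}
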