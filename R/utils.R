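#' Derive a reproducible child seed from a master seed
#'
#' Independent pseudo-random streams (manifest layout, feature noise, taxa
#' draws, per-pair permutations, imputation draws) are keyed off a single
#' master seed so that a whole run is reproducible from one integer.  The
#' derivation is a fixed affine hash modulo 2^31 - 1, so child seeds stay
#' within R's integer range.
#'
#' @param seed master seed (single integer).
#' @param stream non-negative integer identifying the consumer stream.
#' @return a single integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, stream = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed),
            is.numeric(stream), length(stream) == 1L, stream >= 0)
  m <- 2147483647 # 2^31 - 1, prime
  s <- (abs(as.numeric(seed)) %% m)
  # two rounds of a multiplicative congruential step keyed by the stream id
  s <- (s * 48271 + (as.numeric(stream) %% m) + 1) %% m
  s <- (s * 16807 + 1) %% m
  as.integer(s %% (m - 2) + 1)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' @keywords internal
msg <- function(..., logfile = NULL) {
  txt <- paste0(...)
  message(txt)
  if (!is.null(logfile)) cat(txt, "\n", file = logfile, append = TRUE, sep = "")
  invisible(txt)
}

# strict scalar checks used across constructors
assert_scalar_num <- function(x, name, lo = -Inf, hi = Inf, strict_lo = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a finite numeric scalar", name), call. = FALSE)
  if (x < lo || x > hi || (strict_lo && x <= lo))
    stop(sprintf("'%s' out of range [%s, %s]: %s", name, lo, hi, x), call. = FALSE)
  invisible(x)
}
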