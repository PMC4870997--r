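# Internal helpers shared across modules.

#' @keywords internal
"_PACKAGE"

# Deterministic 31-bit sub-seed for (master seed, unit index, stage salt).
# Gives every subject x stage its own reproducible RNG stream, so simulating
# a subset of subjects yields the same draws as simulating all of them.
derive_seed <- function(seed, index, salt = 0L) {
  s <- (as.numeric(seed) %% 2147483647) * 2654435.0 +
    as.numeric(index) * 97561 + as.numeric(salt) * 1299721
  as.integer(s %% 2147483646) + 1L
}

stopifnot_scalar_num <- function(x, name, lower = -Inf, upper = Inf,
                                 strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a finite numeric scalar", name), call. = FALSE)
  if (strict_lower && x <= lower)
    stop(sprintf("'%s' must be > %g", name, lower), call. = FALSE)
  if (!strict_lower && x < lower)
    stop(sprintf("'%s' must be >= %g", name, lower), call. = FALSE)
  if (x > upper)
    stop(sprintf("'%s' must be <= %g", name, upper), call. = FALSE)
  invisible(x)
}

# zero-padded subject labels S01, S02, ...
subject_labels <- function(n) sprintf("S%02d", seq_len(n))

`%||%` <- function(a, b) if (is.null(a)) b else a
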