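#  internal validation helpers

stop_bad <- function(msg, ...) abort(sprintf(msg, ...), class = "scpnscreen_error")

check_fraction <- function(x, name, closed_low = TRUE, closed_high = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stop_bad("`%s` must be a single number, got %s", name, paste(class(x), collapse = "/"))
  lo_ok <- if (closed_low) x >= 0 else x > 0
  hi_ok <- if (closed_high) x <= 1 else x < 1
  if (!lo_ok || !hi_ok)
    stop_bad("`%s` = %g is outside the %s0, 1%s interval", name, x,
             if (closed_low) "[" else "(", if (closed_high) "]" else ")")
  invisible(x)
}

check_positive <- function(x, name, strict = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || (if (strict) x <= 0 else x < 0))
    stop_bad("`%s` must be a %s number, got %s", name,
             if (strict) "positive" else "non-negative", format(x)[1])
  invisible(x)
}

#' Derive a reproducible child seed from a base seed
#'
#' Deterministically maps `(seed, index)` to a 31-bit integer so that each
#' well/field of a plate draws from its own stream while the whole plate stays
#' reproducible from one top-level seed.
#' @param seed integer base seed.
#' @param index non-negative integer offset.
#' @return a single integer in `[0, 2^31 - 1)`.
#' @keywords internal
child_seed <- function(seed, index) {
  # splitmix-style integer hash, kept in double precision below 2^31
  x <- (as.numeric(seed) * 48271 + as.numeric(index) * 16807 + 12345) %% 2147483647
  as.integer(x)
}
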