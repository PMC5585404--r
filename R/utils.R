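# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' @keywords internal
assert_count <- function(x, name, positive = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != round(x) ||
      (positive && x <= 0) || (!positive && x < 0)) {
    stopf("`%s` must be a single %s integer, got %s", name,
          if (positive) "positive" else "non-negative", deparse(x))
  }
  as.integer(x)
}

# Case-normalize gene symbols: mouse "Gata4" and human "GATA4" unify.
normalize_symbols <- function(x) toupper(trimws(x))

# Linear fold-change magnitude: max(fc, 1/fc), so 0.25 and 4 both map to 4.
fc_magnitude <- function(fc) pmax(fc, 1 / fc)
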