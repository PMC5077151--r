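stopf <- function(fmt, ..., call. = FALSE) {
  stop(sprintf(fmt, ...), call. = call.)
}

warnf <- function(fmt, ...) {
  warning(sprintf(fmt, ...), call. = FALSE)
}

# scalar numeric check; allows Inf only when `finite = FALSE`
check_number <- function(x, name, min = -Inf, finite = TRUE,
                         strict_min = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stopf("`%s` must be a single non-missing number", name)
  }
  if (finite && !is.finite(x)) stopf("`%s` must be finite", name)
  if (strict_min) {
    if (x <= min) stopf("`%s` must be > %s", name, format(min))
  } else if (x < min) {
    stopf("`%s` must be >= %s", name, format(min))
  }
  invisible(x)
}

check_counts <- function(x, name) {
  if (!is.numeric(x) || any(is.na(x)) || any(x < 0)) {
    stopf("`%s` must be non-negative counts", name)
  }
  invisible(x)
}

DNA_BASES <- c("A", "C", "G", "T")
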