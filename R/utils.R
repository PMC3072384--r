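`%||%` <- function(x, y) if (is.null(x)) y else x

stop_field <- function(field, msg) {
  stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
}

# numeric scalar check used by constructors
check_prob <- function(x, field, lo = 0, hi = 1, open_lo = FALSE, open_hi = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop_field(field, "must be a single number")
  }
  ok_lo <- if (open_lo) x > lo else x >= lo
  ok_hi <- if (open_hi) x < hi else x <= hi
  if (!ok_lo || !ok_hi) {
    stop_field(field, sprintf(
      "must be in %s%g, %g%s", if (open_lo) "(" else "[", lo, hi,
      if (open_hi) ")" else "]"
    ))
  }
  invisible(x)
}

check_count <- function(x, field, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != floor(x) || x < min) {
    stop_field(field, sprintf("must be an integer >= %d", min))
  }
  invisible(as.integer(x))
}

# file-system safe version of a node name
safe_name <- function(x) gsub("[^A-Za-z0-9_.-]+", "_", x)
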