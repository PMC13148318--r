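#' @importFrom rlang abort warn inform %||% .data
#' @importFrom tibble tibble as_tibble is_tibble
NULL

# Deterministic 31-bit seed for a named substream of a master seed.
# Polynomial rolling hash over the labels; exact in double arithmetic
# because all intermediates stay below 2^53.
derive_seed <- function(master_seed, ...) {
  stopifnot(is.numeric(master_seed), length(master_seed) == 1)
  labs <- paste(vapply(list(...), as.character, character(1)), collapse = "/")
  h <- abs(as.double(master_seed)) %% 2147483647
  for (ch in utf8ToInt(labs)) {
    h <- (h * 131 + ch) %% 2147483647
  }
  as.integer(h)
}

with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

abort_config <- function(message, ...) {
  abort(message, class = "crenrich_config_error", ...)
}

abort_parse <- function(message, ...) {
  abort(message, class = "crenrich_parse_error", ...)
}

abort_data <- function(message, ...) {
  abort(message, class = "crenrich_data_error", ...)
}

# scalar check helpers used by config validation
is_number <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x)

check_prob <- function(x, name, lo = 0, hi = 1, lo_open = FALSE, hi_open = FALSE) {
  ok <- is_number(x) &&
    (if (lo_open) x > lo else x >= lo) &&
    (if (hi_open) x < hi else x <= hi)
  if (!ok) {
    abort_config(sprintf(
      "`%s` must be a number in %s%g, %g%s, got %s",
      name, if (lo_open) "(" else "[", lo, hi, if (hi_open) ")" else "]",
      paste(format(x), collapse = ", ")
    ))
  }
  invisible(x)
}
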