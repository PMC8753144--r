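# internal argument checks

stop_value <- function(msg, call. = FALSE) stop(msg, call. = call.)

check_positive_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stop_value(sprintf("`%s` must be a single positive finite number", name))
  }
  invisible(x)
}

check_nonneg_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0) {
    stop_value(sprintf("`%s` must be a single non-negative finite number", name))
  }
  invisible(x)
}

check_numeric <- function(x, name) {
  if (!is.numeric(x) || length(x) < 1L || anyNA(x)) {
    stop_value(sprintf("`%s` must be numeric with no missing values", name))
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
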