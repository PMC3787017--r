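# Internal validation helpers shared across modules.

stop_input <- function(...) stop(..., call. = FALSE)

is_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

assert_number <- function(x, name = deparse(substitute(x))) {
  if (!is_number(x)) {
    stop_input(sprintf("`%s` must be a single finite number", name))
  }
  invisible(x)
}

assert_fraction <- function(x, name = deparse(substitute(x))) {
  assert_number(x, name)
  if (x <= 0 || x > 1) {
    stop_input(sprintf("`%s` must lie in (0, 1], got %g", name, x))
  }
  invisible(x)
}

assert_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L) {
    stop_input(sprintf(
      "%s is missing required column(s): %s",
      what, paste(missing, collapse = ", ")
    ))
  }
  invisible(df)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
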