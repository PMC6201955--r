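# Internal validation helpers. All user-facing errors funnel through
# abort_bad_arg() so messages carry the argument name.

abort_bad_arg <- function(arg, msg) {
  stop(sprintf("invalid `%s`: %s", arg, msg), call. = FALSE)
}

check_number <- function(x, arg, lower = -Inf, upper = Inf,
                         allow_null = FALSE) {
  if (is.null(x) && allow_null) return(invisible(x))
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    abort_bad_arg(arg, "must be a single finite number")
  if (x < lower) abort_bad_arg(arg, sprintf("must be >= %g", lower))
  if (x > upper) abort_bad_arg(arg, sprintf("must be <= %g", upper))
  invisible(x)
}

check_interval <- function(x, arg) {
  if (!is.numeric(x) || length(x) != 2L || any(!is.finite(x)))
    abort_bad_arg(arg, "must be a finite numeric interval c(start, end)")
  if (x[2] <= x[1]) abort_bad_arg(arg, "end must exceed start")
  invisible(x)
}

check_prob <- function(x, arg) {
  check_number(x, arg, lower = 0, upper = 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
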