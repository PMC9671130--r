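# internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

abort_bad_arg <- function(field, msg) {
  stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
}

# scalar checks used by config constructors
check_number <- function(x, field, min = -Inf, max = Inf, integerish = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    abort_bad_arg(field, "must be a single non-missing number")
  }
  if (x < min || x > max) {
    abort_bad_arg(field, sprintf("must be in [%s, %s]", min, max))
  }
  if (integerish && x != as.integer(x)) {
    abort_bad_arg(field, "must be a whole number")
  }
  x
}

check_fraction <- function(x, field) check_number(x, field, min = 0, max = 1)

# year axis for an engine config
engine_years <- function(config) seq.int(config$start_year, config$end_year)
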