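# Internal argument validators. Errors name the offending field so that
# configuration mistakes surface immediately at construction time.

stop_field <- function(field, msg) {
  stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
}

check_number <- function(x, field, lower = -Inf, upper = Inf,
                         strict_lower = FALSE, allow_null = FALSE) {
  if (is.null(x)) {
    if (allow_null) return(invisible(x))
    stop_field(field, "must be supplied")
  }
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_field(field, "must be a single finite number")
  if (strict_lower && x <= lower)
    stop_field(field, sprintf("must be > %g", lower))
  if (!strict_lower && x < lower)
    stop_field(field, sprintf("must be >= %g", lower))
  if (x > upper)
    stop_field(field, sprintf("must be <= %g", upper))
  invisible(x)
}

check_count <- function(x, field, lower = 1L) {
  check_number(x, field, lower = lower)
  if (x != as.integer(x)) stop_field(field, "must be a whole number")
  invisible(as.integer(x))
}

check_times <- function(x, field = "sample_times") {
  if (!is.numeric(x) || length(x) < 2L || anyNA(x))
    stop_field(field, "must be a numeric vector of length >= 2")
  if (any(x <= 0)) stop_field(field, "must be strictly positive")
  if (any(diff(x) <= 0)) stop_field(field, "must be strictly increasing")
  invisible(as.numeric(x))
}

check_seed <- function(seed) {
  if (is.null(seed)) return(invisible(NULL))
  check_count(seed, "seed", lower = 0L)
}

# Local RNG scope: seed is applied inside the generator and the caller's
# RNG state is restored afterwards, so no hidden global state leaks.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}
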