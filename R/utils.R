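# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG state without disturbing the caller's stream.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

stop_field <- function(field, msg) {
  stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
}

check_fraction <- function(x, field, allow_one = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 &&
    (if (allow_one) x <= 1 else x < 1)
  if (!ok) stop_field(field, sprintf("must be a single number in [0, 1%s",
                                     if (allow_one) "]" else ")"))
  invisible(x)
}

check_count <- function(x, field, min = 1L) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) && x >= min &&
    x == floor(x)
  if (!ok) stop_field(field, sprintf("must be a single integer >= %d", min))
  invisible(as.integer(x))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
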