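# internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_that <- function(ok, msg) {
  if (!isTRUE(ok)) stop(msg, call. = FALSE)
  invisible(TRUE)
}

is_count <- function(x, min = 0) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= min &&
    abs(x - round(x)) < 1e-8
}

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# run expr with a private RNG stream; global .Random.seed is untouched
with_local_seed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}
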