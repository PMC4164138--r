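# small shared helpers (internal)

`%||%` <- function(a, b) if (is.null(a)) b else a

# half-up rounding, fixed so that .5 always moves away from zero toward the
# next state; base round() is banker's and would silently shift states
round_half_up <- function(x) floor(x + 0.5)

# run code with a private RNG stream, restoring the caller's .Random.seed
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

is_count <- function(x) length(x) == 1L && is.numeric(x) && !is.na(x) &&
  x >= 0 && x == floor(x)

is_prob <- function(x) length(x) == 1L && is.numeric(x) && !is.na(x) &&
  x >= 0 && x <= 1

stop_ <- function(...) stop(sprintf(...), call. = FALSE)
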