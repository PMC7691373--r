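# internal helpers shared across modules

# canonical key for an unordered node pair: identifiers sorted
# lexicographically, joined by a separator that cannot occur in an id
# read from a tab/comma edge list
pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "\r")
}

# evaluate `code` under a temporary RNG state seeded with `seed`,
# restoring the caller's stream afterwards; seed = NULL leaves the
# current stream untouched
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# draw n sub-seeds (31-bit positive integers) from a root seed so that
# independent stages consume independent, reproducible streams
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max, n))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_arg <- function(...) stop(..., call. = FALSE)
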