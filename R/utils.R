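# Internal helpers shared across modules.

# Run `expr` under a fixed RNG seed without disturbing the caller's stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  expr
}

# Derive a 32-bit-safe child seed from a parent seed and an integer stream id.
derive_seed <- function(seed, stream) {
  as.integer((as.double(seed) %% 2147483647 + 104729 * as.double(stream)) %%
               2147483647)
}

# sample() without the length-1 surprise.
sample_one <- function(x) if (length(x) == 1L) x else x[sample.int(length(x), 1L)]

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_input <- function(...) stop(..., call. = FALSE)

assert_count <- function(x, name, min = 0L) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x != floor(x) || x < min)
    stop_input(sprintf("`%s` must be a single integer >= %d", name, min))
  as.integer(x)
}

canonical_key <- function(idx) paste(sort(idx), collapse = ",")
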