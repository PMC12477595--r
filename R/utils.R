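# Internal helpers shared across modules.

# Largest-remainder (Hamilton) rounding of target * weights to integers that
# sum exactly to `total`. Weights must be nonnegative and sum to ~1.
largest_remainder <- function(total, weights) {
  stopifnot(total >= 0, all(weights >= 0))
  exact <- total * weights
  base <- floor(exact)
  rem <- exact - base
  short <- total - sum(base)
  if (short > 0) {
    take <- order(rem, decreasing = TRUE)[seq_len(short)]
    base[take] <- base[take] + 1
  }
  as.integer(base)
}

# Run `expr` under a temporary RNG state seeded with `seed` (if non-NULL),
# restoring the caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed))
    stop("seed must be a single integer", call. = FALSE)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed from a run seed, kept below 2^31.
derive_seed <- function(seed, offset) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) * 7919 + offset) %% 2147483647)
}

reverse_complement <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
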