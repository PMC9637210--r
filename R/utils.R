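# shared small helpers

# derive a child RNG seed from a base seed and a stream index; kept < 2^31
child_seed <- function(seed, stream) {
  (as.integer(seed) * 1009L + as.integer(stream) * 9176L) %% 2147483647L
}

# reverse complement for plain character vectors of DNA
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) rlang::abort(msg)
}

# evaluate expr under a fixed seed, restoring the caller's RNG stream
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}
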