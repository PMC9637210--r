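#' Simulate a genomic target sequence
#'
#' Draws an i.i.d. nucleotide sequence at a target GC content, optionally
#' planting exact duplicated segments so that homology search has known
#' ground truth. Used as the fixture generator for probe design.
#'
#' @param length Sequence length in nt (>= 1000).
#' @param gc_target Expected GC fraction in `[0, 1]`.
#' @param planted_repeats Optional tibble/data frame with columns
#'   `source_start`, `dest_start`, `width` (0-based starts): the segment at
#'   `source_start` is copied verbatim to `dest_start`.
#' @param seed Integer RNG seed; the same seed always yields the same bytes.
#'
#' @return A list with `seq` (character scalar), `name`, and `truth`,
#'   a tibble of planted repeat coordinates (0-based half-open).
#' @export
#'
#' @examples
#' g <- sim_genome(2000, gc_target = 0.45, seed = 1)
#' substr(g$seq, 1, 30)
sim_genome <- function(length, gc_target = 0.5, planted_repeats = NULL,
                       seed = 1L) {
  assert_that(length >= 1000, "genome length must be >= 1 kb")
  assert_that(gc_target >= 0 && gc_target <= 1, "gc_target must be in [0,1]")
  p <- c(A = (1 - gc_target) / 2, C = gc_target / 2,
         G = gc_target / 2, T = (1 - gc_target) / 2)
  bases <- with_seed(seed,
    sample(names(p), length, replace = TRUE, prob = p))
  truth <- tibble(source_start = integer(), dest_start = integer(),
                  width = integer())
  if (!is.null(planted_repeats) && nrow(planted_repeats) > 0) {
    pr <- as_tibble(planted_repeats)
    for (i in seq_len(nrow(pr))) {
      w <- pr$width[i]
      if (w > length) rlang::abort("planted repeat longer than genome")
      src <- pr$source_start[i] + seq_len(w)   # 0-based -> 1-based
      dst <- pr$dest_start[i] + seq_len(w)
      assert_that(max(src) <= length && max(dst) <= length,
                  "planted repeat exceeds genome bounds")
      bases[dst] <- bases[src]
    }
    truth <- tibble(source_start = as.integer(pr$source_start),
                    dest_start = as.integer(pr$dest_start),
                    width = as.integer(pr$width))
  }
  list(seq = paste(bases, collapse = ""),
       name = sprintf("synthetic_region_seed%d", as.integer(seed)),
       truth = truth)
}

#' Write a simulated genome to FASTA
#'
#' @param genome A list from [sim_genome()].
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  ss <- Biostrings::DNAStringSet(genome$seq)
  names(ss) <- genome$name
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}
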