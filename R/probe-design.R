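#' Probe design parameters
#'
#' Bundles the tunable parameters of FRET-FISH probe design. The layout
#' presets name the interleaving of donor (D) and acceptor (A) oligos:
#' `G<g>S<s>` means groups of `g` consecutive same-dye oligos with `s` nt
#' between consecutive oligos of different dyes (between groups); within a
#' group consecutive same-dye oligos sit `spacing_same_dye` nt apart.
#'
#' @param l Target (T) sequence length in nt. Default 60.
#' @param n_total Total number of primary oligos in the probe. Default 300,
#'   the densest layout that fits a ~20 kb region at `l = 60` with 5-nt gaps.
#' @param group_size Consecutive same-dye oligos per group (1, 2 or 4).
#' @param spacing_same_dye Gap (nt) between consecutive same-dye oligo
#'   targets within a group.
#' @param spacing_between_dyes Gap (nt) between the last oligo of one group
#'   and the first oligo of the next (different dye).
#' @param min_gap Minimum gap (nt) between consecutive oligo targets.
#' @param gc_low,gc_high Inclusive GC-fraction bounds for a usable oligo.
#' @param max_run_allowed Longest allowed homopolymer run (nt); runs longer
#'   than this mark the oligo bad.
#' @param window_span Optional cap on the probe span (nt); `NULL` = no cap.
#' @param incomplete_group_tolerance Number of layout slots allowed to stay
#'   unfilled before selection fails.
#' @param homology_max Penalty above which an oligo is flagged bad (in units
#'   of summed hit scores; self-hits excluded by default upstream).
#' @param layout One of `"G1S50"`, `"G1S150"`, `"G2S50"`, `"G2S300"`,
#'   `"G4S50"`, `"G4S300"`, `"custom"`. Presets override `group_size` and
#'   `spacing_between_dyes`.
#' @param lambda_spacing Weight (penalty units per nt) of the L1 spacing
#'   deviation in the window objective.
#'
#' @return A list of class `design_params`.
#' @export
design_params <- function(l = 60L, n_total = 300L, group_size = 1L,
                          spacing_same_dye = 5L, spacing_between_dyes = 5L,
                          min_gap = 5L, gc_low = 0.35, gc_high = 0.80,
                          max_run_allowed = 6L, window_span = NULL,
                          incomplete_group_tolerance = 20L,
                          homology_max = 100, layout = "custom",
                          lambda_spacing = 1) {
  layouts <- list(G1S50 = c(1L, 50L), G1S150 = c(1L, 150L),
                  G2S50 = c(2L, 50L), G2S300 = c(2L, 300L),
                  G4S50 = c(4L, 50L), G4S300 = c(4L, 300L))
  layout <- match.arg(layout, c("custom", names(layouts)))
  if (layout != "custom") {
    group_size <- layouts[[layout]][1]
    spacing_between_dyes <- layouts[[layout]][2]
  }
  assert_that(gc_low < gc_high, "gc_low must be < gc_high")
  assert_that(min_gap >= 0, "min_gap must be >= 0")
  assert_that(group_size %in% c(1L, 2L, 4L), "group_size must be 1, 2 or 4")
  structure(list(
    l = as.integer(l), n_total = as.integer(n_total),
    group_size = as.integer(group_size),
    spacing_same_dye = as.integer(spacing_same_dye),
    spacing_between_dyes = as.integer(spacing_between_dyes),
    min_gap = as.integer(min_gap), gc_low = gc_low, gc_high = gc_high,
    max_run_allowed = as.integer(max_run_allowed),
    window_span = window_span,
    incomplete_group_tolerance = as.integer(incomplete_group_tolerance),
    homology_max = homology_max, layout = layout,
    lambda_spacing = lambda_spacing
  ), class = "design_params")
}

#' Enumerate candidate oligos from a target sequence
#'
#' Slides a window of length `l` in 1-nt steps along the target sequence and
#' records, for every offset, the oligo sequence, its GC fraction and its
#' longest homopolymer run. Candidates containing `N` are marked bad.
#'
#' @param seq Target sequence (character scalar, A/C/G/T/N).
#' @param l Oligo length in nt.
#' @param chrom Chromosome / region name carried into intervals.
#'
#' @return A tibble with one row per candidate: `oligo_id`, `chrom`,
#'   `start`, `end` (0-based half-open), `target_seq`, `gc_fraction`,
#'   `max_run`, `has_n`, `homology_penalty` (0 until aggregated), `quality`
#'   (`"good"`/`"bad"`; only N-containing oligos are bad at this stage).
#' @export
#'
#' @examples
#' enumerate_oligos("ACGTACGTACGT", l = 10)
enumerate_oligos <- function(seq, l = 60L, chrom = "region") {
  assert_that(is.character(seq) && length(seq) == 1, "seq must be a string")
  seq <- toupper(seq)
  assert_that(grepl("^[ACGTN]*$", seq), "seq may contain only A,C,G,T,N")
  l <- as.integer(l)
  assert_that(l >= 1, "l must be >= 1")
  n <- nchar(seq)
  if (n < l) {
    rlang::warn(sprintf("sequence (%d nt) shorter than oligo length (%d nt)",
                        n, l))
    return(empty_candidates(chrom))
  }
  dna <- Biostrings::DNAString(seq)
  nw <- n - l + 1L
  freq <- Biostrings::letterFrequencyInSlidingView(dna, l, c("G", "C", "N"))
  gc <- (freq[, "G"] + freq[, "C"]) / l
  has_n <- unname(freq[, "N"] > 0)
  max_run <- window_max_run(seq, l)
  starts <- 0:(nw - 1L)
  tibble(
    oligo_id = sprintf("oligo_%05d", starts),
    chrom = chrom,
    start = starts,
    end = starts + l,
    target_seq = substring(seq, starts + 1L, starts + l),
    gc_fraction = as.numeric(gc),
    max_run = as.integer(max_run),
    has_n = has_n,
    homology_penalty = 0,
    quality = ifelse(has_n, "bad", "good")
  )
}

empty_candidates <- function(chrom) {
  tibble(oligo_id = character(), chrom = character(), start = integer(),
         end = integer(), target_seq = character(), gc_fraction = numeric(),
         max_run = integer(), has_n = logical(), homology_penalty = numeric(),
         quality = character())
}

# longest homopolymer run fully contained in each length-l window.
# e[i] = length of the run ending at position i; within a window starting at
# w the run ending at i contributes min(e[i], i - w + 1).
window_max_run <- function(seq, l) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(ch)
  e <- integer(n)
  e[1] <- 1L
  for (i in 2:n) e[i] <- if (ch[i] == ch[i - 1L]) e[i - 1L] + 1L else 1L
  nw <- n - l + 1L
  out <- integer(nw)
  for (w in seq_len(nw)) {
    idx <- w:(w + l - 1L)
    out[w] <- max(pmin(e[idx], idx - w + 1L))
  }
  out
}

#' Apply composition filters to candidate oligos
#'
#' Marks candidates bad when the GC fraction falls outside the inclusive
#' `[gc_low, gc_high]` band or the longest homopolymer run exceeds
#' `max_run_allowed` (runs of more than 6 identical nucleotides by default).
#' Pure labelling: idempotent, never drops rows.
#'
#' @param cands Candidate tibble from [enumerate_oligos()].
#' @param params A [design_params()] object.
#' @return `cands` with `quality` updated.
#' @export
composition_filter <- function(cands, params = design_params()) {
  cands |>
    mutate(quality = ifelse(
      .data$has_n |
        .data$max_run > params$max_run_allowed |
        .data$gc_fraction < params$gc_low |
        .data$gc_fraction > params$gc_high |
        .data$homology_penalty > params$homology_max,
      "bad", "good"))
}
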