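#' Read a BLAST tabular (outfmt 6) hit file
#'
#' Only `qseqid` and `bitscore` are consumed downstream; the remaining
#' standard columns are read and kept for inspection.
#'
#' @param path Tab-separated hit file with the 12 standard columns.
#' @return A tibble of hits.
#' @export
read_blast_hits <- function(path) {
  cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  readr::read_tsv(path, col_names = cols, show_col_types = FALSE)
}

#' Sum homology penalties onto candidate oligos
#'
#' Every hit score for an oligo is summed into its `homology_penalty`;
#' oligos with no hits get penalty 0. Self-hits (an oligo matching its own
#' locus) are excluded by default since every oligo trivially matches
#' itself.
#'
#' @param cands Candidate tibble (see [enumerate_oligos()]).
#' @param hits Tibble with columns `query_id` (or `qseqid`), `score` (or
#'   `bitscore`), and optionally `is_self` (logical).
#' @param exclude_self Drop hits flagged `is_self` before summing.
#' @param params Optional [design_params()]; when supplied, candidates whose
#'   penalty exceeds `params$homology_max` are marked bad.
#' @return `cands` with `homology_penalty` (and possibly `quality`) updated.
#' @export
aggregate_homology <- function(cands, hits, exclude_self = TRUE,
                               params = NULL) {
  hits <- as_tibble(hits)
  if (!"query_id" %in% names(hits) && "qseqid" %in% names(hits))
    hits <- rename(hits, query_id = "qseqid")
  if (!"score" %in% names(hits) && "bitscore" %in% names(hits))
    hits <- rename(hits, score = "bitscore")
  assert_that(all(c("query_id", "score") %in% names(hits)),
              "hits must have query_id/qseqid and score/bitscore columns")
  if (!"is_self" %in% names(hits)) hits$is_self <- FALSE
  unknown <- setdiff(unique(hits$query_id), cands$oligo_id)
  if (length(unknown) > 0)
    rlang::abort(paste0("hits reference unknown oligo id(s): ",
                        paste(head(unknown, 5), collapse = ", ")))
  if (exclude_self) hits <- filter(hits, !.data$is_self)
  pen <- hits |>
    group_by(.data$query_id) |>
    summarise(homology_penalty = sum(.data$score), .groups = "drop")
  out <- cands |>
    select(-"homology_penalty") |>
    left_join(pen, by = c(oligo_id = "query_id")) |>
    mutate(homology_penalty = dplyr::coalesce(.data$homology_penalty, 0))
  if (!is.null(params)) out <- composition_filter(out, params)
  out
}

#' Exhaustive ungapped homology search against a genome
#'
#' Deterministic stand-in for an external aligner, used to penalize oligos
#' at design time and as the fixture oracle in tests. Each candidate is
#' scanned over both supplied strands of the genome allowing up to
#' `floor(l * (1 - min_identity))` mismatches over the full oligo length;
#' the hit score is the number of matched bases. The hit overlapping the
#' candidate's own interval is flagged `is_self`.
#'
#' @param cands Candidate tibble.
#' @param genome_seq Genome sequence (character scalar).
#' @param min_identity Minimum identity fraction in `(0, 1]`. Default 0.8.
#' @param both_strands Also scan the reverse complement. Default FALSE
#'   (probes are designed on the provided strand).
#' @return A tibble of hits: `query_id`, `subject_start` (0-based),
#'   `strand`, `score`, `is_self`.
#' @export
homology_oracle <- function(cands, genome_seq, min_identity = 0.8,
                            both_strands = FALSE) {
  assert_that(nchar(genome_seq) > 0, "genome_seq must be non-empty")
  subj <- Biostrings::DNAString(toupper(genome_seq))
  strands <- if (both_strands) c("+", "-") else "+"
  res <- purrr::map(seq_len(nrow(cands)), function(i) {
    oligo <- cands$target_seq[i]
    l <- nchar(oligo)
    max_mm <- floor(l * (1 - min_identity))
    out <- list()
    for (st in strands) {
      pat <- if (st == "+") oligo else revcomp(oligo)
      m <- Biostrings::matchPattern(pat, subj, max.mismatch = max_mm)
      if (length(m) == 0) next
      starts0 <- BiocGenerics::start(m) - 1L
      mm <- Biostrings::neditAt(pat, subj, at = BiocGenerics::start(m),
                                with.indels = FALSE)
      out[[st]] <- tibble(
        query_id = cands$oligo_id[i],
        subject_start = starts0,
        strand = st,
        score = l - mm,
        is_self = st == "+" & starts0 == cands$start[i] & mm == 0
      )
    }
    bind_rows(out)
  })
  bind_rows(res)
}
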