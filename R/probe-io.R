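#' Export an assembled probe set
#'
#' Writes three files: a FASTA of full oligo sequences, a BED (0-based
#' half-open) of the target intervals, and a TSV probe table that
#' round-trips losslessly through [read_probe()].
#'
#' @param probe An assembled `probe_set` (see [assemble_oligos()]).
#' @param prefix Output path prefix; writes `<prefix>.fa`, `<prefix>.bed`,
#'   `<prefix>.tsv`.
#' @return A named character vector of the written paths, invisibly.
#' @export
export_probe <- function(probe, prefix) {
  assert_that(!is.na(probe$design_variant),
              "probe must be assembled before export (see assemble_oligos)")
  dir <- dirname(prefix)
  if (!dir.exists(dir))
    rlang::abort(paste0("output directory does not exist: ", dir))
  ol <- probe$oligos
  # FASTA headers carry 1-based inclusive display coordinates
  nm <- sprintf("%s|%s:%d-%d|%s", ol$oligo_id, ol$chrom, ol$start + 1L,
                ol$end, ol$dye_role)
  assert_that(!anyDuplicated(nm) > 0, "FASTA headers must be unique")
  fa <- Biostrings::DNAStringSet(ol$full_seq)
  names(fa) <- nm
  paths <- c(fasta = paste0(prefix, ".fa"), bed = paste0(prefix, ".bed"),
             tsv = paste0(prefix, ".tsv"))
  Biostrings::writeXStringSet(fa, paths["fasta"])
  bed <- tibble(chrom = ol$chrom, start = ol$start, end = ol$end,
                name = ol$oligo_id, score = round(ol$homology_penalty),
                strand = "+")
  readr::write_tsv(bed, paths["bed"], col_names = FALSE)
  tab <- tibble(name = ol$oligo_id, chrom = ol$chrom, start = ol$start,
                end = ol$end, dye_role = ol$dye_role,
                gc = ol$gc_fraction, max_run = ol$max_run,
                penalty = ol$homology_penalty, target_seq = ol$target_seq,
                full_seq = ol$full_seq, slot = ol$slot,
                ideal_start = ol$ideal_start,
                design_variant = probe$design_variant,
                layout = probe$params$layout)
  readr::write_tsv(tab, paths["tsv"])
  invisible(paths)
}

#' Read a probe table written by [export_probe()]
#'
#' @param tsv_path Path to the `<prefix>.tsv` file.
#' @return A `probe_set` with the fields recoverable from the table.
#' @export
read_probe <- function(tsv_path) {
  tab <- readr::read_tsv(tsv_path, show_col_types = FALSE)
  oligos <- tibble(
    oligo_id = tab$name, chrom = tab$chrom,
    start = as.integer(tab$start), end = as.integer(tab$end),
    target_seq = tab$target_seq, gc_fraction = tab$gc,
    max_run = as.integer(tab$max_run), has_n = grepl("N", tab$target_seq),
    homology_penalty = tab$penalty, quality = "good",
    slot = as.integer(tab$slot), dye_role = tab$dye_role,
    ideal_start = as.integer(tab$ideal_start),
    deviation = as.integer(tab$start) - as.integer(tab$ideal_start),
    lss = NA_character_, rss = NA_character_,
    full_seq = tab$full_seq
  )
  if (tab$design_variant[1] == "design2") {
    oligos$lss <- SS_5P
    oligos$rss <- SS_3P
  }
  structure(list(
    oligos = oligos,
    params = design_params(l = oligos$end[1] - oligos$start[1],
                           n_total = nrow(oligos),
                           layout = tab$layout[1]),
    span = max(oligos$end) - min(oligos$start),
    objective = NA_real_,
    n_missing = NA_integer_,
    anchor = NA_integer_,
    design_variant = tab$design_variant[1],
    detection_oligos = NULL
  ), class = "probe_set")
}
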