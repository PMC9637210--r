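#' Count accessibility reads in probe windows
#'
#' Sums per-base read-start counts of a coverage track over each genomic
#' window (same start/end as the corresponding probe span). A read
#' contributes to the window containing its 5' start, so reads are never
#' double-counted. Bases without coverage count as 0 (with a warning when a
#' window is partly uncovered).
#'
#' @param windows Tibble with `locus`, `chrom`, `start`, `end` (0-based
#'   half-open).
#' @param coverage Tibble (bedGraph-like) with `chrom`, `start`, `end`,
#'   `count`: reads starting per base over `[start, end)`.
#' @return `windows` with an `atac_count` column.
#' @export
atac_window_counts <- function(windows, coverage) {
  assert_that(all(windows$end > windows$start), "malformed interval")
  counts <- numeric(nrow(windows))
  warned <- FALSE
  for (i in seq_len(nrow(windows))) {
    w <- windows[i, ]
    cv <- filter(coverage, .data$chrom == w$chrom,
                 .data$end > w$start, .data$start < w$end)
    if (nrow(cv) == 0) {
      counts[i] <- 0
      warned <- TRUE
      next
    }
    ov <- pmin(cv$end, w$end) - pmax(cv$start, w$start)
    counts[i] <- sum(cv$count * ov)
    covered <- sum(ov)
    if (covered < w$end - w$start) warned <- TRUE
  }
  if (warned)
    rlang::warn("some window bases have no coverage; counted as 0")
  mutate(windows, atac_count = counts)
}

#' Correlate mean compaction score with accessibility counts
#'
#' Spearman (SCC) and Pearson (PCC) correlation between per-locus mean
#' score and window read count. Compaction and accessibility are expected
#' to be inversely related, so the report flags whether the rank
#' correlation is negative.
#'
#' @param comparison Tibble with one row per locus: `mean_score`,
#'   `atac_count` (>= 3 loci).
#' @return Tibble with `scc`, `pcc`, `n_loci`, `inverse` (is SCC < 0).
#' @export
correlate_score_vs_atac <- function(comparison) {
  assert_that(nrow(comparison) >= 3, "need >= 3 loci")
  if (sd(comparison$mean_score) == 0 || sd(comparison$atac_count) == 0) {
    rlang::warn("constant vector: correlations undefined")
    return(tibble(scc = NA_real_, pcc = NA_real_,
                  n_loci = nrow(comparison), inverse = NA))
  }
  scc <- cor(comparison$mean_score, comparison$atac_count,
             method = "spearman")
  pcc <- cor(comparison$mean_score, comparison$atac_count,
             method = "pearson")
  tibble(scc = scc, pcc = pcc, n_loci = nrow(comparison),
         inverse = scc < 0)
}

#' Simulate an accessibility track coupled to compaction
#'
#' Emulates the inverse relation between local chromatin compaction and
#' transposase accessibility: the expected read count of each locus window
#' decays exponentially with its compaction parameter, with multiplicative
#' log-normal noise; read starts are placed uniformly within the window.
#'
#' @param loci Tibble with `locus`, `chrom`, `start`, `end`, `compaction`
#'   (in `[0, 1]`; >= 3 loci).
#' @param base_count Expected count at compaction 0.
#' @param coupling Exponential decay rate per unit compaction.
#' @param noise_cv Coefficient of variation of the multiplicative noise.
#' @param seed RNG seed.
#' @return List with `coverage` (per-base run-length tibble: `chrom`,
#'   `start`, `end`, `count`) and `truth` (`loci` with the realised
#'   `n_reads`).
#' @export
sim_atac <- function(loci, base_count = 2000, coupling = 3, noise_cv = 0.2,
                     seed = 1L) {
  assert_that(nrow(loci) >= 3, "need >= 3 loci")
  with_seed(seed, {
    mu <- base_count * exp(-coupling * loci$compaction)
    noise <- if (noise_cv > 0)
      exp(rnorm(nrow(loci), -0.5 * log(1 + noise_cv^2),
                sqrt(log(1 + noise_cv^2)))) else 1
    n_reads <- round(mu * noise)
    cov_rows <- purrr::map(seq_len(nrow(loci)), function(i) {
      w <- loci[i, ]
      nb <- w$end - w$start
      if (n_reads[i] == 0) return(NULL)
      starts <- sort(sample.int(nb, n_reads[i], replace = TRUE)) - 1L
      r <- rle(starts)
      tibble(chrom = w$chrom, start = w$start + r$values,
             end = w$start + r$values + 1L, count = r$lengths)
    })
    list(coverage = bind_rows(cov_rows),
         truth = mutate(loci, n_reads = n_reads))
  })
}

#' Read / write bedGraph coverage
#'
#' Plain four-column bedGraph (`chrom`, `start`, `end`, `count`),
#' tab-separated, no header.
#'
#' @param path File path.
#' @return A coverage tibble.
#' @export
read_bedgraph <- function(path) {
  readr::read_tsv(path, col_names = c("chrom", "start", "end", "count"),
                  show_col_types = FALSE)
}

#' @rdname read_bedgraph
#' @param coverage Coverage tibble to write.
#' @export
write_bedgraph <- function(coverage, path) {
  readr::write_tsv(coverage[, c("chrom", "start", "end", "count")], path,
                   col_names = FALSE)
  invisible(path)
}
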