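test_that("oligo enumeration yields len - l + 1 candidates in genomic order", {
  s60 <- strrep("ACGT", 15)
  expect_equal(nrow(enumerate_oligos(s60, 60)), 1)
  s62 <- paste0(s60, "AC")
  c62 <- enumerate_oligos(s62, 60)
  expect_equal(nrow(c62), 3)
  expect_equal(c62$start, 0:2)
  expect_warning(c59 <- enumerate_oligos(substr(s60, 1, 59), 60), "shorter")
  expect_equal(nrow(c59), 0)

  # property over random lengths
  for (seed in 1:5) {
    g <- sim_genome(1000 + seed * 37, seed = seed)
    cands <- enumerate_oligos(g$seq, 60)
    expect_equal(nrow(cands), nchar(g$seq) - 60 + 1)
    expect_true(all(diff(cands$start) == 1))
    expect_equal(cands$end - cands$start, rep(60L, nrow(cands)))
    # gc and max_run agree with direct computation on a sample of oligos
    idx <- sample(nrow(cands), 20)
    for (i in idx) {
      chars <- strsplit(cands$target_seq[i], "")[[1]]
      expect_equal(cands$gc_fraction[i], mean(chars %in% c("G", "C")))
      expect_equal(cands$max_run[i], max(rle(chars)$lengths))
    }
  }
})

test_that("N-containing oligos are marked bad at enumeration", {
  s <- paste0(strrep("ACGT", 20), "N", strrep("ACGT", 20))
  cands <- enumerate_oligos(s, 60)
  spans_n <- cands$start <= 80 & cands$end > 80   # N sits at 0-based 80
  expect_true(all(cands$quality[spans_n] == "bad"))
  expect_true(all(cands$quality[!spans_n] == "good"))
})

test_that("composition filter enforces GC band and homopolymer limit, idempotently", {
  mk <- function(s) enumerate_oligos(s, 60) |> composition_filter()
  run7 <- paste0("AAAAAAA", substr(strrep("CGTA", 15), 1, 53))   # run of 7
  expect_equal(mk(run7)$quality, "bad")
  expect_equal(mk(run7)$max_run, 7L)
  run6 <- paste0("AAAAAA", substr(strrep("CGTA", 15), 1, 54))    # run of 6
  expect_equal(mk(run6)$quality, "good")
  interior <- strrep("ACGTG", 12)   # GC 60%, max run 1
  expect_equal(mk(interior)$quality, "good")
  # direct boundary checks via synthetic candidate rows
  cand <- make_cands(0, 60, "good")
  cand$gc_fraction <- 0.35
  expect_equal(composition_filter(cand)$quality, "good")
  cand$gc_fraction <- 0.3499
  expect_equal(composition_filter(cand)$quality, "bad")
  cand$gc_fraction <- 0.80
  expect_equal(composition_filter(cand)$quality, "good")
  cand$gc_fraction <- 0.801
  expect_equal(composition_filter(cand)$quality, "bad")
  cand$gc_fraction <- 0.5
  cand$max_run <- 6L
  expect_equal(composition_filter(cand)$quality, "good")
  cand$max_run <- 7L
  expect_equal(composition_filter(cand)$quality, "bad")
  # idempotence on a random region
  g <- sim_genome(3000, seed = 11)
  c1 <- enumerate_oligos(g$seq, 60) |> composition_filter()
  expect_identical(c1, composition_filter(c1))
  ok <- c1$quality == "good"
  expect_true(all(c1$gc_fraction[ok] >= 0.35 & c1$gc_fraction[ok] <= 0.80))
  expect_true(all(c1$max_run[ok] <= 6))
})

test_that("homology penalties are summed per oligo, self-hits excluded", {
  cands <- make_cands(c(0, 100, 200), 60, "good")
  hits <- tibble::tibble(query_id = c("oligo_00100", "oligo_00100"),
                         score = c(30, 40), is_self = FALSE)
  out <- aggregate_homology(cands, hits)
  expect_equal(out$homology_penalty, c(0, 70, 0))
  # self-only hit with exclusion -> 0
  hits2 <- tibble::tibble(query_id = "oligo_00000", score = 60,
                          is_self = TRUE)
  expect_equal(aggregate_homology(cands, hits2)$homology_penalty[1], 0)
  expect_equal(aggregate_homology(cands, hits2,
                                  exclude_self = FALSE)$homology_penalty[1],
               60)
  bad <- tibble::tibble(query_id = "nonexistent", score = 1, is_self = FALSE)
  expect_error(aggregate_homology(cands, bad), "nonexistent")
})

test_that("homology oracle matches an exhaustive character-level scan", {
  g <- sim_genome(1500, seed = 3)
  # plant the oligo at 100 verbatim again at 900
  g2 <- sim_genome(1500, seed = 3,
                   planted_repeats = tibble::tibble(source_start = 100,
                                                    dest_start = 900,
                                                    width = 60))
  cands <- enumerate_oligos(g2$seq, 60)
  target <- cands[cands$start == 100, ]
  hits <- homology_oracle(target, g2$seq, min_identity = 0.8)
  expect_equal(nrow(hits), 2)
  expect_equal(sum(hits$is_self), 1)
  ref <- oracle_homology_scan(target$target_seq, g2$seq, 0.8)
  expect_equal(sort(hits$subject_start), sort(ref$start))
  expect_equal(hits$score[order(hits$subject_start)],
               ref$score[order(ref$start)])

  # random 60-mer vs unrelated 1 kb: no hits at 0.8
  other <- sim_genome(1000, seed = 77)
  rnd <- cands[cands$start == 300, ]
  expect_equal(nrow(homology_oracle(rnd, other$seq, 0.8)), 0)
  expect_equal(nrow(oracle_homology_scan(rnd$target_seq, other$seq, 0.8)), 0)

  # min_identity 1, oligo == genome: exactly one hit
  solo <- make_cands(0, 60, "good")
  solo$target_seq <- substr(g2$seq, 1, 60)
  expect_equal(nrow(homology_oracle(solo, solo$target_seq, 1.0)), 1)
})

test_that("window selection matches brute-force enumeration and honours constraints", {
  # ~160 candidates with scattered bad oligos and varying penalties
  set.seed(42)
  g <- sim_genome(1200, seed = 21)
  cands <- enumerate_oligos(g$seq, 60) |> composition_filter()
  cands <- cands[seq(1, nrow(cands), by = 7), ]   # thin to ~160
  cands$homology_penalty <- round(rexp(nrow(cands), 1 / 10), 2)
  cands$quality[sample(nrow(cands), 15)] <- "bad"
  params <- design_params(l = 60, n_total = 8, group_size = 2,
                          spacing_same_dye = 10, spacing_between_dyes = 40,
                          incomplete_group_tolerance = 1)
  ps <- select_best_window(cands, params)
  ref <- oracle_best_window(cands, params)
  expect_equal(ps$objective, ref$objective, tolerance = 1e-9)
  expect_equal(ps$anchor, ref$anchor)
  # constraints
  gaps <- ps$oligos$start[-1] - ps$oligos$end[-nrow(ps$oligos)]
  expect_true(all(gaps >= params$min_gap))
  counts <- table(ps$oligos$dye_role)
  expect_lte(abs(counts[["donor"]] - counts[["acceptor"]]),
             params$group_size)
  expect_true(all(ps$oligos$quality == "good"))
  # dye roles alternate in groups of group_size along the slot grid
  expected_role <- ifelse(((ps$oligos$slot - 1) %/% 2) %% 2 == 0,
                          "donor", "acceptor")
  expect_equal(ps$oligos$dye_role, expected_role)
})

test_that("good oligos flanked by bad neighbours are removed", {
  starts <- seq(0, by = 70, length.out = 9)
  qual <- c("good", "good", "bad", "good", "bad", "good", "good", "good",
            "good")
  cands <- make_cands(starts, 60, qual)
  params <- design_params(l = 60, n_total = 5, group_size = 1,
                          spacing_same_dye = 10, spacing_between_dyes = 10,
                          incomplete_group_tolerance = 1)
  ps <- select_best_window(cands, params)
  # candidate at start 210 (index 4) has bad neighbours on both sides
  expect_false(210 %in% ps$oligos$start)
})

test_that("a uniquely feasible window is found; infeasible layouts error", {
  # good oligos only at one window location
  starts <- seq(0, by = 65, length.out = 6)
  cands <- make_cands(c(starts, 1000 + starts * 2), 60,
                      c(rep("good", 6), rep("bad", 6)))
  params <- design_params(l = 60, n_total = 6, group_size = 1,
                          spacing_same_dye = 5, spacing_between_dyes = 5,
                          incomplete_group_tolerance = 0)
  ps <- select_best_window(cands, params)
  expect_equal(sort(ps$oligos$start), starts)
  # too few good oligos
  expect_error(
    select_best_window(make_cands(starts, 60, "bad"), params),
    "usable")
  # region shorter than the layout span
  params_big <- design_params(l = 60, n_total = 50,
                              incomplete_group_tolerance = 0)
  expect_error(select_best_window(cands, params_big), "usable|span")
})

test_that("assembly produces the documented full sequences per design", {
  g <- sim_genome(2000, seed = 9)
  cands <- enumerate_oligos(g$seq, 60) |> composition_filter()
  params <- design_params(n_total = 10, incomplete_group_tolerance = 1)
  ps <- select_best_window(cands, params)
  d1 <- assemble_oligos(ps, variant = "design1")
  expect_true(all(nchar(d1$oligos$full_seq) == 100))
  expect_equal(substr(d1$oligos$full_seq, 21, 80), d1$oligos$target_seq)
  d2 <- assemble_oligos(ps, variant = "design2")
  # 3' terminal 5-mer (AATTA) is the reverse complement of the next
  # oligo's 5' terminal 5-mer (TAATT)
  last5 <- substr(d2$oligos$full_seq, nchar(d2$oligos$full_seq) - 4,
                  nchar(d2$oligos$full_seq))
  first5 <- substr(d2$oligos$full_seq, 1, 5)
  expect_true(all(last5 == "AATTA"))
  expect_true(all(first5 == "TAATT"))
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(last5)))
  expect_equal(unname(rc), unname(first5))
  d3 <- assemble_oligos(ps, variant = "design3")
  expect_identical(d3$oligos$full_seq, d1$oligos$full_seq)
  expect_true(all(d3$detection_oligos$stabilized))
  expect_false(any(d1$detection_oligos$stabilized))
  # detection oligos are reverse complements of the adapters
  ad <- default_adapters()
  lstar <- d1$detection_oligos$sequence[d1$detection_oligos$dye_role ==
                                          "donor" &
                                          d1$detection_oligos$oligo == "L*"]
  expect_equal(lstar, as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(ad$donor[["L"]]))))
  # adapter validation
  bad_ad <- ad
  bad_ad$donor[["L"]] <- "ACGT"
  expect_error(assemble_oligos(ps, adapters = bad_ad), "20 nt")
  dup_ad <- ad
  dup_ad$acceptor[["L"]] <- ad$donor[["L"]]
  expect_warning(assemble_oligos(ps, adapters = dup_ad), "orthogonal")
})

test_that("probe export round-trips and is byte-identical for equal inputs", {
  g <- sim_genome(2000, seed = 5)
  cands <- enumerate_oligos(g$seq, 60) |> composition_filter()
  params <- design_params(n_total = 12, incomplete_group_tolerance = 1)
  probe <- select_best_window(cands, params) |>
    assemble_oligos(variant = "design1")
  td <- withr::local_tempdir()
  paths <- export_probe(probe, file.path(td, "probe"))
  expect_true(all(file.exists(paths)))
  back <- read_probe(paths["tsv"])
  for (col in c("oligo_id", "chrom", "start", "end", "target_seq",
                "gc_fraction", "max_run", "homology_penalty", "dye_role",
                "full_seq")) {
    expect_equal(back$oligos[[col]], probe$oligos[[col]], label = col)
  }
  expect_equal(back$design_variant, probe$design_variant)
  expect_equal(back$span, probe$span)
  # BED rows == oligo count; FASTA headers unique
  bed <- readr::read_tsv(paths["bed"], col_names = FALSE,
                         show_col_types = FALSE)
  expect_equal(nrow(bed), nrow(probe$oligos))
  fa <- Biostrings::readDNAStringSet(paths["fasta"])
  expect_equal(length(unique(names(fa))), length(fa))
  # determinism: regenerate everything and compare bytes
  probe2 <- select_best_window(
    enumerate_oligos(sim_genome(2000, seed = 5)$seq, 60) |>
      composition_filter(), params) |>
    assemble_oligos(variant = "design1")
  paths2 <- export_probe(probe2, file.path(td, "probe2"))
  for (k in names(paths)) {
    expect_identical(readBin(paths[[k]], "raw", file.size(paths[[k]])),
                     readBin(paths2[[k]], "raw", file.size(paths2[[k]])))
  }
})
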