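# Default 20-nt adapters, one L/R pair per dye role. Synthetic orthogonal
# sequences fixed once for reproducible assemblies; users supply their own
# production adapters via the `adapters` argument.
default_adapters <- function() {
  list(
    donor = c(L = "CGCTGTATCGGCTAACGTTC", R = "GTTCAGCATAGGTCACCTAG"),
    acceptor = c(L = "TACCGAGGATCAGTTCGCAC", R = "CAGTTGACGCGTATCCATTG")
  )
}

# 5-nt complementary stabilization strings: TAATT is the reverse
# complement of AATTA, so the 3' AATTA of one oligo anneals to the 5'
# TAATT of the next.
SS_3P <- "AATTA"   # appended 3'
SS_5P <- "TAATT"   # appended 5'

#' Assemble full oligo sequences for a probe design variant
#'
#' Design 1: `full_seq = L + T + R` (20 + l + 20 nt); detection oligos are
#' the reverse complements of the adapters. Design 2: the primary oligos
#' additionally carry stabilization strings (5' `TAATT`, 3' `AATTA`) so the
#' 3' end of each oligo is complementary to the 5' end of the next. Design
#' 3: primaries identical to design 1; the stabilization strings are moved
#' onto the detection oligos instead.
#'
#' @param probe A `probe_set` from [select_best_window()].
#' @param adapters Named list with `donor` and `acceptor` elements, each a
#'   named character vector `c(L = ..., R = ...)` of 20-nt sequences.
#' @param variant `"design1"`, `"design2"` or `"design3"`.
#' @return The `probe_set` with `full_seq`, `lss`, `rss` columns on
#'   `$oligos`, `design_variant` set, and `$detection_oligos` populated.
#' @export
assemble_oligos <- function(probe, adapters = default_adapters(),
                            variant = c("design1", "design2", "design3")) {
  variant <- match.arg(variant)
  for (role in c("donor", "acceptor")) {
    ad <- adapters[[role]]
    assert_that(!is.null(ad) && all(c("L", "R") %in% names(ad)),
                paste0("adapters$", role, " must have L and R entries"))
    if (any(nchar(ad) != 20))
      rlang::abort(paste0("adapter length must be 20 nt (", role, ")"))
  }
  check_adapter_orthogonality(adapters)
  ol <- probe$oligos
  L <- vapply(ol$dye_role, function(r) adapters[[r]][["L"]], character(1))
  R <- vapply(ol$dye_role, function(r) adapters[[r]][["R"]], character(1))
  if (variant == "design2") {
    ol$lss <- SS_5P
    ol$rss <- SS_3P
    ol$full_seq <- paste0(SS_5P, L, ol$target_seq, R, SS_3P)
  } else {
    ol$lss <- NA_character_
    ol$rss <- NA_character_
    ol$full_seq <- paste0(L, ol$target_seq, R)
  }
  det <- purrr::map(c("donor", "acceptor"), function(role) {
    ad <- adapters[[role]]
    lstar <- revcomp(ad[["L"]])
    rstar <- revcomp(ad[["R"]])
    if (variant == "design3") {
      lstar <- paste0(SS_5P, lstar)
      rstar <- paste0(rstar, SS_3P)
    }
    tibble(dye_role = role, oligo = c("L*", "R*"),
           sequence = c(lstar, rstar),
           stabilized = variant == "design3")
  }) |> bind_rows()
  probe$oligos <- ol
  probe$design_variant <- variant
  probe$detection_oligos <- det
  probe
}

# warn when two adapters share a >=15-nt exact substring
check_adapter_orthogonality <- function(adapters) {
  seqs <- unlist(adapters)
  nm <- names(seqs)
  for (i in seq_along(seqs)) {
    for (j in seq_along(seqs)) {
      if (i >= j) next
      for (s in 1:6) {   # all 15-mers of a 20-mer
        kmer <- substr(seqs[i], s, s + 14)
        if (grepl(kmer, seqs[j], fixed = TRUE)) {
          rlang::warn(sprintf(
            "adapters %s and %s share a >=15-nt substring; not orthogonal",
            nm[i], nm[j]))
          return(invisible(FALSE))
        }
      }
    }
  }
  invisible(TRUE)
}
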