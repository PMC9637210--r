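#' Quantify FRET-FISH dot pairs across image fields
#'
#' Runs the full per-field pipeline: nucleus segmentation on the DNA
#' channel, dot detection in the donor and acceptor channels, donor-
#' acceptor pairing at the radial threshold, FRET/donor intensity read-out,
#' and scoring. The convenience wrapper behind the `quantify` workflow.
#'
#' @param fields List of fields (named channel arrays, e.g.
#'   `sim_image_dataset()$fields`) or a single field.
#' @param expected_per_nucleus Dots per nucleus to keep.
#' @param pair_radius_px Pairing radius in px (default 7).
#' @param mode Segmentation mode (`"2d"` or `"3d"`).
#' @param min_area_um2 Minimum nucleus area for segmentation.
#' @param statistic Intensity statistic (see [detect_dots()]).
#' @return List with `pairs` (scored pair tibble with `field` column),
#'   `nuclei` (per-field nucleus tibble), `segs` (list of `nucleus_seg`).
#' @export
quantify_fields <- function(fields, expected_per_nucleus = 2L,
                            pair_radius_px = 7, mode = "2d",
                            min_area_um2 = 50,
                            statistic = "integrated") {
  if (!is.null(names(fields)) && "dna" %in% names(fields))
    fields <- list(fields)
  pairs <- list(); nuclei <- list(); segs <- list()
  for (f in seq_along(fields)) {
    st <- fields[[f]]
    seg <- segment_nuclei(st, mode = mode, min_area_um2 = min_area_um2)
    segs[[f]] <- seg
    if (nrow(seg$nuclei) == 0) next
    nuclei[[f]] <- mutate(seg$nuclei, field = f)
    dd <- detect_dots(st, "donor", seg, expected_per_nucleus,
                      intensity_statistic = statistic)
    aa <- detect_dots(st, "acceptor", seg, expected_per_nucleus,
                      intensity_statistic = statistic)
    if (nrow(dd) == 0 || nrow(aa) == 0) next
    pp <- pair_dots(dd, aa, max_separation_px = pair_radius_px)
    if (nrow(pp) == 0) next
    pp <- measure_fret_intensity(pp, st, statistic = statistic)
    pp <- suppressWarnings(score_pairs(pp))
    pairs[[f]] <- mutate(pp, field = f)
  }
  list(pairs = bind_rows(pairs), nuclei = bind_rows(nuclei), segs = segs)
}
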