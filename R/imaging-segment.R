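#' Segment nuclei from the DNA-stain channel
#'
#' In `"2d"` mode the axial maximum projection is thresholded automatically
#' (inter-class-variance / Otsu), touching nuclei are split by watershed on
#' the distance map, and objects below a minimum area are discarded. In
#' `"3d"` mode the volume is additionally thresholded and voxels are
#' assigned the label of their 2D projection footprint (nuclei may not
#' overlap in projection). Labels are dense from 1.
#'
#' @param stack Named list of channel arrays `[z, y, x]` with a `dna`
#'   element and optionally `voxel_size_um`.
#' @param mode `"2d"` or `"3d"`.
#' @param min_area_um2 Minimum nucleus area (um^2) in the projection.
#' @param voxel_size_um Voxel size `(dz, dy, dx)`; taken from the stack when
#'   present.
#'
#' @return A `nucleus_seg`: list with `nuclei` (tibble: `label`,
#'   `area_2d_px`, `volume_vox`, `hoechst_total`, `centroid_y/x`,
#'   `cycle_class`, `hoechst_subclass`), `label_2d` (matrix), `label_3d`
#'   (array or NULL), `voxel_size_um`.
#' @export
segment_nuclei <- function(stack, mode = c("2d", "3d"),
                           min_area_um2 = 50,
                           voxel_size_um = NULL) {
  mode <- match.arg(mode)
  assert_that("dna" %in% names(stack), "stack must contain a dna channel")
  vox <- voxel_size_um %||% stack$voxel_size_um %||%
    c(dz = 0.3, dy = 1.9 / 7, dx = 1.9 / 7)
  dna <- stack$dna
  mp <- apply(dna, c(2, 3), max)          # axial max projection (y, x)
  rng <- range(mp)
  if (rng[2] <= rng[1]) {
    return(empty_seg(dim(mp), vox))       # blank image: no nuclei
  }
  mpn <- (mp - rng[1]) / (rng[2] - rng[1])
  th <- EBImage::otsu(EBImage::Image(mpn), range = c(0, 1))
  bin <- mpn > th
  if (!any(bin)) return(empty_seg(dim(mp), vox))
  bin <- EBImage::fillHull(EBImage::Image(bin))
  dm <- EBImage::distmap(bin)
  lab <- EBImage::watershed(dm, tolerance = 1, ext = 1)
  lab <- as.matrix(EBImage::imageData(lab))
  # drop small objects, relabel densely
  min_px <- min_area_um2 / (vox[["dy"]] * vox[["dx"]])
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= min_px)
  if (length(keep) == 0) return(empty_seg(dim(mp), vox))
  relab <- integer(max(lab))
  relab[keep] <- seq_along(keep)
  lab2 <- matrix(0L, nrow(lab), ncol(lab))
  nz <- lab > 0
  lab2[nz] <- relab[lab[nz]]
  lab3 <- NULL
  if (mode == "3d") {
    nrm <- (dna - min(dna)) / (max(dna) - min(dna))
    # pooled histogram: otsu is per-frame on 3D images, so reshape to 2D
    thv <- EBImage::otsu(EBImage::Image(matrix(nrm, ncol = 1L)),
                         range = c(0, 1))
    binv <- nrm > thv
    lab3 <- array(0L, dim(dna))
    lab_rep <- aperm(array(lab2, c(dim(lab2), dim(dna)[1])), c(3, 1, 2))
    lab3[binv] <- lab_rep[binv]
  }
  nlab <- max(lab2)
  rows <- purrr::map(seq_len(nlab), function(l) {
    sel2 <- lab2 == l
    idx <- which(sel2, arr.ind = TRUE)
    # hoechst integrated over the 3D extrusion of the 2D mask
    sel_cols <- sel2
    hoechst <- sum(vapply(seq_len(dim(dna)[1]),
                          function(z) sum(dna[z, , ][sel_cols]), numeric(1)))
    tibble(label = l,
           area_2d_px = sum(sel2),
           volume_vox = if (is.null(lab3)) NA_integer_ else sum(lab3 == l),
           hoechst_total = hoechst,
           centroid_y = mean(idx[, 1]), centroid_x = mean(idx[, 2]),
           cycle_class = "unknown", hoechst_subclass = NA_character_)
  })
  structure(list(nuclei = bind_rows(rows), label_2d = lab2, label_3d = lab3,
                 voxel_size_um = vox),
            class = "nucleus_seg")
}

empty_seg <- function(dim2, vox) {
  structure(list(
    nuclei = tibble(label = integer(), area_2d_px = numeric(),
                    volume_vox = integer(), hoechst_total = numeric(),
                    centroid_y = numeric(), centroid_x = numeric(),
                    cycle_class = character(), hoechst_subclass = character()),
    label_2d = matrix(0L, dim2[1], dim2[2]), label_3d = NULL,
    voxel_size_um = vox), class = "nucleus_seg")
}

#' @export
print.nucleus_seg <- function(x, ...) {
  cat("<nucleus_seg> ", nrow(x$nuclei), " nuclei",
      if (!is.null(x$label_3d)) " (3d)" else " (2d)", "\n", sep = "")
  invisible(x)
}
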