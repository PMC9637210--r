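#' Anisotropic 3D Euclidean distance transform of a mask
#'
#' Distance (in um) from every in-mask voxel to the nearest out-of-mask
#' voxel, honouring anisotropic voxel size, via the separable
#' lower-envelope algorithm on squared distances.
#'
#' @param mask Logical 3D array `[z, y, x]`.
#' @param voxel_size_um Named `(dz, dy, dx)` spacing in um.
#' @return Numeric array of distances (um); 0 outside the mask.
#' @export
edt3d <- function(mask, voxel_size_um = c(dz = 0.3, dy = 1.9 / 7,
                                          dx = 1.9 / 7)) {
  f <- array(ifelse(mask, 1e18, 0), dim(mask))
  f <- dt_axis(f, 1, voxel_size_um[["dz"]])
  f <- dt_axis(f, 2, voxel_size_um[["dy"]])
  f <- dt_axis(f, 3, voxel_size_um[["dx"]])
  sqrt(f)
}

# squared-distance transform along one axis with sample spacing w
dt_axis <- function(f, axis, w) {
  perm <- c(axis, setdiff(1:3, axis))
  a <- aperm(f, perm)
  da <- dim(a)
  m <- matrix(a, nrow = da[1])
  for (j in seq_len(ncol(m))) m[, j] <- dt1d(m[, j], w)
  dim(m) <- da
  aperm(array(m, da), order(perm))
}

# 1D squared-distance lower envelope (parabolas)
dt1d <- function(f, w) {
  n <- length(f)
  if (all(f == 0) || all(!is.finite(f))) return(f)
  v <- integer(n); zl <- numeric(n + 1)
  d <- numeric(n)
  k <- 1L
  v[1] <- 1L
  zl[1] <- -Inf; zl[2] <- Inf
  w2 <- w * w
  for (q in 2:n) {
    repeat {
      p <- v[k]
      s <- ((f[q] + w2 * q * q) - (f[p] + w2 * p * p)) / (2 * w2 * (q - p))
      if (s <= zl[k]) {
        k <- k - 1L
        if (k == 0L) { k <- 1L; v[1] <- q; zl[1] <- -Inf; zl[2] <- Inf
          break }
      } else {
        k <- k + 1L
        v[k] <- q
        zl[k] <- s
        zl[k + 1] <- Inf
        break
      }
    }
  }
  k <- 1L
  for (q in seq_len(n)) {
    while (zl[k + 1] < q) k <- k + 1L
    p <- v[k]
    d[q] <- w2 * (q - p)^2 + f[p]
  }
  d
}

#' Normalised 3D distance to the nuclear edge
#'
#' For each dot, the Euclidean distance (um, anisotropy honoured) to the
#' boundary of its nucleus mask divided by the maximum interior distance of
#' that nucleus: 0 on the boundary, 1 at the deepest interior point.
#'
#' @param dots Tibble with `nucleus_label`, `z`, `y`, `x` (1-based voxel
#'   coordinates).
#' @param label_3d Integer 3D label array (e.g. `seg$label_3d` or a truth
#'   mask).
#' @param voxel_size_um Voxel spacing `(dz, dy, dx)` in um.
#' @return `dots` with a `lamina_dist_norm` column in `[0, 1]`.
#' @export
normalized_lamina_distance <- function(dots, label_3d,
                                       voxel_size_um = c(dz = 0.3,
                                                         dy = 1.9 / 7,
                                                         dx = 1.9 / 7)) {
  out <- numeric(nrow(dots))
  for (l in unique(dots$nucleus_label)) {
    sel <- dots$nucleus_label == l
    mask <- label_3d == l
    if (!any(mask)) rlang::abort(paste0("no mask voxels for nucleus ", l))
    # crop to bounding box for speed
    w <- which(mask, arr.ind = TRUE)
    rz <- range(w[, 1]); ry <- range(w[, 2]); rx <- range(w[, 3])
    pad <- 1L
    z1 <- max(1, rz[1] - pad); z2 <- min(dim(mask)[1], rz[2] + pad)
    y1 <- max(1, ry[1] - pad); y2 <- min(dim(mask)[2], ry[2] + pad)
    x1 <- max(1, rx[1] - pad); x2 <- min(dim(mask)[3], rx[2] + pad)
    sub <- mask[z1:z2, y1:y2, x1:x2]
    ed <- edt3d(sub, voxel_size_um)
    dmax <- max(ed)
    zi <- round(dots$z[sel]) - z1 + 1L
    yi <- round(dots$y[sel]) - y1 + 1L
    xi <- round(dots$x[sel]) - x1 + 1L
    inb <- zi >= 1 & zi <= dim(sub)[1] & yi >= 1 & yi <= dim(sub)[2] &
      xi >= 1 & xi <= dim(sub)[3]
    if (!all(inb)) rlang::abort("dot outside nucleus mask")
    dd <- ed[cbind(zi, yi, xi)]
    if (any(sub[cbind(zi, yi, xi)] == FALSE))
      rlang::abort("dot outside nucleus mask")
    # boundary voxels have EDT ~ one voxel; rescale so the boundary maps
    # to 0 and the deepest point to 1
    vmin <- min(ed[sub])
    out[sel] <- pmin(1, pmax(0, (dd - vmin) / (dmax - vmin)))
  }
  mutate(dots, lamina_dist_norm = out)
}

#' Assign dots to four radial nuclear layers
#'
#' Splits normalised lamina distances at their empirical quartiles
#' (0-25%, 26-50%, 51-75%, 76-100%). Layer 1 is the outermost shell
#' (smallest distances), layer 4 the innermost. With `n` divisible by 4 and
#' distinct values each layer holds exactly `n / 4` dots; boundary ties are
#' resolved by stable input order.
#'
#' @param distances Numeric vector of normalised lamina distances (>= 4
#'   finite values).
#' @return A list with `layer` (integer labels 1-4), `fractions` (per-layer
#'   proportions), `cutpoints` (the three interior quartiles).
#' @export
assign_layers <- function(distances) {
  ok <- is.finite(distances)
  if (sum(ok) < 4) rlang::abort("need >= 4 finite distances")
  d <- distances[ok]
  n <- length(d)
  if (max(d) == min(d)) {
    rlang::warn("all distances identical: every dot assigned to layer 1")
    layer <- rep(NA_integer_, length(distances))
    layer[ok] <- 1L
    return(list(layer = layer,
                fractions = c(`1` = 1, `2` = 0, `3` = 0, `4` = 0),
                cutpoints = rep(d[1], 3)))
  }
  r <- rank(d, ties.method = "first")
  lay <- as.integer(ceiling(4 * r / n))
  layer <- rep(NA_integer_, length(distances))
  layer[ok] <- lay
  fr <- tabulate(lay, 4) / n
  names(fr) <- as.character(1:4)
  list(layer = layer, fractions = fr,
       cutpoints = unname(quantile(d, c(0.25, 0.5, 0.75))))
}

#' 3D Euclidean distance between points
#'
#' @param p1,p2 Numeric length-3 vectors or 3-column matrices (same
#'   physical frame, e.g. um).
#' @return Distance(s).
#' @export
distance_3d <- function(p1, p2) {
  if (is.null(dim(p1))) p1 <- matrix(p1, ncol = 3)
  if (is.null(dim(p2))) p2 <- matrix(p2, ncol = 3)
  drop(sqrt(rowSums((p1 - p2)^2)))
}

#' Per-nucleus intensity statistics in a channel
#'
#' Sums or averages voxel intensities over each nucleus mask (2D masks are
#' extruded along z), with optional constant background subtraction.
#'
#' @param stack Named list of channel arrays.
#' @param channel Channel name.
#' @param seg A `nucleus_seg`.
#' @param statistic `"total"` or `"mean"`.
#' @param background Constant background per voxel subtracted before
#'   aggregation.
#' @return Tibble with `label` and `value`.
#' @export
nuclear_intensity <- function(stack, channel, seg,
                              statistic = c("total", "mean"),
                              background = 0) {
  statistic <- match.arg(statistic)
  if (!channel %in% names(stack))
    rlang::abort(paste0("channel not in stack: ", channel))
  img <- stack[[channel]]
  nz <- dim(img)[1]
  rows <- purrr::map(seg$nuclei$label, function(l) {
    if (!is.null(seg$label_3d)) {
      sel <- seg$label_3d == l
      if (!any(sel)) rlang::abort(paste0("empty mask for nucleus ", l))
      vals <- img[sel] - background
    } else {
      m2 <- seg$label_2d == l
      if (!any(m2)) rlang::abort(paste0("empty mask for nucleus ", l))
      vals <- unlist(lapply(seq_len(nz), function(z) img[z, , ][m2])) -
        background
    }
    tibble(label = l,
           value = if (statistic == "total") sum(vals) else mean(vals))
  })
  bind_rows(rows)
}
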