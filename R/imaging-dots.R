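# separable 3D Gaussian smoothing by banded matrix products along each axis
gauss3d <- function(img, sigma) {
  d <- dim(img)
  smooth_axis <- function(arr, axis, s) {
    if (s <= 0) return(arr)
    n <- dim(arr)[axis]
    r <- max(1L, ceiling(3 * s))
    K <- matrix(0, n, n)
    for (i in seq_len(n)) {
      j <- max(1, i - r):min(n, i + r)
      w <- stats::dnorm(j, i, s)
      K[i, j] <- w / sum(w)
    }
    perm <- c(axis, setdiff(1:3, axis))
    a <- aperm(arr, perm)
    da <- dim(a)
    m <- K %*% matrix(a, nrow = da[1])
    dim(m) <- da
    aperm(m, order(perm))
  }
  img <- smooth_axis(img, 1, sigma[["z"]])
  img <- smooth_axis(img, 2, sigma[["y"]])
  smooth_axis(img, 3, sigma[["x"]])
}

# 3x3x3 running maximum (separable box max)
maxfilt3 <- function(img) {
  d <- dim(img)
  shift_max <- function(arr, axis) {
    n <- dim(arr)[axis]
    idx_m <- c(1, seq_len(n - 1)); idx_p <- c(seq_len(n - 1) + 1, n)
    slice <- function(i) {
      switch(axis, arr[i, , , drop = FALSE], arr[, i, , drop = FALSE],
             arr[, , i, drop = FALSE])
    }
    pmax(arr,
         switch(axis, arr[idx_m, , , drop = FALSE],
                arr[, idx_m, , drop = FALSE], arr[, , idx_m, drop = FALSE]),
         switch(axis, arr[idx_p, , , drop = FALSE],
                arr[, idx_p, , drop = FALSE], arr[, , idx_p, drop = FALSE]))
  }
  img <- shift_max(img, 1); img <- shift_max(img, 2); shift_max(img, 3)
}

#' Detect FISH dots within segmented nuclei
#'
#' Band-pass filters the channel (difference of Gaussians), finds 3D local
#' maxima above a robust quality threshold inside each nucleus, keeps the
#' `expected_per_nucleus` most intense, and refines each position to
#' sub-voxel precision by three-point parabolic interpolation per axis.
#'
#' @param stack Named list of channel arrays.
#' @param channel Channel name to detect in.
#' @param seg A `nucleus_seg` from [segment_nuclei()].
#' @param expected_per_nucleus Dots to keep per nucleus (2 for a diploid
#'   locus).
#' @param sigma_small,sigma_large DoG sigmas (px), `(z, y, x)`.
#' @param quality_k Quality threshold in robust noise units (median absolute
#'   deviation of the filtered image).
#' @param intensity_statistic `"integrated"` (background-subtracted sum over
#'   a PSF-sized box; default) or `"peak"` (background-subtracted peak
#'   voxel). Background is the median of a surrounding shell.
#'
#' @return Tibble of dots: `nucleus_label`, `channel`, `z`, `y`, `x`
#'   (1-based voxel-center, sub-voxel), `intensity`, `quality`.
#' @export
detect_dots <- function(stack, channel, seg, expected_per_nucleus = 2L,
                        sigma_small = c(z = 0.8, y = 1.0, x = 1.0),
                        sigma_large = c(z = 1.6, y = 2.0, x = 2.0),
                        quality_k = 5,
                        intensity_statistic = c("integrated", "peak")) {
  intensity_statistic <- match.arg(intensity_statistic)
  if (!channel %in% names(stack))
    rlang::abort(paste0("channel not in stack: ", channel))
  img <- stack[[channel]]
  dog <- gauss3d(img, sigma_small) - gauss3d(img, sigma_large)
  noise <- stats::mad(dog, center = 0)
  thr <- quality_k * noise
  is_max <- dog == maxfilt3(dog) & dog > thr
  idx <- which(is_max, arr.ind = TRUE)
  if (nrow(idx) == 0) return(empty_dots(channel))
  lab <- seg$label_2d[cbind(idx[, 2], idx[, 3])]
  keep <- lab > 0
  idx <- idx[keep, , drop = FALSE]
  lab <- lab[keep]
  if (nrow(idx) == 0) return(empty_dots(channel))
  dots <- tibble(nucleus_label = as.integer(lab),
                 channel = channel,
                 zi = idx[, 1], yi = idx[, 2], xi = idx[, 3],
                 quality = dog[idx] / noise) |>
    group_by(.data$nucleus_label) |>
    arrange(dplyr::desc(.data$quality), .by_group = TRUE) |>
    slice(seq_len(expected_per_nucleus)) |>
    ungroup()
  refine <- purrr::pmap(list(dots$zi, dots$yi, dots$xi), function(z, y, x) {
    p <- c(z, y, x)
    for (ax in 1:3) {
      if (p[ax] > 1 && p[ax] < dim(dog)[ax]) {
        at <- function(off) {
          q <- c(z, y, x); q[ax] <- q[ax] + off
          dog[q[1], q[2], q[3]]
        }
        denom <- at(-1) - 2 * at(0) + at(1)
        if (denom < 0) p[ax] <- p[ax] + 0.5 * (at(-1) - at(1)) / denom
      }
    }
    p
  })
  dots |>
    mutate(z = map_dbl(refine, 1), y = map_dbl(refine, 2),
           x = map_dbl(refine, 3),
           intensity = purrr::pmap_dbl(
             list(.data$zi, .data$yi, .data$xi),
             function(zz, yy, xx) dot_intensity(img, c(zz, yy, xx),
                                                intensity_statistic))) |>
    select("nucleus_label", "channel", "z", "y", "x", "intensity", "quality")
}

empty_dots <- function(channel) {
  tibble(nucleus_label = integer(), channel = character(), z = numeric(),
         y = numeric(), x = numeric(), intensity = numeric(),
         quality = numeric())
}

# background-subtracted intensity statistic at an integer voxel position:
# local background = median of a 2-voxel-thick shell around the core box
dot_intensity <- function(img, p, statistic = "integrated",
                          core = c(2L, 3L, 3L), shell = 2L) {
  d <- dim(img)
  if (any(p < 1) || any(p > d)) rlang::abort("dot outside stack bounds")
  p <- round(p)
  box <- function(r) {
    z <- max(1, p[1] - r[1]):min(d[1], p[1] + r[1])
    y <- max(1, p[2] - r[2]):min(d[2], p[2] + r[2])
    x <- max(1, p[3] - r[3]):min(d[3], p[3] + r[3])
    list(z = z, y = y, x = x)
  }
  b1 <- box(core)
  b2 <- box(core + shell)
  outer_vals <- img[b2$z, b2$y, b2$x]
  inner_mask <- array(FALSE, dim(outer_vals))
  inner_mask[match(b1$z, b2$z), match(b1$y, b2$y), match(b1$x, b2$x)] <- TRUE
  bg <- stats::median(outer_vals[!inner_mask])
  core_vals <- img[b1$z, b1$y, b1$x]
  if (statistic == "peak") {
    max(0, img[p[1], p[2], p[3]] - bg)
  } else {
    max(0, sum(core_vals) - bg * length(core_vals))
  }
}

#' Pair donor and acceptor dots within nuclei
#'
#' Within each nucleus, donor and acceptor dots are matched by 3D distance:
#' the retained matching maximises the number of pairs within
#' `max_separation_px` and, among those, minimises total distance (exact
#' enumeration for up to 7 dots per channel, distance-ascending greedy
#' above). Dots more than `max_separation_px` apart are never paired; each
#' dot appears in at most one pair.
#'
#' @param donor_dots,acceptor_dots Dot tibbles from [detect_dots()].
#' @param max_separation_px Pairing radius (7 px, i.e. 1.9 um laterally).
#' @param voxel_size_um Optional; when supplied the threshold is applied in
#'   um (interpreted as `max_separation_um = max_separation_px *` lateral
#'   pixel pitch) with anisotropic distances.
#' @return Tibble of pairs: nucleus_label, donor and acceptor coordinates,
#'   `separation_px`, plus unmatched dots in `attr(, "unmatched")`.
#' @export
pair_dots <- function(donor_dots, acceptor_dots, max_separation_px = 7,
                      voxel_size_um = NULL) {
  labs <- union(donor_dots$nucleus_label, acceptor_dots$nucleus_label)
  pairs <- list()
  unmatched <- list()
  for (l in sort(labs)) {
    dd <- filter(donor_dots, .data$nucleus_label == l)
    aa <- filter(acceptor_dots, .data$nucleus_label == l)
    if (nrow(dd) == 0 || nrow(aa) == 0) {
      unmatched[[length(unmatched) + 1L]] <- bind_rows(dd, aa)
      next
    }
    if (is.null(voxel_size_um)) {
      D <- sqrt(outer(dd$z, aa$z, `-`)^2 + outer(dd$y, aa$y, `-`)^2 +
                  outer(dd$x, aa$x, `-`)^2)
      thr <- max_separation_px
    } else {
      vz <- voxel_size_um[["dz"]]; vy <- voxel_size_um[["dy"]]
      vx <- voxel_size_um[["dx"]]
      D <- sqrt((outer(dd$z, aa$z, `-`) * vz)^2 +
                  (outer(dd$y, aa$y, `-`) * vy)^2 +
                  (outer(dd$x, aa$x, `-`) * vx)^2)
      thr <- max_separation_px * vx
    }
    m <- match_dots(D, thr)
    if (nrow(m) > 0) {
      pairs[[length(pairs) + 1L]] <- tibble(
        nucleus_label = l,
        donor_idx = m[, 1], acceptor_idx = m[, 2],
        z_donor = dd$z[m[, 1]], y_donor = dd$y[m[, 1]],
        x_donor = dd$x[m[, 1]],
        z_acceptor = aa$z[m[, 2]], y_acceptor = aa$y[m[, 2]],
        x_acceptor = aa$x[m[, 2]],
        i_donor_raw = dd$intensity[m[, 1]],
        i_acceptor_raw = aa$intensity[m[, 2]],
        separation_px = D[cbind(m[, 1], m[, 2])])
    }
    un_d <- setdiff(seq_len(nrow(dd)), m[, 1])
    un_a <- setdiff(seq_len(nrow(aa)), m[, 2])
    if (length(un_d) + length(un_a) > 0)
      unmatched[[length(unmatched) + 1L]] <- bind_rows(dd[un_d, ], aa[un_a, ])
  }
  out <- bind_rows(pairs)
  attr(out, "unmatched") <- bind_rows(unmatched)
  out
}

# exact max-cardinality min-total-distance matching for small instances,
# greedy by ascending distance otherwise; returns matrix [donor, acceptor]
match_dots <- function(D, thr) {
  nd <- nrow(D); na <- ncol(D)
  if (max(nd, na) <= 7) {
    m <- max(nd, na)
    PEN <- 1e6
    C <- matrix(PEN, m, m)
    C[seq_len(nd), seq_len(na)] <- pmin(D, PEN)
    C[C > thr & C < PEN] <- PEN
    best <- NULL; best_cost <- Inf
    for (p in all_perms(m)) {
      cost <- sum(C[cbind(seq_len(m), p)])
      if (cost < best_cost - 1e-12) {
        best_cost <- cost
        best <- p
      }
    }
    keep <- which(seq_len(m) <= nd & best <= na &
                    C[cbind(seq_len(m), best)] < PEN)
    cbind(keep, best[keep])
  } else {
    ord <- order(D)
    used_d <- logical(nd); used_a <- logical(na)
    res <- NULL
    for (o in ord) {
      if (D[o] > thr) break
      i <- (o - 1) %% nd + 1; j <- (o - 1) %/% nd + 1
      if (!used_d[i] && !used_a[j]) {
        used_d[i] <- TRUE; used_a[j] <- TRUE
        res <- rbind(res, c(i, j))
      }
    }
    if (is.null(res)) matrix(integer(), 0, 2) else res[order(res[, 1]), ,
                                                       drop = FALSE]
  }
}

all_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in all_perms(n - 1L)) {
    for (k in 0:(n - 1L)) {
      out[[length(out) + 1L]] <- append(p, n, after = k)
    }
  }
  out
}

#' Measure FRET and donor intensities for dot pairs
#'
#' Reads the FRET read-out at the acceptor dot position in the FRET channel
#' (donor excitation, acceptor emission) and the donor intensity at the
#' donor dot position in the donor channel, both as local-background-
#' subtracted statistics clipped at zero.
#'
#' @param pairs Pair tibble from [pair_dots()].
#' @param stack Named list with `fret` and `donor` channel arrays.
#' @param statistic `"integrated"` or `"peak"` (see [detect_dots()]).
#' @return `pairs` with `i_fret` and `i_donor` columns.
#' @export
measure_fret_intensity <- function(pairs, stack,
                                   statistic = c("integrated", "peak")) {
  statistic <- match.arg(statistic)
  assert_that(all(c("fret", "donor") %in% names(stack)),
              "stack must contain fret and donor channels")
  pairs |>
    mutate(
      i_fret = purrr::pmap_dbl(
        list(.data$z_acceptor, .data$y_acceptor, .data$x_acceptor),
        function(z, y, x) dot_intensity(stack$fret, c(z, y, x), statistic)),
      i_donor = purrr::pmap_dbl(
        list(.data$z_donor, .data$y_donor, .data$x_donor),
        function(z, y, x) dot_intensity(stack$donor, c(z, y, x), statistic)))
}

#' Estimate the chromatic shift between two bead stacks
#'
#' Detects beads in both channels, matches them by mutual nearest
#' neighbour, and returns the rigid translation minimising the mean squared
#' bead displacement (the mean displacement), iterated once after outlier
#' rejection.
#'
#' @param stack_a,stack_b 3D arrays of the same bead field in two channels.
#' @param quality_k Detection threshold in robust noise units.
#' @return A `channel_shift`: list with `translation` (z, y, x in px),
#'   `residual` (RMS px), `n_beads`.
#' @export
estimate_channel_shift <- function(stack_a, stack_b, quality_k = 10) {
  pa <- find_beads(stack_a, quality_k)
  pb <- find_beads(stack_b, quality_k)
  if (nrow(pa) < 3 || nrow(pb) < 3)
    rlang::abort("need at least 3 detectable beads in both channels")
  D <- sqrt(outer(pa$z, pb$z, `-`)^2 + outer(pa$y, pb$y, `-`)^2 +
              outer(pa$x, pb$x, `-`)^2)
  m <- match_dots(D, thr = 10)
  if (nrow(m) < 3) rlang::abort("fewer than 3 matched beads")
  dz <- pb$z[m[, 2]] - pa$z[m[, 1]]
  dy <- pb$y[m[, 2]] - pa$y[m[, 1]]
  dx <- pb$x[m[, 2]] - pa$x[m[, 1]]
  tr <- c(z = mean(dz), y = mean(dy), x = mean(dx))
  res <- sqrt(mean((dz - tr[1])^2 + (dy - tr[2])^2 + (dx - tr[3])^2))
  structure(list(translation = tr, residual = res, n_beads = nrow(m)),
            class = "channel_shift")
}

# bead detection: local maxima + centre-of-mass refinement in a +/-3 box
find_beads <- function(img, quality_k) {
  bg <- stats::median(img)
  noise <- stats::mad(img)
  thr <- bg + quality_k * max(noise, 1e-9)
  is_max <- img == maxfilt3(img) & img > thr
  idx <- which(is_max, arr.ind = TRUE)
  if (nrow(idx) == 0) return(tibble(z = numeric(), y = numeric(),
                                    x = numeric()))
  d <- dim(img)
  refined <- purrr::map(seq_len(nrow(idx)), function(i) {
    p <- idx[i, ]
    z <- max(1, p[1] - 3):min(d[1], p[1] + 3)
    y <- max(1, p[2] - 3):min(d[2], p[2] + 3)
    x <- max(1, p[3] - 3):min(d[3], p[3] + 3)
    w <- pmax(img[z, y, x] - bg, 0)
    sw <- sum(w)
    gz <- array(rep(z, length(y) * length(x)), dim(w))
    gy <- aperm(array(rep(y, length(z) * length(x)),
                      c(length(y), length(z), length(x))), c(2, 1, 3))
    gx <- aperm(array(rep(x, length(z) * length(y)),
                      c(length(x), length(z), length(y))), c(2, 3, 1))
    c(sum(gz * w), sum(gy * w), sum(gx * w)) / sw
  })
  tibble(z = map_dbl(refined, 1), y = map_dbl(refined, 2),
         x = map_dbl(refined, 3))
}

#' Apply a channel shift to dot coordinates
#'
#' Subtracts the estimated translation so that shifted-channel coordinates
#' land in the reference frame; applying then inverting is the identity.
#'
#' @param dots Dot tibble with `z`, `y`, `x`.
#' @param shift A `channel_shift` (or numeric `(z, y, x)`).
#' @param invert Add the shift back instead.
#' @return The dot tibble with corrected coordinates.
#' @export
correct_dots <- function(dots, shift, invert = FALSE) {
  tr <- if (inherits(shift, "channel_shift")) shift$translation else shift
  s <- if (invert) -1 else 1
  mutate(dots, z = .data$z - s * tr[[1]], y = .data$y - s * tr[[2]],
         x = .data$x - s * tr[[3]])
}

#' @export
print.channel_shift <- function(x, ...) {
  cat("<channel_shift> (z, y, x) = (",
      paste(signif(x$translation, 4), collapse = ", "),
      ") px, residual ", signif(x$residual, 3), " px over ", x$n_beads,
      " beads\n", sep = "")
  invisible(x)
}
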