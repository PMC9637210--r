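#' Förster transfer efficiency
#'
#' `E = 1 / (1 + (r / R0)^6)`: the standard distance law for resonance
#' energy transfer, with `R0` the dye-pair Förster radius (52 Angstrom for
#' Cy3/Cy5, 60 Angstrom for AF488/AF594).
#'
#' @param r Donor-acceptor separation (Angstrom).
#' @param r0 Förster radius (Angstrom).
#' @return Efficiency in `(0, 1]`.
#' @export
forster_efficiency <- function(r, r0 = 60) {
  1 / (1 + (r / r0)^6)
}

#' Configuration for the imaging simulator
#'
#' Defaults emulate a diploid-locus FRET-FISH experiment with the AF488 /
#' AF594 dye pair: two dots per nucleus whose donor-acceptor separation is
#' drawn from a two-state mixture (compact state near 56 Angstrom giving
#' E ~ 0.6, open state near 87 Angstrom giving E ~ 0.1 at R0 = 60), 5%
#' acceptor crosstalk and 5% donor bleed-through into the FRET channel,
#' a 2N/4N DNA-content mixture for cell-cycle gating, and 0.3 um focal
#' spacing with the 1.9 um / 7 px lateral pixel pitch.
#'
#' @param n_nuclei Number of nuclei to render.
#' @param nuclei_per_field Nuclei per image field (laid out on a grid).
#' @param nucleus_radii_um Ellipsoid semi-axes (z, y, x) in um.
#' @param radius_jitter Fractional s.d. of per-nucleus radius jitter.
#' @param voxel_size_um Voxel size (dz, dy, dx) in um.
#' @param dots_per_nucleus Loci per nucleus (2 for a diploid autosomal locus).
#' @param r_compact,r_open Mean separations (Angstrom) of the compact and
#'   open chromatin states.
#' @param w_compact Mixture weight of the compact state.
#' @param r_cv Fractional s.d. of per-dot separation around its state mean.
#' @param r0 Förster radius (Angstrom).
#' @param crosstalk_alpha Fraction of acceptor photons excited directly at
#'   the donor wavelength (leaks into the FRET channel).
#' @param bleed_beta Fraction of donor emission leaking into the FRET
#'   channel.
#' @param n_donor,n_acceptor Photon budget per dot and channel.
#' @param background Mean background counts per voxel.
#' @param read_noise_sd Gaussian read noise s.d. (counts).
#' @param psf_sigma_px PSF sigma (z, y, x) in px.
#' @param channel_jitter_px Isotropic s.d. of residual donor/acceptor
#'   localization offset (px).
#' @param channel_shift_px Deterministic (z, y, x) shift applied to the
#'   acceptor and FRET channels (chromatic shift; 0 by default).
#' @param w_4n Fraction of nuclei with 4N DNA content.
#' @param hoechst_cv Fractional s.d. of per-nucleus DNA-stain density.
#' @param condensation_factor Multiplier on DNA-stain density with matching
#'   shrinkage of the nuclear radii (ATP-depletion emulation at > 1).
#' @param separation_scale Multiplier on all separations (< 1 emulates
#'   global compaction).
#' @param seed Integer RNG seed.
#'
#' @return A list of class `sim_imaging_config`.
#' @export
sim_imaging_config <- function(
    n_nuclei = 40L, nuclei_per_field = 4L,
    nucleus_radii_um = c(z = 2.2, y = 5, x = 5), radius_jitter = 0.08,
    voxel_size_um = c(dz = 0.3, dy = 1.9 / 7, dx = 1.9 / 7),
    dots_per_nucleus = 2L,
    r_compact = 56, r_open = 87, w_compact = 0.5, r_cv = 0.08, r0 = 60,
    crosstalk_alpha = 0.05, bleed_beta = 0.05,
    n_donor = 4000, n_acceptor = 4000,
    background = 10, read_noise_sd = 2,
    psf_sigma_px = c(z = 1.0, y = 1.3, x = 1.3),
    channel_jitter_px = 0.3, channel_shift_px = c(z = 0, y = 0, x = 0),
    w_4n = 0.3, hoechst_cv = 0.08,
    condensation_factor = 1, separation_scale = 1,
    seed = 1L) {
  cfg <- as.list(environment())
  assert_that(w_compact >= 0 && w_compact <= 1, "w_compact must be in [0,1]")
  assert_that(all(c(crosstalk_alpha, bleed_beta, background) >= 0),
              "rates must be nonnegative")
  structure(cfg, class = "sim_imaging_config")
}

#' Simulate a multi-channel FRET-FISH image dataset
#'
#' Renders fields of ellipsoidal nuclei (DNA channel) containing
#' diffraction-limited dot pairs whose emission follows the Förster law:
#' per dot, with transfer efficiency `E` and photon budgets `N_D`, `N_A`,
#' the donor channel receives `(1 - E) N_D`, the FRET channel
#' `E N_D + beta (1 - E) N_D + alpha N_A`, and the acceptor channel `N_A`
#' photons, each rendered as a 3D Gaussian PSF before Poisson and read
#' noise. Photon conservation holds before noise: donor plus transferred
#' photons equal `N_D`.
#'
#' @param config A [sim_imaging_config()].
#' @return A list with `fields` (each a list of channel arrays `dna`,
#'   `donor`, `acceptor`, `fret` indexed `[z, y, x]`, plus `voxel_size_um`),
#'   `truth` (list of tibbles `dots` and `nuclei`, and `masks`, the
#'   ground-truth 3D label arrays), and `config`.
#' @export
sim_image_dataset <- function(config = sim_imaging_config()) {
  cfg <- config
  vz <- cfg$voxel_size_um[["dz"]]; vy <- cfg$voxel_size_um[["dy"]]
  vx <- cfg$voxel_size_um[["dx"]]
  # per-nucleus cell size in px, with margin
  shrink <- cfg$condensation_factor^(-1 / 3)
  ry_px <- cfg$nucleus_radii_um[["y"]] / vy
  rx_px <- cfg$nucleus_radii_um[["x"]] / vx
  rz_px <- cfg$nucleus_radii_um[["z"]] / vz
  cell_y <- ceiling(2.6 * ry_px); cell_x <- ceiling(2.6 * rx_px)
  nz <- ceiling(2 * rz_px) + 7L
  ncol_f <- ceiling(sqrt(cfg$nuclei_per_field))
  nrow_f <- ceiling(cfg$nuclei_per_field / ncol_f)
  ny <- nrow_f * cell_y; nx <- ncol_f * cell_x
  n_fields <- ceiling(cfg$n_nuclei / cfg$nuclei_per_field)

  with_seed(cfg$seed, {
    fields <- vector("list", n_fields)
    masks <- vector("list", n_fields)
    dots_truth <- list()
    nuc_truth <- list()
    nuc_global <- 0L
    for (f in seq_len(n_fields)) {
      ch <- list(dna = array(0, c(nz, ny, nx)),
                 donor = array(0, c(nz, ny, nx)),
                 acceptor = array(0, c(nz, ny, nx)),
                 fret = array(0, c(nz, ny, nx)))
      lab3d <- array(0L, c(nz, ny, nx))
      n_here <- min(cfg$nuclei_per_field, cfg$n_nuclei - (f - 1L) * cfg$nuclei_per_field)
      for (k in seq_len(n_here)) {
        nuc_global <- nuc_global + 1L
        gy <- (k - 1L) %/% ncol_f; gx <- (k - 1L) %% ncol_f
        cy <- gy * cell_y + cell_y / 2 + runif(1, -1, 1)
        cx <- gx * cell_x + cell_x / 2 + runif(1, -1, 1)
        cz <- nz / 2 + runif(1, -0.5, 0.5)
        jit <- pmax(0.7, 1 + rnorm(3, 0, cfg$radius_jitter))
        rz <- rz_px * jit[1] * shrink
        ry <- ry_px * jit[2] * shrink
        rx <- rx_px * jit[3] * shrink
        # ellipsoid mask on local box
        zz <- seq_len(nz); yy <- seq_len(ny); xx <- seq_len(nx)
        dz2 <- ((zz - cz) / rz)^2
        dy2 <- ((yy - cy) / ry)^2
        dx2 <- ((xx - cx) / rx)^2
        inside <- outer(outer(dz2, dy2, `+`), dx2, `+`) <= 1
        content <- if (runif(1) < cfg$w_4n) "4N" else "2N"
        dens <- 30 * (if (content == "4N") 2 else 1) *
          cfg$condensation_factor * exp(rnorm(1, 0, cfg$hoechst_cv))
        ch$dna[inside] <- ch$dna[inside] + dens
        lab3d[inside] <- k
        nuc_truth[[length(nuc_truth) + 1L]] <- tibble(
          field = f, label = k, nucleus_id = nuc_global,
          content = content, hoechst_density = dens,
          cz = cz, cy = cy, cx = cx, rz = rz, ry = ry, rx = rx,
          volume_vox = sum(inside))
        # dots inside the nucleus (scaled radius <= 0.7)
        for (d in seq_len(cfg$dots_per_nucleus)) {
          repeat {
            u <- runif(3, -0.7, 0.7)
            if (sum(u^2) <= 0.49) break
          }
          pz <- cz + u[1] * rz; py <- cy + u[2] * ry; px <- cx + u[3] * rx
          state <- if (runif(1) < cfg$w_compact) "compact" else "open"
          r_mean <- (if (state == "compact") cfg$r_compact else cfg$r_open) *
            cfg$separation_scale
          r_sep <- r_mean * exp(rnorm(1, 0, cfg$r_cv))
          eff <- forster_efficiency(r_sep, cfg$r0)
          n_d <- cfg$n_donor; n_a <- cfg$n_acceptor
          ph_donor <- (1 - eff) * n_d
          ph_fret <- eff * n_d + cfg$bleed_beta * (1 - eff) * n_d +
            cfg$crosstalk_alpha * n_a
          ph_acc <- n_a
          # acceptor/fret rendered at the acceptor dye position: the
          # physical separation (Angstrom) is far below voxel size, so the
          # offset is localization jitter plus any chromatic shift
          jd <- rnorm(3, 0, cfg$channel_jitter_px / sqrt(3))
          pa <- c(pz, py, px) + jd + cfg$channel_shift_px
          add_psf(ch$donor, c(pz, py, px), ph_donor, cfg$psf_sigma_px) -> ch$donor
          add_psf(ch$fret, pa, ph_fret, cfg$psf_sigma_px) -> ch$fret
          add_psf(ch$acceptor, pa, ph_acc, cfg$psf_sigma_px) -> ch$acceptor
          dots_truth[[length(dots_truth) + 1L]] <- tibble(
            field = f, nucleus_label = k, nucleus_id = nuc_global,
            dot = d, z = pz, y = py, x = px,
            z_acc = pa[1], y_acc = pa[2], x_acc = pa[3],
            r_separation = r_sep, efficiency = eff, state = state,
            ph_donor = ph_donor, ph_fret = ph_fret, ph_acceptor = ph_acc)
        }
      }
      # noise
      for (nm in names(ch)) {
        img <- ch[[nm]] + cfg$background
        noisy <- array(rpois(length(img), img), dim = dim(img))
        if (cfg$read_noise_sd > 0)
          noisy <- noisy + array(rnorm(length(img), 0, cfg$read_noise_sd),
                                 dim = dim(img))
        ch[[nm]] <- pmax(noisy, 0)
      }
      ch$voxel_size_um <- cfg$voxel_size_um
      fields[[f]] <- ch
      masks[[f]] <- lab3d
    }
    list(fields = fields,
         truth = list(dots = bind_rows(dots_truth),
                      nuclei = bind_rows(nuc_truth),
                      masks = masks),
         config = cfg)
  })
}

# add a 3D Gaussian spot of integrated intensity `photons` at position
# p = (z, y, x) (1-based voxel-center coordinates)
add_psf <- function(img, p, photons, sigma) {
  d <- dim(img)
  sz <- sigma[["z"]]; sy <- sigma[["y"]]; sx <- sigma[["x"]]
  rz <- ceiling(4 * sz); ry <- ceiling(4 * sy); rx <- ceiling(4 * sx)
  z1 <- max(1, floor(p[1] - rz)); z2 <- min(d[1], ceiling(p[1] + rz))
  y1 <- max(1, floor(p[2] - ry)); y2 <- min(d[2], ceiling(p[2] + ry))
  x1 <- max(1, floor(p[3] - rx)); x2 <- min(d[3], ceiling(p[3] + rx))
  gz <- stats::dnorm(z1:z2, p[1], sz)
  gy <- stats::dnorm(y1:y2, p[2], sy)
  gx <- stats::dnorm(x1:x2, p[3], sx)
  blob <- outer(outer(gz, gy), gx) * photons
  img[z1:z2, y1:y2, x1:x2] <- img[z1:z2, y1:y2, x1:x2] + blob
  img
}

#' Simulate a pair of bead stacks with a known chromatic shift
#'
#' Bright isolated beads on a dark background, with channel B translated by
#' `shift_px` relative to channel A. Fixture for [estimate_channel_shift()].
#'
#' @param n_beads Number of beads.
#' @param dim_zyx Stack dimensions (z, y, x).
#' @param shift_px True (z, y, x) translation of channel B.
#' @param photons Photons per bead.
#' @param psf_sigma_px PSF sigma (z, y, x) in px.
#' @param noise Apply Poisson noise (with background 5).
#' @param seed RNG seed.
#' @return List with `a`, `b` (arrays), `truth` (bead positions tibble).
#' @export
sim_beads <- function(n_beads = 8L, dim_zyx = c(16L, 64L, 64L),
                      shift_px = c(z = 0, y = 0, x = 0), photons = 20000,
                      psf_sigma_px = c(z = 1.0, y = 1.3, x = 1.3),
                      noise = TRUE, seed = 1L) {
  with_seed(seed, {
    a <- array(0, dim_zyx); b <- array(0, dim_zyx)
    pos <- tibble(
      z = runif(n_beads, 5, dim_zyx[1] - 4),
      y = runif(n_beads, 8, dim_zyx[2] - 7),
      x = runif(n_beads, 8, dim_zyx[3] - 7))
    for (i in seq_len(n_beads)) {
      p <- c(pos$z[i], pos$y[i], pos$x[i])
      a <- add_psf(a, p, photons, psf_sigma_px)
      b <- add_psf(b, p + shift_px, photons, psf_sigma_px)
    }
    if (noise) {
      a <- array(rpois(length(a), a + 5), dim = dim_zyx)
      b <- array(rpois(length(b), b + 5), dim = dim_zyx)
    }
    list(a = a, b = b, truth = pos)
  })
}
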