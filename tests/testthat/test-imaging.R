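make_blank_stack <- function(nz = 12, ny = 48, nx = 48, value = 0) {
  list(dna = array(value, c(nz, ny, nx)),
       donor = array(value, c(nz, ny, nx)),
       acceptor = array(value, c(nz, ny, nx)),
       fret = array(value, c(nz, ny, nx)),
       voxel_size_um = c(dz = 0.3, dy = 1.9 / 7, dx = 1.9 / 7))
}

# render one noiseless ellipsoid into the dna channel
add_ellipsoid <- function(arr, centre, radii, value = 100) {
  d <- dim(arr)
  dz2 <- ((seq_len(d[1]) - centre[1]) / radii[1])^2
  dy2 <- ((seq_len(d[2]) - centre[2]) / radii[2])^2
  dx2 <- ((seq_len(d[3]) - centre[3]) / radii[3])^2
  inside <- outer(outer(dz2, dy2, `+`), dx2, `+`) <= 1
  arr[inside] <- value
  arr
}

test_that("segmentation recovers isolated and touching nuclei, and handles blanks", {
  st <- make_blank_stack()
  st$dna <- add_ellipsoid(st$dna, c(6, 24, 24), c(4, 16, 16))
  truth <- st$dna[6, , ] > 0
  seg <- segment_nuclei(st)
  expect_equal(nrow(seg$nuclei), 1)
  overlap <- sum(seg$label_2d == 1 & truth) / sum(truth)
  expect_gte(overlap, 0.99)

  # two ellipsoids whose projections touch: watershed separates them
  st2 <- make_blank_stack(ny = 48, nx = 88)
  st2$dna <- add_ellipsoid(st2$dna, c(6, 24, 26), c(4, 15, 15))
  st2$dna <- add_ellipsoid(st2$dna, c(6, 24, 56), c(4, 15, 15))
  seg2 <- segment_nuclei(st2)
  expect_equal(nrow(seg2$nuclei), 2)
  cx <- sort(seg2$nuclei$centroid_x)
  expect_lt(abs(cx[1] - 26), 3)
  expect_lt(abs(cx[2] - 56), 3)

  # blank image: zero nuclei, no error
  seg0 <- segment_nuclei(make_blank_stack())
  expect_equal(nrow(seg0$nuclei), 0)
})

test_that("segmentation labels are disjoint and dense from 1", {
  ds <- sim_image_dataset(sim_imaging_config(n_nuclei = 4, seed = 2))
  seg <- segment_nuclei(ds$fields[[1]])
  labs <- sort(unique(as.vector(seg$label_2d)))
  expect_equal(labs, 0:max(labs))
  expect_equal(max(labs), nrow(seg$nuclei))
})

test_that("3d mode attaches volumes and a 3D label array", {
  ds <- sim_image_dataset(sim_imaging_config(n_nuclei = 2, seed = 3))
  seg <- segment_nuclei(ds$fields[[1]], mode = "3d")
  expect_false(is.null(seg$label_3d))
  expect_true(all(seg$nuclei$volume_vox > 0))
  # 3D labels project onto the 2D labels
  proj <- apply(seg$label_3d, c(2, 3), max)
  expect_true(all(proj[proj > 0] == seg$label_2d[proj > 0]))
})

test_that("dot detection finds planted spots with sub-voxel accuracy", {
  st <- make_blank_stack()
  st$dna <- add_ellipsoid(st$dna, c(6, 24, 24), c(5, 20, 20))
  seg <- segment_nuclei(st)
  # one spot, SNR ~ 10 against Poisson background
  pos <- c(6.3, 22.6, 27.2)
  sig <- c(z = 1.0, y = 1.3, x = 1.3)
  st$donor <- fretfish:::add_psf(st$donor, pos, 5000, sig)
  set.seed(7)
  st$donor <- array(rpois(length(st$donor), st$donor + 10), dim(st$donor))
  dots <- detect_dots(st, "donor", seg, expected_per_nucleus = 1)
  expect_equal(nrow(dots), 1)
  expect_lt(max(abs(c(dots$z, dots$y, dots$x) - pos)), 1)

  # three spots, keep the two brightest
  st3 <- make_blank_stack()
  st3$dna <- add_ellipsoid(st3$dna, c(6, 24, 24), c(5, 20, 20))
  seg3 <- segment_nuclei(st3)
  st3$donor <- fretfish:::add_psf(st3$donor, c(6, 14, 14), 6000, sig)
  st3$donor <- fretfish:::add_psf(st3$donor, c(6, 30, 30), 5000, sig)
  st3$donor <- fretfish:::add_psf(st3$donor, c(6, 14, 34), 1500, sig)
  set.seed(8)
  st3$donor <- array(rpois(length(st3$donor), st3$donor + 10),
                     dim(st3$donor))
  dots3 <- detect_dots(st3, "donor", seg3, expected_per_nucleus = 2)
  expect_equal(nrow(dots3), 2)
  got <- dots3[order(dots3$y), ]
  expect_lt(abs(got$y[1] - 14), 1.5)
  expect_lt(abs(got$y[2] - 30), 1.5)

  # noise-only nucleus: nothing passes the quality threshold
  stn <- make_blank_stack()
  stn$dna <- add_ellipsoid(stn$dna, c(6, 24, 24), c(5, 20, 20))
  segn <- segment_nuclei(stn)
  set.seed(9)
  stn$donor <- array(rpois(length(stn$donor), 10), dim(stn$donor))
  expect_equal(nrow(detect_dots(stn, "donor", segn)), 0)

  expect_error(detect_dots(stn, "missing", segn), "channel")
})

test_that("channel shift is recovered from bead fields", {
  b0 <- sim_beads(8, shift_px = c(z = 0, y = 0, x = 0), noise = FALSE,
                  seed = 4)
  cs0 <- estimate_channel_shift(b0$a, b0$b)
  expect_lt(max(abs(cs0$translation)), 1e-6)

  b1 <- sim_beads(8, shift_px = c(z = 0, y = 2, x = 1), noise = FALSE,
                  seed = 4)
  cs1 <- estimate_channel_shift(b1$a, b1$b)
  expect_lt(max(abs(cs1$translation - c(0, 2, 1))), 0.1)

  # Poisson noise, 10 seeds: recovery within 0.2 px
  errs <- sapply(1:10, function(s) {
    b <- sim_beads(8, shift_px = c(z = 1, y = -1.5, x = 0.5), noise = TRUE,
                   seed = s)
    cs <- estimate_channel_shift(b$a, b$b)
    max(abs(cs$translation - c(1, -1.5, 0.5)))
  })
  expect_lt(max(errs), 0.2)

  # fewer than 3 beads errors
  b2 <- sim_beads(2, noise = FALSE, seed = 5)
  expect_error(estimate_channel_shift(b2$a, b2$b), "3")

  # correcting then inverting is the identity
  dots <- tibble::tibble(z = c(3, 4), y = c(10, 20), x = c(5, 6))
  rt <- correct_dots(correct_dots(dots, cs1), cs1, invert = TRUE)
  expect_equal(rt, dots)
})

test_that("pairing respects the 7 px radius and matches the assignment oracle", {
  mk_dot <- function(lab, z, y, x) {
    tibble::tibble(nucleus_label = lab, channel = "c", z = z, y = y, x = x,
                   intensity = 1, quality = 10)
  }
  # 8 px apart: not paired
  p0 <- pair_dots(mk_dot(1, 0, 0, 0), mk_dot(1, 0, 0, 8))
  expect_equal(nrow(p0), 0)
  # coincident: paired at separation 0
  p1 <- pair_dots(mk_dot(1, 2, 3, 4), mk_dot(1, 2, 3, 4))
  expect_equal(nrow(p1), 1)
  expect_equal(p1$separation_px, 0)

  # random tables vs exhaustive oracle, several seeds and sizes
  for (seed in 1:12) {
    set.seed(seed)
    nd <- sample(1:5, 1); na <- sample(1:5, 1)
    dd <- mk_dot(1, runif(nd, 0, 10), runif(nd, 0, 20), runif(nd, 0, 20))
    aa <- mk_dot(1, runif(na, 0, 10), runif(na, 0, 20), runif(na, 0, 20))
    pp <- pair_dots(dd, aa)
    D <- sqrt(outer(dd$z, aa$z, `-`)^2 + outer(dd$y, aa$y, `-`)^2 +
                outer(dd$x, aa$x, `-`)^2)
    ref <- oracle_assignment(D, 7)
    expect_equal(nrow(pp), ref$k)
    if (nrow(pp) > 0) {
      expect_equal(sum(pp$separation_px), ref$total, tolerance = 1e-9)
      expect_true(all(pp$separation_px <= 7))
      # each dot used at most once
      expect_false(any(duplicated(pp$donor_idx)))
      expect_false(any(duplicated(pp$acceptor_idx)))
      # symmetric in channel order
      qq <- pair_dots(aa, dd)
      expect_equal(nrow(qq), nrow(pp))
      expect_equal(sort(qq$separation_px), sort(pp$separation_px),
                   tolerance = 1e-9)
    }
  }
})

test_that("FRET intensity read-out is background-subtracted and clipped", {
  st <- make_blank_stack(value = 0)
  st$fret[] <- 20          # flat background
  st$donor[] <- 20
  st$fret[6, 24, 24] <- 70 # +50 above background at the acceptor voxel
  pairs <- tibble::tibble(nucleus_label = 1,
                          z_donor = 6, y_donor = 10, x_donor = 10,
                          z_acceptor = 6, y_acceptor = 24, x_acceptor = 24,
                          separation_px = 0)
  m <- measure_fret_intensity(pairs, st, statistic = "peak")
  expect_equal(m$i_fret, 50)
  expect_equal(m$i_donor, 0)   # background-only location clips to 0

  # out-of-bounds dot errors
  pairs_bad <- dplyr::mutate(pairs, z_acceptor = 99)
  expect_error(measure_fret_intensity(pairs_bad, st), "bounds")
})

test_that("end-to-end detection: recall >= 0.95, RMSE <= 1 voxel, intensities within 10%", {
  cfg <- sim_imaging_config(n_nuclei = 12, seed = 42)
  ds <- sim_image_dataset(cfg)
  q <- quantify_fields(ds$fields)
  truth <- ds$truth$dots
  # recall of true dot pairs
  expect_gte(nrow(q$pairs) / nrow(truth), 0.95)
  # match measured pairs to truth within each field by position
  errs <- c(); ierrs <- c()
  for (f in unique(q$pairs$field)) {
    pf <- q$pairs[q$pairs$field == f, ]
    tf <- truth[truth$field == f, ]
    for (i in seq_len(nrow(pf))) {
      d2 <- (tf$z - pf$z_donor[i])^2 + (tf$y - pf$y_donor[i])^2 +
        (tf$x - pf$x_donor[i])^2
      j <- which.min(d2)
      errs <- c(errs, sqrt(d2[j]))
      ierrs <- c(ierrs, abs(pf$i_fret[i] - tf$ph_fret[j]) / tf$ph_fret[j])
    }
  }
  expect_lte(sqrt(mean(errs^2)), 1)
  expect_lte(median(ierrs), 0.10)
})
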