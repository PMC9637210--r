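#' Simulate a photon-arrival decay histogram
#'
#' Samples photon arrival times from a mixture of exponential decays,
#' optionally convolved with a Gaussian instrument response (IRF), and bins
#' them on a uniform grid. The default photon budget (1000) matches a
#' typical per-signal FLIM acquisition target.
#'
#' @param tau Lifetimes in ns (one per component).
#' @param amplitudes Relative component weights (recycled to sum 1).
#' @param photons Total photon count (>= 100).
#' @param irf_sigma Gaussian IRF width (ns); 0 = ideal delta response.
#' @param t0 Time offset (ns) added to every arrival.
#' @param bin_width Histogram bin width (ns).
#' @param t_max Upper edge of the last bin (ns); late/early arrivals are
#'   clamped into the edge bins so counts always sum to `photons`.
#' @param background_fraction Fraction of photons drawn uniformly over the
#'   record (dark counts / ambient light).
#' @param seed Integer RNG seed.
#'
#' @return A `decay_histogram`: list with `bin_centers` (ns), `counts`,
#'   `bin_width`, `total_photons`, and `irf` (normalized curve on the same
#'   bins, or `NULL`).
#' @export
sim_decay <- function(tau, amplitudes = rep(1, length(tau)), photons = 1000L,
                      irf_sigma = 0, t0 = 0, bin_width = 0.05, t_max = 50,
                      background_fraction = 0, seed = 1L) {
  assert_that(all(tau > 0), "lifetimes must be positive")
  assert_that(photons >= 100, "photons must be >= 100")
  w <- amplitudes / sum(amplitudes)
  t <- with_seed(seed, {
    comp <- sample.int(length(tau), photons, replace = TRUE, prob = w)
    tt <- t0 + rexp(photons, rate = 1 / tau[comp])
    if (irf_sigma > 0) tt <- tt + rnorm(photons, 0, irf_sigma)
    nbg <- round(background_fraction * photons)
    if (nbg > 0) tt[seq_len(nbg)] <- runif(nbg, 0, t_max)
    tt
  })
  edges <- seq(0, t_max, by = bin_width)
  t <- pmin(pmax(t, 0), t_max - bin_width / 2)
  counts <- tabulate(findInterval(t, edges, rightmost.closed = TRUE),
                     nbins = length(edges) - 1L)
  irf <- NULL
  if (irf_sigma > 0) {
    centers <- edges[-length(edges)] + bin_width / 2
    irf <- stats::dnorm(centers, mean = t0, sd = irf_sigma)
    irf <- irf / sum(irf)
  }
  new_decay_histogram(edges[-length(edges)] + bin_width / 2, counts, irf)
}

#' Construct a decay histogram object
#'
#' @param bin_centers Strictly increasing, uniformly spaced bin centers (ns).
#' @param counts Nonnegative integer photon counts per bin.
#' @param irf Optional IRF curve on the same bins (normalized to sum 1).
#' @return A `decay_histogram` object.
#' @export
new_decay_histogram <- function(bin_centers, counts, irf = NULL) {
  assert_that(length(bin_centers) == length(counts),
              "bin_centers and counts must have equal length")
  d <- diff(bin_centers)
  assert_that(all(d > 0), "bins must be strictly increasing")
  assert_that(max(d) - min(d) < 1e-9 * mean(d) + 1e-12,
              "bins must be uniformly spaced")
  assert_that(all(counts >= 0), "counts must be nonnegative")
  if (!is.null(irf)) {
    assert_that(length(irf) == length(counts),
                "irf must share the histogram bins")
    irf <- irf / sum(irf)
  }
  structure(list(bin_centers = as.numeric(bin_centers),
                 counts = as.numeric(counts),
                 bin_width = mean(d),
                 total_photons = sum(counts),
                 irf = irf),
            class = "decay_histogram")
}

#' Read a decay histogram from CSV
#'
#' Expects columns `time_ns` and `counts`; an optional IRF CSV has columns
#' `time_ns` and `irf` on the same grid.
#'
#' @param path Decay CSV path.
#' @param irf_path Optional IRF CSV path.
#' @return A `decay_histogram`.
#' @export
read_decay_csv <- function(path, irf_path = NULL) {
  d <- readr::read_csv(path, show_col_types = FALSE)
  irf <- NULL
  if (!is.null(irf_path)) {
    ir <- readr::read_csv(irf_path, show_col_types = FALSE)
    assert_that(nrow(ir) == nrow(d), "IRF grid must match decay grid")
    irf <- ir$irf
  }
  new_decay_histogram(d$time_ns, d$counts, irf)
}

#' Write a decay histogram to CSV
#' @param hist A `decay_histogram`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_decay_csv <- function(hist, path) {
  readr::write_csv(tibble(time_ns = hist$bin_centers, counts = hist$counts),
                   path)
  invisible(path)
}

#' @export
print.decay_histogram <- function(x, ...) {
  cat("<decay_histogram> ", length(x$counts), " bins of ",
      signif(x$bin_width, 3), " ns, ", x$total_photons, " photons",
      if (!is.null(x$irf)) ", with IRF" else "", "\n", sep = "")
  invisible(x)
}
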