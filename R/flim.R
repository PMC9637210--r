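#' Multi-exponential tail fit of a decay histogram
#'
#' Fits `y(t) = sum_i A[i] * exp(-(t - t0) / tau[i]) + Bkgr` to the tail of
#' a photon-decay histogram (the region after the histogram maximum, where
#' the instrument response has died out) by Poisson maximum likelihood.
#' Component intensities `I[k] = A[k] * tau[k] / bin_width`, and the
#' intensity- and amplitude-weighted average lifetimes, are attached.
#'
#' @param hist A `decay_histogram`.
#' @param n Number of exponential components. When `NULL`, 1 vs 2 are
#'   compared by penalized deviance (AIC).
#' @param tail_start Start of the fit region (ns). Default: one bin past the
#'   histogram maximum, plus two IRF sigmas when an IRF is attached.
#' @param objective `"poisson"` (deviance, default) or `"ls"`
#'   (least squares on counts).
#' @param restarts Number of seeded random restarts (best deviance kept).
#' @param seed Seed for the restart jitter.
#'
#' @return A `lifetime_fit`: list with `n`, `A`, `tau` (ns, sorted
#'   decreasing), `t0`, `bkgr`, `i_components`, `i_sum`, `a_sum`,
#'   `tau_av_int`, `tau_av_amp`, `deviance`, `reduced_deviance`, `df`.
#' @export
fit_tail_multiexp <- function(hist, n = NULL, tail_start = NULL,
                              objective = c("poisson", "ls"),
                              restarts = 5L, seed = 1L) {
  objective <- match.arg(objective)
  if (is.null(n)) {
    f1 <- fit_tail_multiexp(hist, 1L, tail_start, objective, restarts, seed)
    f2 <- tryCatch(
      suppressWarnings(
        fit_tail_multiexp(hist, 2L, tail_start, objective, restarts, seed)),
      error = function(e) NULL)
    if (!is.null(f2) && f2$deviance + 2 * 2 < f1$deviance) return(f2)
    return(f1)
  }
  n <- as.integer(n)
  peak <- which.max(hist$counts)
  if (is.null(tail_start)) {
    off <- if (!is.null(hist$irf)) {
      ir_sd <- sqrt(sum(hist$irf * hist$bin_centers^2) -
                      sum(hist$irf * hist$bin_centers)^2)
      ceiling(2 * ir_sd / hist$bin_width)
    } else 0L
    i0 <- peak + 1L + off
  } else {
    i0 <- which(hist$bin_centers >= tail_start)[1]
  }
  t <- hist$bin_centers[i0:length(hist$bin_centers)]
  y <- hist$counts[i0:length(hist$counts)]
  assert_that(length(t) >= 10, "tail region must span >= 10 bins")
  t0 <- t[1]
  tt <- t - t0

  dev_fun <- make_deviance(tt, y, n, objective)
  init <- tail_init(tt, y, n)
  best <- optimize_restarts(dev_fun, init, restarts, seed)
  th <- best$par
  A <- exp(th[seq_len(n)])
  tau <- exp(th[n + seq_len(n)])
  bkgr <- exp(th[2 * n + 1])
  ord <- order(A, decreasing = TRUE)
  A <- A[ord]; tau <- tau[ord]
  if (n >= 2 && max(tau) / min(tau) < 1.5 && hist$total_photons < 1e4)
    rlang::warn("lifetime ratio < 1.5 with < 10^4 photons: components may not be identifiable")
  i_comp <- A * tau / hist$bin_width
  fit <- structure(list(
    n = n, A = A, tau = tau, t0 = t0, bkgr = bkgr,
    i_components = i_comp, i_sum = sum(i_comp), a_sum = sum(A),
    tau_av_int = sum(i_comp * tau) / sum(i_comp),
    tau_av_amp = sum(A * tau) / sum(A),
    deviance = best$value,
    df = length(y) - (2 * n + 1),
    reduced_deviance = best$value / max(1, length(y) - (2 * n + 1)),
    objective = objective,
    tail_bins = c(i0, length(hist$counts))
  ), class = "lifetime_fit")
  fit
}

make_deviance <- function(tt, y, n, objective) {
  function(th) {
    A <- exp(th[seq_len(n)])
    tau <- exp(th[n + seq_len(n)])
    bkgr <- exp(th[2 * n + 1])
    mu <- drop(exp(outer(tt, -1 / tau)) %*% A) + bkgr
    if (objective == "poisson") {
      pos <- y > 0
      2 * (sum(mu - y) + sum(y[pos] * log(y[pos] / mu[pos])))
    } else {
      sum((y - mu)^2)
    }
  }
}

tail_init <- function(tt, y, n) {
  tau0 <- sum(tt * y) / max(sum(y), 1)      # mean arrival ~ tau for mono-exp
  tau0 <- max(tau0, 10 * (tt[2] - tt[1]))
  taus <- if (n == 1) tau0 else tau0 * exp(seq(-0.8, 0.8, length.out = n))
  A0 <- max(y[1], 1) / n
  c(log(rep(A0, n)), log(taus), log(max(mean(tail(y, 10)), 1e-3)))
}

optimize_restarts <- function(fn, init, restarts, seed) {
  jitters <- with_seed(seed, replicate(restarts, rnorm(length(init), 0, 0.3),
                                       simplify = FALSE))
  jitters[[1]] <- rep(0, length(init))    # first start = plain init
  best <- NULL
  for (j in jitters) {
    r <- tryCatch({
      r1 <- optim(init + j, fn, method = "Nelder-Mead",
                  control = list(maxit = 5000, reltol = 1e-14))
      optim(r1$par, fn, method = "BFGS",
            control = list(maxit = 500, reltol = 1e-14))
    }, error = function(e) NULL)
    if (is.null(r)) next
    if (is.null(best) || r$value < best$value) best <- r
  }
  if (is.null(best)) rlang::abort("lifetime fit did not converge")
  best
}

#' Average lifetimes of a multi-exponential fit
#'
#' Intensity-weighted mean `sum(I * tau) / sum(I)` (the mean photon arrival
#' time) and amplitude-weighted mean `sum(A * tau) / sum(A)` (the mean
#' decay time).
#'
#' @param fit A `lifetime_fit`.
#' @return Named numeric vector `c(tau_av_int, tau_av_amp)` in ns.
#' @export
average_lifetimes <- function(fit) {
  if (fit$i_sum <= 0) rlang::abort("zero total intensity")
  c(tau_av_int = sum(fit$i_components * fit$tau) / fit$i_sum,
    tau_av_amp = sum(fit$A * fit$tau) / fit$a_sum)
}

#' FRET efficiency from quenched and unquenched donor lifetimes
#'
#' `E = 1 - tau_da / tau_d`. Negative values (quenched lifetime above the
#' unquenched reference) are unphysical and clipped to 0 with a warning.
#'
#' @param tau_da Quenched donor lifetime (ns).
#' @param tau_d Unquenched donor lifetime (ns).
#' @return Efficiency in `[0, 1)`.
#' @export
fret_efficiency <- function(tau_da, tau_d) {
  assert_that(all(tau_da > 0) && all(tau_d > 0), "lifetimes must be positive")
  e <- 1 - tau_da / tau_d
  if (any(e < 0)) {
    rlang::warn("tau_da > tau_d: negative efficiency clipped to 0")
    e <- pmax(e, 0)
  }
  e
}

#' IRF-convolved two-component donor fit
#'
#' Fits the donor decay model
#' `{IRF(t + Shift_IRF) + Bkgr_IRF} (x) {A_D exp(-t/tau_D) + A_DA exp(-t/tau_DA) + Bkgr}`
#' with the unquenched donor lifetime `tau_D` fixed and the quenched
#' lifetime `tau_DA`, the bound/unbound amplitudes, the IRF shift and the
#' background terms free. FRET efficiency is `1 - tau_DA / tau_D`.
#'
#' @param hist A `decay_histogram` (its `irf` is used unless `irf` given).
#' @param irf Optional IRF curve on the histogram bins.
#' @param tau_d_fixed Unquenched donor lifetime (ns), e.g. 3.057 for AF488
#'   in situ.
#' @param restarts Seeded random restarts.
#' @param seed Restart jitter seed.
#'
#' @return A `fret_donor_fit`: list with `tau_d`, `tau_da`, `a_d`, `a_da`
#'   (fractions), `shift_irf`, `bkgr_irf`, `bkgr`, `efficiency` (NA when the
#'   quenched fraction is ~0), `deviance`, `reduced_deviance`.
#' @export
fit_fret_donor <- function(hist, irf = NULL, tau_d_fixed, restarts = 5L,
                           seed = 1L) {
  irf <- irf %||% hist$irf
  assert_that(!is.null(irf), "an IRF is required for the donor model fit")
  assert_that(tau_d_fixed > 0, "tau_d_fixed must be positive")
  irf <- irf / sum(irf)
  if (sum(irf > 0) == 1)
    rlang::inform("IRF has a single non-zero bin: treated as a delta response")
  y <- hist$counts
  tc <- hist$bin_centers
  dt <- hist$bin_width
  tt <- tc - tc[1]

  model <- function(th) {
    a_d <- exp(th[1]); a_da <- exp(th[2])
    tau_da <- tau_d_fixed * stats::plogis(th[3])
    shift <- th[4]
    bkgr_irf <- exp(th[5]); bkgr <- exp(th[6])
    irf_s <- stats::approx(tc, irf, xout = tc + shift, rule = 2)$y
    irf_s <- irf_s / sum(irf_s) + bkgr_irf
    dec <- a_d * exp(-tt / tau_d_fixed) + a_da * exp(-tt / tau_da) + bkgr
    mu <- causal_conv(irf_s, dec)
    pmax(mu, 1e-12)
  }
  dev_fun <- function(th) {
    mu <- model(th)
    pos <- y > 0
    2 * (sum(mu - y) + sum(y[pos] * log(y[pos] / mu[pos])))
  }
  a0 <- max(y) / 2
  init <- c(log(a0), log(a0), stats::qlogis(0.5), 0,
            log(1e-6), log(max(mean(tail(y, 10)), 1e-3)))
  best <- optimize_restarts(dev_fun, init, restarts, seed)
  th <- best$par
  a_d_raw <- exp(th[1]); a_da_raw <- exp(th[2])
  tau_da <- tau_d_fixed * stats::plogis(th[3])
  frac_da <- a_da_raw / (a_d_raw + a_da_raw)
  # no quenched fraction: amplitude ~0, or tau_da ~ tau_d (the two
  # components are then interchangeable and the split is arbitrary)
  if (frac_da < 0.02 || (1 - tau_da / tau_d_fixed) < 0.02) {
    rlang::inform("no resolvable quenched fraction: efficiency reported as NA")
    eff <- NA_real_
    frac_da <- 0
  } else {
    eff <- fret_efficiency(tau_da, tau_d_fixed)
  }
  structure(list(
    tau_d = tau_d_fixed, tau_da = tau_da,
    a_d = 1 - frac_da, a_da = frac_da,
    shift_irf = th[4], bkgr_irf = exp(th[5]), bkgr = exp(th[6]),
    efficiency = eff,
    deviance = best$value,
    reduced_deviance = best$value / max(1, length(y) - 6),
    df = length(y) - 6
  ), class = "fret_donor_fit")
}

# discrete causal convolution on the histogram grid, zero-padded to a
# power-of-two FFT length
causal_conv <- function(irf, dec) {
  n <- length(dec)
  m <- stats::nextn(2L * n - 1L, 2)
  fa <- stats::fft(c(irf, numeric(m - n)))
  fb <- stats::fft(c(dec, numeric(m - n)))
  full <- Re(stats::fft(fa * fb, inverse = TRUE)) / m
  full[seq_len(n)]
}

#' @export
print.lifetime_fit <- function(x, ...) {
  cat("<lifetime_fit> ", x$n, " component(s): tau =",
      paste(signif(x$tau, 4), collapse = ", "),
      "ns; tau_av_int =", signif(x$tau_av_int, 4),
      "ns; tau_av_amp =", signif(x$tau_av_amp, 4), "ns\n")
  invisible(x)
}

#' @export
print.fret_donor_fit <- function(x, ...) {
  cat("<fret_donor_fit> tau_da =", signif(x$tau_da, 4),
      "ns (tau_d fixed", signif(x$tau_d, 4), "ns), E =",
      signif(x$efficiency, 3), ", quenched fraction =",
      signif(x$a_da, 3), "\n")
  invisible(x)
}
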