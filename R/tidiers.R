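#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a multi-exponential lifetime fit
#'
#' One row per exponential component with amplitude, lifetime and
#' component intensity.
#'
#' @param x A `lifetime_fit`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.lifetime_fit <- function(x, ...) {
  tibble(component = seq_len(x$n), amplitude = x$A, tau_ns = x$tau,
         intensity = x$i_components)
}

#' @rdname tidy.lifetime_fit
#' @export
glance.lifetime_fit <- function(x, ...) {
  tibble(n_components = x$n, tau_av_int = x$tau_av_int,
         tau_av_amp = x$tau_av_amp, bkgr = x$bkgr,
         deviance = x$deviance, reduced_deviance = x$reduced_deviance,
         df = x$df)
}

#' Tidy an IRF-convolved donor fit
#'
#' @param x A `fret_donor_fit`.
#' @param ... Unused.
#' @return A one-row tibble of parameters.
#' @export
tidy.fret_donor_fit <- function(x, ...) {
  tibble(term = c("tau_d", "tau_da", "a_d", "a_da", "shift_irf",
                  "bkgr_irf", "bkgr", "efficiency"),
         estimate = c(x$tau_d, x$tau_da, x$a_d, x$a_da, x$shift_irf,
                      x$bkgr_irf, x$bkgr, x$efficiency))
}

#' @rdname tidy.fret_donor_fit
#' @export
glance.fret_donor_fit <- function(x, ...) {
  tibble(efficiency = x$efficiency, tau_da = x$tau_da,
         quenched_fraction = x$a_da, deviance = x$deviance,
         reduced_deviance = x$reduced_deviance, df = x$df)
}

#' Tidy a mode split
#'
#' @param x A `mode_split`.
#' @param ... Unused.
#' @return A one-row tibble.
#' @export
tidy.mode_split <- function(x, ...) {
  tibble(is_bimodal = x$is_bimodal, threshold = x$threshold,
         frac_low = x$frac_low, frac_high = x$frac_high,
         bandwidth = x$bandwidth)
}

#' Tidy a probe set
#'
#' @param x A `probe_set`.
#' @param ... Unused.
#' @return The oligo tibble.
#' @export
tidy.probe_set <- function(x, ...) x$oligos

#' @rdname tidy.probe_set
#' @export
glance.probe_set <- function(x, ...) {
  counts <- table(x$oligos$dye_role)
  tibble(n_oligos = nrow(x$oligos),
         n_donor = as.integer(counts["donor"] %||% 0L),
         n_acceptor = as.integer(counts["acceptor"] %||% 0L),
         span_nt = x$span, objective = x$objective,
         n_missing = x$n_missing,
         min_gap_nt = min(diff(sort(x$oligos$start)) -
                            (x$oligos$end[1] - x$oligos$start[1])),
         design_variant = x$design_variant, layout = x$params$layout)
}
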