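#' Plot a score distribution with its mode split
#'
#' Histogram plus kernel-density curve; when a `mode_split` is supplied its
#' threshold is drawn and the two modes shaded.
#'
#' @param scores Tibble with a `score_pct` column (or numeric vector).
#' @param split Optional `mode_split` from [split_modes()].
#' @return A ggplot object.
#' @export
plot_score_distribution <- function(scores, split = NULL) {
  if (is.numeric(scores)) scores <- tibble(score_pct = scores)
  p <- ggplot2::ggplot(scores, ggplot2::aes(x = .data$score_pct)) +
    ggplot2::geom_histogram(ggplot2::aes(y = ggplot2::after_stat(density)),
                            bins = 40, fill = "grey80", colour = "grey40") +
    ggplot2::geom_density(colour = "red") +
    ggplot2::labs(x = "FRET-FISH score (%)", y = "density") +
    ggplot2::theme_minimal()
  if (!is.null(split) && isTRUE(split$is_bimodal)) {
    p <- p + ggplot2::geom_vline(xintercept = split$threshold,
                                 linetype = "dashed") +
      ggplot2::annotate("text", x = split$threshold, y = Inf,
                        label = sprintf("%.0f%% | %.0f%%",
                                        100 * split$frac_low,
                                        100 * split$frac_high),
                        vjust = 1.5, hjust = -0.1)
  }
  p
}

#' @export
autoplot.mode_split <- function(object, scores, ...) {
  plot_score_distribution(scores, object)
}

#' Plot probe oligo layout along the target
#'
#' Oligo target intervals coloured by dye role.
#'
#' @param probe A `probe_set`.
#' @return A ggplot object.
#' @export
plot_probe_layout <- function(probe) {
  ggplot2::ggplot(probe$oligos,
                  ggplot2::aes(xmin = .data$start, xmax = .data$end,
                               ymin = 0, ymax = 1,
                               fill = .data$dye_role)) +
    ggplot2::geom_rect() +
    ggplot2::scale_fill_manual(values = c(donor = "#2e8b57",
                                          acceptor = "#ff8c00")) +
    ggplot2::labs(x = "position (nt)", y = NULL, fill = "dye") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}

#' Plot a decay histogram with an optional fitted curve
#'
#' @param hist A `decay_histogram`.
#' @param fit Optional `lifetime_fit` whose tail model is overlaid.
#' @return A ggplot object (log-scaled counts).
#' @export
plot_decay <- function(hist, fit = NULL) {
  df <- tibble(t = hist$bin_centers, counts = hist$counts)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$t, y = .data$counts)) +
    ggplot2::geom_point(size = 0.4, alpha = 0.6) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "time (ns)", y = "photons") +
    ggplot2::theme_minimal()
  if (!is.null(fit)) {
    tt <- df$t[df$t >= fit$t0]
    mu <- drop(exp(outer(tt - fit$t0, -1 / fit$tau)) %*% fit$A) + fit$bkgr
    p <- p + ggplot2::geom_line(data = tibble(t = tt, counts = mu),
                                colour = "red")
  }
  p
}

#' @export
autoplot.decay_histogram <- function(object, fit = NULL, ...) {
  plot_decay(object, fit)
}

#' Plot score vs accessibility concordance
#'
#' @param comparison Per-locus tibble with `mean_score` and `atac_count`.
#' @return A ggplot object.
#' @export
plot_atac_concordance <- function(comparison) {
  cors <- correlate_score_vs_atac(comparison)
  ggplot2::ggplot(comparison,
                  ggplot2::aes(x = .data$atac_count, y = .data$mean_score)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "grey50", linetype = "dashed") +
    ggplot2::labs(x = "window read count",
                  y = "mean FRET-FISH score (%)",
                  subtitle = sprintf("SCC %.2f, PCC %.2f", cors$scc,
                                     cors$pcc)) +
    ggplot2::theme_minimal()
}
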