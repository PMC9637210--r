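#' Classify nuclei into cell-cycle groups from DNA-stain intensity
#'
#' The distribution of integrated nuclear DNA-stain (Hoechst) intensity in
#' a cycling population is bimodal: a 2N peak (G1) and a 4N peak (G2/M).
#' The threshold is placed at the kernel-density valley between the two
#' highest modes (fallback: a 2-component Gaussian mixture on log
#' intensity); nuclei below it are G1, above it non-G1. Within G1, the top
#' quartile by intensity is labelled Hoechst-high (`"high"`), the rest
#' `"low"` (optionally the bottom quartile only). Mitotic nuclei cannot be
#' inferred from intensity and are accepted only via user annotations.
#'
#' @param nuclei Tibble with `label` and `hoechst_total` (e.g.
#'   `seg$nuclei`).
#' @param high_def `"top_quartile"` for high with `"rest"` low (default), or
#'   `"bottom_quartile"` for low restricted to the bottom quartile.
#' @param annotations Optional tibble (`label`, `class`) of user-supplied
#'   classes (e.g. `"M"`); overrides the automatic call for those labels.
#' @return `nuclei` with `cycle_class` (`"G1"`, `"nonG1"`, `"M"`,
#'   `"unknown"`) and `hoechst_subclass` (`"high"`, `"low"`, `NA`); the
#'   threshold is attached as `attr(, "threshold")`.
#' @export
classify_cell_cycle <- function(nuclei, high_def = c("top_quartile",
                                                     "bottom_quartile"),
                                annotations = NULL) {
  high_def <- match.arg(high_def)
  if (nrow(nuclei) < 2) rlang::abort("need >= 2 nuclei")
  h <- nuclei$hoechst_total
  if (max(h) == min(h)) {
    rlang::warn("all DNA-stain intensities equal: cell cycle unknown")
    nuclei$cycle_class <- "unknown"
    nuclei$hoechst_subclass <- NA_character_
    return(nuclei)
  }
  lh <- log(h)
  thr <- kde_valley(lh)
  if (is.na(thr)) thr <- mixture_valley(lh)
  if (is.na(thr)) {
    rlang::warn("DNA-content distribution not resolvably bimodal: cell cycle unknown")
    nuclei$cycle_class <- "unknown"
    nuclei$hoechst_subclass <- NA_character_
    return(nuclei)
  }
  cls <- ifelse(lh < thr, "G1", "nonG1")
  sub <- rep(NA_character_, length(cls))
  g1 <- which(cls == "G1")
  if (length(g1) >= 4) {
    r <- rank(h[g1], ties.method = "first")
    n1 <- length(g1)
    top <- r > n1 - floor(n1 / 4)
    if (high_def == "top_quartile") {
      sub[g1] <- ifelse(top, "high", "low")
    } else {
      bottom <- r <= floor(n1 / 4)
      sub[g1] <- ifelse(top, "high", ifelse(bottom, "low", NA_character_))
    }
  }
  nuclei$cycle_class <- cls
  nuclei$hoechst_subclass <- sub
  if (!is.null(annotations)) {
    i <- match(annotations$label, nuclei$label)
    ok <- !is.na(i)
    nuclei$cycle_class[i[ok]] <- annotations$class[ok]
  }
  attr(nuclei, "threshold") <- exp(thr)
  nuclei
}

# valley between the two highest KDE modes; NA when a second mode with
# >= 10% of the main peak height is absent
kde_valley <- function(x, min_peak_frac = 0.1) {
  if (length(x) < 4) return(NA_real_)
  de <- stats::density(x)
  y <- de$y
  loc_max <- which(diff(sign(diff(y))) == -2) + 1L
  loc_max <- loc_max[y[loc_max] >= min_peak_frac * max(y)]
  if (length(loc_max) < 2) return(NA_real_)
  top2 <- loc_max[order(y[loc_max], decreasing = TRUE)][1:2]
  i1 <- min(top2); i2 <- max(top2)
  between <- i1:i2
  valley <- between[which.min(y[between])]
  # the dip must be a real valley, not a shoulder
  if (y[valley] > 0.95 * min(y[i1], y[i2])) return(NA_real_)
  de$x[valley]
}

# 2-component Gaussian mixture fallback on log intensity
mixture_valley <- function(x) {
  fit <- tryCatch(
    mclust::Mclust(x, G = 2, modelNames = "V", verbose = FALSE),
    error = function(e) NULL)
  if (is.null(fit)) return(NA_real_)
  mu <- fit$parameters$mean
  sg <- sqrt(fit$parameters$variance$sigmasq)
  if (length(sg) == 1) sg <- rep(sg, 2)
  sep <- abs(diff(mu)) / mean(sg)
  if (sep < 2) return(NA_real_)   # modes not resolved
  # decision boundary between the two components
  grid <- seq(min(mu), max(mu), length.out = 512)
  p <- fit$parameters$pro
  d1 <- p[1] * stats::dnorm(grid, mu[1], sg[1])
  d2 <- p[2] * stats::dnorm(grid, mu[2], sg[2])
  grid[which.min(abs(d1 - d2))]
}
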