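#' FRET-FISH compaction score
#'
#' `score = 100 * i_fret / (i_fret + i_donor)`: the sensitized-emission
#' read-out as a percentage. Higher scores indicate more compact chromatin.
#' The score is invariant under joint scaling of both intensities and
#' strictly increasing in `i_fret` for fixed `i_donor`. Records with both
#' intensities zero are undefined (NA with a warning).
#'
#' @param i_fret FRET-channel intensity (donor excitation, acceptor
#'   emission), >= 0.
#' @param i_donor Donor-channel intensity (donor excitation, donor
#'   emission), >= 0.
#' @return Score(s) in `[0, 100]`.
#' @export
#'
#' @examples
#' fret_score(100, 100)   # 50
#' fret_score(39.5, 60.5) # 39.5
fret_score <- function(i_fret, i_donor) {
  assert_that(all(i_fret >= 0) && all(i_donor >= 0),
              "intensities must be nonnegative")
  tot <- i_fret + i_donor
  if (any(tot == 0)) {
    rlang::warn("records with i_fret + i_donor == 0 are undefined: NA")
  }
  ifelse(tot > 0, 100 * i_fret / tot, NA_real_)
}

#' Score measured dot pairs
#'
#' Applies [fret_score()] to a pair tibble from [measure_fret_intensity()],
#' dropping undefined records.
#'
#' @param pairs Tibble with `i_fret` and `i_donor`.
#' @param condition Optional condition label attached to all rows.
#' @return `pairs` with a `score_pct` column, undefined rows removed.
#' @export
score_pairs <- function(pairs, condition = NA_character_) {
  out <- pairs |>
    mutate(score_pct = suppressWarnings(
      fret_score(.data$i_fret, .data$i_donor)),
      condition = condition)
  n_bad <- sum(is.na(out$score_pct))
  if (n_bad > 0)
    rlang::warn(sprintf("dropped %d pair(s) with zero total intensity", n_bad))
  filter(out, !is.na(.data$score_pct))
}

#' Crosstalk baseline from single-dye control samples
#'
#' Summarises the score distributions of donor-only and acceptor-only
#' control hybridizations (median, IQR), tests whether they agree with one
#' another (homogeneous controls), and, when test scores are supplied,
#' whether the test distribution exceeds the pooled control baseline
#' (one-sided rank test). No subtraction is applied to test scores; raw
#' scores are reported.
#'
#' @param scores_donor_only,scores_acceptor_only Numeric control score
#'   vectors.
#' @param scores_test Optional test-condition scores.
#' @return A list with `summary` (tibble per control), `homogeneous`
#'   (logical), `p_homogeneity`, and when test scores are given
#'   `p_above_baseline`.
#' @export
crosstalk_baseline <- function(scores_donor_only, scores_acceptor_only,
                               scores_test = NULL) {
  if (length(scores_donor_only) == 0 || length(scores_acceptor_only) == 0)
    rlang::abort("control score vectors must be non-empty")
  summ <- tibble(
    control = c("donor_only", "acceptor_only"),
    n = c(length(scores_donor_only), length(scores_acceptor_only)),
    median = c(median(scores_donor_only), median(scores_acceptor_only)),
    iqr = c(stats::IQR(scores_donor_only), stats::IQR(scores_acceptor_only)))
  p_hom <- suppressWarnings(
    wilcox.test(scores_donor_only, scores_acceptor_only,
                exact = FALSE)$p.value)
  if (is.na(p_hom)) p_hom <- 1    # identical constant controls
  out <- list(summary = summ, homogeneous = p_hom > 0.05,
              p_homogeneity = p_hom)
  if (!is.null(scores_test)) {
    ctrl <- c(scores_donor_only, scores_acceptor_only)
    out$p_above_baseline <- suppressWarnings(
      wilcox.test(scores_test, ctrl, alternative = "greater",
                  exact = FALSE)$p.value)
  }
  out
}

#' Split a bimodal score distribution into its two modes
#'
#' Kernel-density estimate (Silverman bandwidth by default) of the score
#' distribution; the threshold separating the lower and higher mode is the
#' density minimum between the two dominant maxima (`method = "valley"`,
#' default) or the second-derivative zero crossing nearest that minimum
#' (`method = "inflection"`). Fractions are the empirical proportions
#' below and above the threshold.
#'
#' @param scores Numeric vector (>= 30 values).
#' @param bw Bandwidth specification passed to [stats::density()].
#' @param method `"valley"` or `"inflection"`.
#' @param min_peak_frac Minimum height of the secondary mode relative to
#'   the main peak for the distribution to count as bimodal.
#' @return A `mode_split`: list with `threshold`, `frac_low`, `frac_high`,
#'   `bandwidth`, `is_bimodal`, `modes` (x positions).
#' @export
split_modes <- function(scores, bw = "nrd0",
                        method = c("valley", "inflection"),
                        min_peak_frac = 0.1) {
  method <- match.arg(method)
  if (length(scores) < 30) rlang::abort("need >= 30 scores to split modes")
  de <- stats::density(scores, bw = bw)
  y <- de$y
  loc_max <- which(diff(sign(diff(y))) == -2) + 1L
  loc_max <- loc_max[y[loc_max] >= min_peak_frac * max(y)]
  if (length(loc_max) < 2) {
    return(structure(list(threshold = NA_real_, frac_low = 1,
                          frac_high = NA_real_, bandwidth = de$bw,
                          is_bimodal = FALSE,
                          modes = de$x[loc_max]), class = "mode_split"))
  }
  top2 <- sort(loc_max[order(y[loc_max], decreasing = TRUE)][1:2])
  between <- top2[1]:top2[2]
  valley <- between[which.min(y[between])]
  if (y[valley] > 0.95 * min(y[top2])) {
    return(structure(list(threshold = NA_real_, frac_low = 1,
                          frac_high = NA_real_, bandwidth = de$bw,
                          is_bimodal = FALSE,
                          modes = de$x[top2]), class = "mode_split"))
  }
  thr <- de$x[valley]
  if (method == "inflection") {
    d2 <- diff(y, differences = 2)
    sgn <- diff(sign(d2))
    cross <- which(sgn != 0) + 1L
    cross <- cross[cross > top2[1] & cross < top2[2]]
    if (length(cross) > 0) thr <- de$x[cross[which.min(abs(cross - valley))]]
  }
  fl <- mean(scores < thr)
  structure(list(threshold = thr, frac_low = fl, frac_high = 1 - fl,
                 bandwidth = de$bw, is_bimodal = TRUE,
                 modes = de$x[top2]), class = "mode_split")
}

#' @export
print.mode_split <- function(x, ...) {
  if (x$is_bimodal) {
    cat("<mode_split> bimodal; threshold ", signif(x$threshold, 4),
        ", fractions ", signif(x$frac_low, 3), " / ",
        signif(x$frac_high, 3), "\n", sep = "")
  } else {
    cat("<mode_split> unimodal (no threshold)\n")
  }
  invisible(x)
}

#' Compare score distributions between two conditions
#'
#' Two-sided Wilcoxon rank-sum test with a Hodges-Lehmann estimate of the
#' median shift (`b - a`).
#'
#' @param scores_a,scores_b Numeric score vectors.
#' @param exact Force the exact test (otherwise [stats::wilcox.test()]
#'   default behaviour).
#' @return Tibble with `p_value`, `median_shift`, `n_a`, `n_b`.
#' @export
compare_conditions <- function(scores_a, scores_b, exact = NULL) {
  assert_that(length(scores_a) > 0 && length(scores_b) > 0,
              "both groups must be non-empty")
  if (length(scores_a) < 3 || length(scores_b) < 3) {
    rlang::warn("group size < 3: p-value reported as NA")
    return(tibble(p_value = NA_real_,
                  median_shift = median(scores_b) - median(scores_a),
                  n_a = length(scores_a), n_b = length(scores_b)))
  }
  wt <- suppressWarnings(
    wilcox.test(scores_b, scores_a, conf.int = TRUE, exact = exact))
  tibble(p_value = wt$p.value,
         median_shift = unname(wt$estimate),
         n_a = length(scores_a), n_b = length(scores_b))
}
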