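#' Select the best probe window from labelled candidates
#'
#' Searches every possible anchor offset along the target region for the
#' layout window that minimises total oligo penalty plus a spacing-deviation
#' term. The layout places `n_total` oligo slots on an ideal grid: within a
#' group of `group_size` same-dye oligos consecutive targets are
#' `spacing_same_dye` nt apart, and consecutive groups (alternating donor /
#' acceptor) are `spacing_between_dyes` nt apart. Each slot snaps to the
#' nearest usable candidate within half an oligo length of its ideal
#' position, subject to a minimum inter-oligo gap.
#'
#' Usable candidates are good-quality oligos after removing good oligos both
#' of whose flanking candidates are bad. The objective is
#' `sum(penalty) + lambda_spacing * sum(|start - ideal|)` with each unfilled
#' slot costing `lambda_spacing * l`; at most `incomplete_group_tolerance`
#' slots may stay unfilled. Ties between equally scoring windows go to the
#' smallest start coordinate.
#'
#' @param cands Candidate tibble, composition-filtered and (optionally)
#'   homology-penalized.
#' @param params A [design_params()] object.
#' @return A `probe_set` object: list with `oligos` (tibble of selected
#'   oligos with `dye_role`, `slot`, `ideal_start`, `deviation`), `params`,
#'   `span`, `objective`, `n_missing`, `design_variant` (unset until
#'   [assemble_oligos()]).
#' @export
select_best_window <- function(cands, params = design_params()) {
  cands <- arrange(cands, .data$start)
  usable <- remove_isolated_good(cands)
  n_req <- params$n_total - params$incomplete_group_tolerance
  if (nrow(usable) < n_req) {
    rlang::abort(sprintf(
      "only %d usable oligos; need at least %d (n_total %d - tolerance %d)",
      nrow(usable), n_req, params$n_total, params$incomplete_group_tolerance))
  }
  grid <- layout_grid(params)
  span_total <- grid$ideal_start[length(grid$ideal_start)] + params$l
  seq_len_nt <- max(cands$end)
  if (!is.null(params$window_span)) {
    span_total <- min(span_total, params$window_span)
  }
  anchor_max <- seq_len_nt - span_total
  if (anchor_max < 0) {
    rlang::abort(sprintf(
      "layout span (%d nt) exceeds region length (%d nt): spacing constraints unsatisfiable",
      span_total, seq_len_nt))
  }
  ustart <- usable$start
  upen <- usable$homology_penalty
  half <- params$l %/% 2L
  best <- NULL
  for (s0 in 0:anchor_max) {
    fit <- fill_window(s0, grid, ustart, upen, params, half)
    if (is.null(fit)) next
    if (is.null(best) || fit$objective < best$objective) {
      best <- fit
      best$anchor <- s0
    }
  }
  if (is.null(best)) {
    rlang::abort(paste0(
      "no feasible window: could not fill ", params$n_total,
      " slots within tolerance ", params$incomplete_group_tolerance,
      " (first unsatisfiable constraint: slot snapping within +/-", half,
      " nt at min_gap ", params$min_gap, ")"))
  }
  sel <- usable[best$idx, ]
  oligos <- sel |>
    mutate(slot = best$slot,
           dye_role = grid$dye[best$slot],
           ideal_start = best$anchor + grid$ideal_start[best$slot],
           deviation = .data$start - .data$ideal_start) |>
    arrange(.data$start)
  structure(list(
    oligos = oligos,
    params = params,
    span = max(oligos$end) - min(oligos$start),
    objective = best$objective,
    n_missing = best$n_missing,
    anchor = best$anchor,
    design_variant = NA_character_,
    detection_oligos = NULL
  ), class = "probe_set")
}

# drop good oligos whose immediate candidate neighbours are both bad
remove_isolated_good <- function(cands) {
  q <- cands$quality == "good"
  n <- length(q)
  if (n == 0) return(cands[0, ])
  left_bad <- c(FALSE, !q[-n])   # first oligo has no left neighbour
  right_bad <- c(!q[-1], FALSE)
  keep <- q & !(left_bad & right_bad)
  cands[keep, ]
}

# ideal slot starts (0-based, relative to anchor) and dye roles
layout_grid <- function(params) {
  n <- params$n_total
  g <- params$group_size
  starts <- integer(n)
  dye <- character(n)
  pos <- 0L
  for (k in seq_len(n)) {
    starts[k] <- pos
    grp <- (k - 1L) %/% g
    dye[k] <- if (grp %% 2L == 0L) "donor" else "acceptor"
    same_group_next <- (k %% g) != 0L
    gap <- if (same_group_next) params$spacing_same_dye else
      params$spacing_between_dyes
    gap <- max(gap, params$min_gap)
    pos <- pos + params$l + gap
  }
  list(ideal_start = starts, dye = dye)
}

# greedy slot fill for one anchor; returns NULL when infeasible
fill_window <- function(s0, grid, ustart, upen, params, half) {
  n <- length(grid$ideal_start)
  idx <- integer(0)
  slot <- integer(0)
  objective <- 0
  n_missing <- 0L
  prev_end <- -Inf
  for (k in seq_len(n)) {
    ideal <- s0 + grid$ideal_start[k]
    lo <- max(ideal - half, prev_end + params$min_gap)
    hi <- ideal + half
    i1 <- findInterval(lo - 1L, ustart) + 1L
    i2 <- findInterval(hi, ustart)
    if (i2 >= i1) {
      cand <- i1:i2
      cost <- upen[cand] + params$lambda_spacing * abs(ustart[cand] - ideal)
      j <- cand[which.min(cost)]   # which.min: first = smallest start on ties
      idx <- c(idx, j)
      slot <- c(slot, k)
      objective <- objective + upen[j] +
        params$lambda_spacing * abs(ustart[j] - ideal)
      prev_end <- ustart[j] + params$l
    } else {
      n_missing <- n_missing + 1L
      if (n_missing > params$incomplete_group_tolerance) return(NULL)
      objective <- objective + params$lambda_spacing * params$l
    }
  }
  list(idx = idx, slot = slot, objective = objective, n_missing = n_missing)
}

#' @export
print.probe_set <- function(x, ...) {
  counts <- table(x$oligos$dye_role)
  cat("<probe_set> ", nrow(x$oligos), " oligos (",
      paste(names(counts), counts, sep = ": ", collapse = ", "),
      "), span ", x$span, " nt, layout ", x$params$layout,
      if (!is.na(x$design_variant)) paste0(", ", x$design_variant) else "",
      "\n", sep = "")
  invisible(x)
}
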