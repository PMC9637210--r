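# Independent brute-force oracles used to verify the package's algorithms.
# Deliberately written with plain loops, no shared code with R/.

# exhaustive ungapped homology scan: all offsets, character comparison
oracle_homology_scan <- function(oligo, genome, min_identity = 0.8) {
  l <- nchar(oligo)
  oc <- strsplit(oligo, "")[[1]]
  gc <- strsplit(genome, "")[[1]]
  hits <- list()
  for (s in 0:(length(gc) - l)) {
    matches <- sum(oc == gc[(s + 1):(s + l)])
    if (matches / l >= min_identity) {
      hits[[length(hits) + 1]] <- c(start = s, score = matches)
    }
  }
  if (length(hits) == 0) {
    return(data.frame(start = integer(), score = numeric()))
  }
  as.data.frame(do.call(rbind, hits))
}

# brute-force best-window search: every integer anchor, plain greedy fill
oracle_best_window <- function(cands, params) {
  cands <- cands[order(cands$start), ]
  good <- cands$quality == "good"
  n <- nrow(cands)
  keep <- logical(n)
  for (i in seq_len(n)) {
    if (!good[i]) next
    lb <- if (i > 1) !good[i - 1] else FALSE
    rb <- if (i < n) !good[i + 1] else FALSE
    keep[i] <- !(lb && rb)
  }
  us <- cands[keep, ]
  # ideal grid
  nt <- params$n_total
  ideal <- integer(nt)
  pos <- 0L
  for (k in seq_len(nt)) {
    ideal[k] <- pos
    gap <- if ((k %% params$group_size) != 0L) params$spacing_same_dye else
      params$spacing_between_dyes
    pos <- pos + params$l + max(gap, params$min_gap)
  }
  span <- ideal[nt] + params$l
  half <- params$l %/% 2
  best_obj <- Inf
  best_anchor <- NA
  for (s0 in 0:(max(cands$end) - span)) {
    obj <- 0
    miss <- 0
    prev_end <- -Inf
    feasible <- TRUE
    for (k in seq_len(nt)) {
      id <- s0 + ideal[k]
      costs <- rep(Inf, nrow(us))
      for (j in seq_len(nrow(us))) {
        if (abs(us$start[j] - id) <= half &&
            us$start[j] >= prev_end + params$min_gap) {
          costs[j] <- us$homology_penalty[j] +
            params$lambda_spacing * abs(us$start[j] - id)
        }
      }
      if (all(!is.finite(costs))) {
        miss <- miss + 1
        obj <- obj + params$lambda_spacing * params$l
        if (miss > params$incomplete_group_tolerance) {
          feasible <- FALSE
          break
        }
      } else {
        j <- which.min(costs)
        obj <- obj + costs[j]
        prev_end <- us$start[j] + params$l
      }
    }
    if (feasible && obj < best_obj) {
      best_obj <- obj
      best_anchor <- s0
    }
  }
  list(objective = best_obj, anchor = best_anchor)
}

# exhaustive min-total-distance assignment for pairing (<= 5 per channel):
# maximise the number of pairs within `thr`, then minimise total distance
oracle_assignment <- function(D, thr) {
  nd <- nrow(D)
  na <- ncol(D)
  best <- list(k = -1, total = Inf, pairs = NULL)
  assignments <- function(d_idx, a_free, acc) {
    if (d_idx > nd) {
      k <- nrow(acc)
      tot <- if (k > 0) sum(D[acc]) else 0
      if (k > best$k || (k == best$k && tot < best$total - 1e-12)) {
        best <<- list(k = k, total = tot, pairs = acc)
      }
      return(invisible(NULL))
    }
    assignments(d_idx + 1, a_free, acc)      # donor left unmatched
    for (a in which(a_free)) {
      if (D[d_idx, a] <= thr) {
        a2 <- a_free
        a2[a] <- FALSE
        assignments(d_idx + 1, a2, rbind(acc, c(d_idx, a)))
      }
    }
  }
  assignments(1, rep(TRUE, na), matrix(integer(), 0, 2))
  best
}

# exact two-sided rank-sum p-value by enumeration of all group splits
oracle_ranksum_p <- function(a, b) {
  pooled <- c(a, b)
  n <- length(a)
  w_obs <- sum(rank(pooled)[seq_len(n)])
  splits <- utils::combn(length(pooled), n)
  ws <- apply(splits, 2, function(ix) sum(rank(pooled)[ix]))
  p_low <- mean(ws <= w_obs)
  p_high <- mean(ws >= w_obs)
  min(1, 2 * min(p_low, p_high))
}

# small helper: candidate tibble from explicit fields
make_cands <- function(starts, l, quality, penalty = 0, chrom = "chr") {
  tibble::tibble(
    oligo_id = sprintf("oligo_%05d", starts),
    chrom = chrom, start = as.integer(starts),
    end = as.integer(starts + l),
    target_seq = strrep("A", l), gc_fraction = 0.5,
    max_run = 1L, has_n = FALSE,
    homology_penalty = rep(penalty, length.out = length(starts)),
    quality = rep(quality, length.out = length(starts)))
}
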