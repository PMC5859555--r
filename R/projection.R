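# Coordinate-space projection: the union of all calls in one partition is
# decomposed into maximal disjoint segments over which the set of supporting
# callers is constant. Segment expectations come from the trained powerset
# table by lookup of the supporting set.

#' Project partition callsets onto disjoint support segments
#'
#' @param partition_callsets named list, caller id -> [sv_callset()], all
#'   restricted to a single partition (one sv_type, one size bin).
#' @param expectations optional named expectation vector (keys as from
#'   [all_group_expectations()]); when supplied each segment gets its
#'   supporting set's expectation by lookup.
#' @return data.frame with columns `start`, `end` (0-based inclusive),
#'   `support` (comma-joined sorted caller ids) and, when expectations are
#'   given, `expectation`.
#' @export
project_support <- function(partition_callsets, expectations = NULL) {
  ids <- as.integer(names(partition_callsets))
  nonempty <- vapply(partition_callsets, nrow, 0L) > 0
  if (!any(nonempty)) {
    return(data.frame(start = numeric(0), end = numeric(0),
                      support = character(0), expectation = numeric(0)))
  }
  sets <- partition_callsets[nonempty]
  ids <- ids[nonempty]
  # elementary boundaries: call starts and ends+1
  starts <- unlist(lapply(sets, function(cs) cs$s_start), use.names = FALSE)
  ends <- unlist(lapply(sets, function(cs) cs$s_end), use.names = FALSE)
  bounds <- sort(unique(c(starts, ends + 1)))
  seg_s <- bounds[-length(bounds)]
  seg_e <- bounds[-1] - 1
  # per-caller coverage of each elementary segment
  cov <- matrix(FALSE, length(seg_s), length(ids))
  for (k in seq_along(sets)) {
    m <- iv_merge(iv(sets[[k]]$s_start, sets[[k]]$s_end))
    cov[, k] <- iv_overlap_each(iv(seg_s, seg_e), m) > 0
  }
  keep <- rowSums(cov) > 0
  seg_s <- seg_s[keep]
  seg_e <- seg_e[keep]
  cov <- cov[keep, , drop = FALSE]
  support <- apply(cov, 1, function(r) group_key(ids[r]))
  # merge contiguous elementary segments with identical support
  if (length(seg_s) > 1) {
    brk <- c(TRUE, seg_s[-1] != seg_e[-length(seg_e)] + 1 |
               support[-1] != support[-length(support)])
    g <- cumsum(brk)
    seg_s <- seg_s[brk]
    seg_e <- as.numeric(tapply(seg_e, g, max))
    support <- support[brk]
  }
  out <- data.frame(start = seg_s, end = seg_e, support = support,
                    stringsAsFactors = FALSE)
  if (!is.null(expectations)) {
    miss <- setdiff(unique(out$support), names(expectations))
    if (length(miss)) {
      stop_data("supporting set(s) missing from expectation map: ",
                paste(miss, collapse = "; "))
    }
    out$expectation <- unname(expectations[out$support])
  }
  out
}

# Fuse surviving (already filtered) segments: contiguous/overlapping runs are
# joined into proposal calls; expectation of a fused call is the
# segment-length-weighted mean of its member segments.
fuse_segments <- function(segments) {
  if (nrow(segments) == 0) {
    return(data.frame(start = numeric(0), end = numeric(0),
                      expectation = numeric(0), support = character(0)))
  }
  o <- order(segments$start)
  segments <- segments[o, , drop = FALSE]
  brk <- c(TRUE, segments$start[-1] >
             segments$end[-nrow(segments)] + 1)
  g <- cumsum(brk)
  lens <- segments$end - segments$start + 1
  data.frame(
    start = as.numeric(tapply(segments$start, g, min)),
    end = as.numeric(tapply(segments$end, g, max)),
    expectation = as.numeric(
      tapply(seq_len(nrow(segments)), g, function(idx) {
        stats::weighted.mean(segments$expectation[idx], lens[idx])
      })),
    support = as.character(
      tapply(segments$support, g, function(su) {
        group_key(unique(unlist(strsplit(su, ",", fixed = TRUE))))
      })),
    stringsAsFactors = FALSE)
}

proposal_intervals <- function(projection, p) {
  keep <- projection$expectation >= p
  iv_merge(iv(projection$start[keep], projection$end[keep]))
}

#' Fit the optimal expectation cutoff for one partition
#'
#' Searches the candidate grid (0 plus every distinct expectation value
#' present in `expectations`) for the cutoff `p` minimizing the pooled
#' weighted distance between the proposal callset (segments with expectation
#' `>= p`, fused) and the truth, across the training observations. Ties are
#' broken toward the larger cutoff (the more conservative filter). The
#' default `search = "exhaustive"` scans every candidate and is exact; the
#' iterative `"em"` refinement over the sorted grid is only worthwhile for
#' large caller counts and must agree with the exhaustive search on small
#' fixtures.
#'
#' @param obs_partitions list (one element per observation) of named lists
#'   caller id -> [sv_callset()] restricted to the partition.
#' @param truths list of truth [sv_callset()] restricted to the partition.
#' @param expectations named expectation vector for this partition.
#' @param weights per-observation weights.
#' @param metric distance metric for the proposal-vs-truth comparison.
#' @param search `"exhaustive"` (exact) or `"em"` (iterative refinement).
#' @return list with `alpha`, `distance` (achieved pooled distance),
#'   `candidates` and `distances` (the full scan, exhaustive only).
#' @export
fit_cutoff <- function(obs_partitions, truths, expectations,
                       weights = NULL, metric = "J",
                       search = c("exhaustive", "em")) {
  search <- match.arg(search)
  weights <- weights %||% rep(1, length(obs_partitions))
  candidates <- sort(unique(c(0, unname(expectations))))
  if (!length(candidates)) {
    svf_log(1L, "no cutoff candidates; alpha = 0 (keep everything)")
    return(list(alpha = 0, distance = NA_real_,
                candidates = numeric(0), distances = numeric(0)))
  }
  projections <- lapply(obs_partitions, project_support, expectations)
  truth_iv <- lapply(truths, function(tr)
    iv_merge(iv(tr$s_start, tr$s_end)))
  pooled_dist <- function(p) {
    d <- vapply(seq_along(projections), function(y) {
      prop <- proposal_intervals(projections[[y]], p)
      tm <- truth_iv[[y]]
      lp <- iv_total_len(prop)
      lt <- iv_total_len(tm)
      if (metric == "J") {
        if (lp == 0 && lt == 0) return(0)
        inter <- iv_intersect_len(prop, tm)
        return(1 - inter / (lp + lt - inter))
      }
      # event-based metrics on the fused proposal intervals
      ty <- if (nrow(truths[[y]])) truths[[y]]$sv_type[1] else "DEL"
      prop_cs <- sv_callset(prop[, 1], prop[, 2], rep(ty, nrow(prop)))
      callset_distance(prop_cs, truths[[y]], metric)
    }, 0)
    sum(weights * d) / sum(weights)
  }
  if (search == "exhaustive") {
    dists <- vapply(candidates, pooled_dist, 0)
    best <- max(which(dists == min(dists)))  # tie -> larger cutoff
    return(list(alpha = candidates[best], distance = dists[best],
                candidates = candidates, distances = dists))
  }
  # iterative coarse-to-fine refinement over the sorted candidate grid
  lo <- 1L
  hi <- length(candidates)
  evaluated <- new.env()
  ev <- function(k) {
    key <- as.character(k)
    if (is.null(evaluated[[key]])) evaluated[[key]] <- pooled_dist(candidates[k])
    evaluated[[key]]
  }
  repeat {
    idx <- unique(round(seq(lo, hi, length.out = min(7, hi - lo + 1))))
    vals <- vapply(idx, ev, 0)
    kbest <- idx[max(which(vals == min(vals)))]
    pos <- match(kbest, idx)
    lo2 <- idx[max(1, pos - 1)]
    hi2 <- idx[min(length(idx), pos + 1)]
    if (lo2 == lo && hi2 == hi) break
    lo <- lo2
    hi <- hi2
    if (hi - lo <= 6) {
      idx <- seq(lo, hi)
      vals <- vapply(idx, ev, 0)
      kbest <- idx[max(which(vals == min(vals)))]
      break
    }
  }
  list(alpha = candidates[kbest], distance = ev(kbest),
       candidates = candidates, distances = NULL)
}

#' Estimate per-caller breakpoint spreads from training data
#'
#' For every caller, collects the left/right breakpoint differentials
#' (caller breakpoint minus matched truth breakpoint) over all calls that
#' overlap a same-type truth call; the match is the truth call with the
#' largest bp overlap (ties to the leftmost). The spread is the sample
#' standard deviation of each differential distribution; callers with fewer
#' than two overlapping calls get spread 0 and are excluded from smoothing.
#'
#' @param observations list of [sv_observation()] with truth.
#' @return Named list, caller id -> list(sigma_l, sigma_r, n, z_l, z_r).
#' @export
estimate_breakpoint_spreads <- function(observations) {
  ids <- obs_caller_ids(observations[[1]])
  out <- list()
  for (id in ids) {
    zl <- numeric(0)
    zr <- numeric(0)
    for (o in observations) {
      cs <- o$callsets[[as.character(id)]]
      tr <- o$truth
      if (is.null(tr) || nrow(cs) == 0 || nrow(tr) == 0) next
      for (ty in intersect(unique(cs$sv_type), unique(tr$sv_type))) {
        cc <- cs[cs$sv_type == ty, , drop = FALSE]
        tt <- tr[tr$sv_type == ty, , drop = FALSE]
        if (!nrow(cc) || !nrow(tt)) next
        for (i in seq_len(nrow(cc))) {
          ov <- pmin(cc$s_end[i], tt$s_end) - pmax(cc$s_start[i], tt$s_start) + 1
          ov[ov < 1] <- 0
          if (all(ov == 0)) next
          j <- which(ov == max(ov))
          j <- j[which.min(tt$s_start[j])]  # tie -> leftmost truth call
          zl <- c(zl, cc$s_start[i] - tt$s_start[j])
          zr <- c(zr, cc$s_end[i] - tt$s_end[j])
        }
      }
    }
    n <- length(zl)
    if (n < 2) {
      if (n == 0) svf_log(2L, "caller ", id, ": no truth overlaps; sigma = 0")
      out[[as.character(id)]] <- list(sigma_l = 0, sigma_r = 0, n = n,
                                      z_l = zl, z_r = zr)
    } else {
      out[[as.character(id)]] <- list(sigma_l = stats::sd(zl),
                                      sigma_r = stats::sd(zr),
                                      n = n, z_l = zl, z_r = zr)
    }
  }
  out
}
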