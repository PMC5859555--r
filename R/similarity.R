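#' Base-pair intersection of two callsets
#'
#' Number of flattened base pairs covered by at least one call in `a` AND at
#' least one call in `b` (multiplicity-free union coverage per side). With
#' `type_match = TRUE` the intersection is computed per sv_type and summed, so
#' a DEL cannot intersect a DUP.
#'
#' @param a,b [sv_callset()] objects.
#' @param type_match compare only within matching SV types.
#' @return bp count.
#' @export
bp_intersection <- function(a, b, type_match = FALSE) {
  if (type_match) {
    types <- intersect(unique(a$sv_type), unique(b$sv_type))
    return(sum(vapply(types, function(ty) {
      iv_intersect_len(iv_merge(callset_intervals(a, ty)),
                       iv_merge(callset_intervals(b, ty)))
    }, 0)))
  }
  iv_intersect_len(iv_merge(callset_intervals(a)),
                   iv_merge(callset_intervals(b)))
}

#' Jaccard base-pair similarity of two callsets
#'
#' `|a intersect b| / |a union b|` over base-pair sets. When both callsets are
#' empty the similarity is defined as 1 (trivial agreement), so a sparse
#' partition with no calls on either side does not register as maximal
#' disagreement.
#'
#' @inheritParams bp_intersection
#' @return Similarity in `[0, 1]`.
#' @export
jaccard <- function(a, b, type_match = FALSE) {
  if (type_match) {
    # base pairs tagged by sv_type: intersect/union computed per type, summed
    types <- union(unique(a$sv_type), unique(b$sv_type))
    inter <- 0
    uni <- 0
    for (ty in types) {
      ma <- iv_merge(callset_intervals(a, ty))
      mb <- iv_merge(callset_intervals(b, ty))
      it <- iv_intersect_len(ma, mb)
      inter <- inter + it
      uni <- uni + iv_total_len(ma) + iv_total_len(mb) - it
    }
    if (uni == 0) {
      svf_log(3L, "jaccard on two empty callsets -> 1 by convention")
      return(1)
    }
    return(inter / uni)
  }
  ma <- iv_merge(callset_intervals(a))
  mb <- iv_merge(callset_intervals(b))
  la <- iv_total_len(ma)
  lb <- iv_total_len(mb)
  if (la == 0 && lb == 0) {
    svf_log(3L, "jaccard on two empty callsets -> 1 by convention")
    return(1)
  }
  inter <- iv_intersect_len(ma, mb)
  inter / (la + lb - inter)
}

# overlap indicator per call of `c` against callset `other`.
# any-bp overlap by default; reciprocal_overlap > 0 requires a single
# counterpart call covering >= ro of both calls' lengths.
overlapped_flags <- function(c, other, reciprocal_overlap = 0,
                             type_match = TRUE) {
  n <- nrow(c)
  if (n == 0) return(logical(0))
  out <- logical(n)
  types <- if (type_match) unique(c$sv_type) else "any"
  for (ty in types) {
    sel <- if (type_match) which(c$sv_type == ty) else seq_len(n)
    oth <- if (type_match) other[other$sv_type == ty, , drop = FALSE]
           else other
    if (!length(sel) || nrow(oth) == 0) next
    if (reciprocal_overlap <= 0) {
      m <- iv_merge(iv(oth$s_start, oth$s_end))
      ov <- iv_overlap_each(iv(c$s_start[sel], c$s_end[sel]), m)
      out[sel] <- ov > 0
    } else {
      os <- oth$s_start
      oe <- oth$s_end
      o <- order(os)
      os <- os[o]; oe <- oe[o]
      for (i in sel) {
        cand <- which(os <= c$s_end[i] & oe >= c$s_start[i])
        if (!length(cand)) next
        ov <- pmin(c$s_end[i], oe[cand]) - pmax(c$s_start[i], os[cand]) + 1
        lens <- oe[cand] - os[cand] + 1
        li <- c$s_end[i] - c$s_start[i] + 1
        out[i] <- any(ov >= reciprocal_overlap * li &
                        ov >= reciprocal_overlap * lens)
      }
    }
  }
  out
}

#' Event-based precision
#'
#' Fraction of calls in `c` overlapped by at least one truth call (any-bp
#' overlap by default, within matching SV type). An empty `c` has precision 1
#' (no false positives).
#'
#' @param c candidate [sv_callset()].
#' @param truth truth [sv_callset()].
#' @param reciprocal_overlap optional reciprocal-overlap fraction; 0 means
#'   bare any-bp overlap.
#' @param type_match only count overlaps within the same sv_type.
#' @return Value in `[0, 1]`.
#' @export
precision <- function(c, truth, reciprocal_overlap = 0, type_match = TRUE) {
  if (nrow(c) == 0) {
    svf_log(3L, "precision of empty callset -> 1 by convention")
    return(1)
  }
  mean(overlapped_flags(c, truth, reciprocal_overlap, type_match))
}

#' Event-based recall
#'
#' Fraction of truth calls overlapped by at least one call in `c`. An empty
#' truth set has recall 1.
#'
#' @inheritParams precision
#' @return Value in `[0, 1]`.
#' @export
recall <- function(c, truth, reciprocal_overlap = 0, type_match = TRUE) {
  precision(truth, c, reciprocal_overlap, type_match)
}

#' F-measure from precision and recall
#'
#' `2 p r / (p + r)`, defined as 0 when `p + r == 0`.
#'
#' @param p,r precision and recall values in `[0, 1]`.
#' @return Value in `[0, 1]`.
#' @export
f1 <- function(p, r) {
  ifelse(p + r == 0, 0, 2 * p * r / (p + r))
}

metric_value <- function(a, b, metric = c("J", "prec", "rec", "F1"),
                         reciprocal_overlap = 0) {
  metric <- match.arg(metric)
  switch(metric,
         J = jaccard(a, b),
         prec = precision(a, b, reciprocal_overlap),
         rec = recall(a, b, reciprocal_overlap),
         F1 = f1(precision(a, b, reciprocal_overlap),
                 recall(a, b, reciprocal_overlap)))
}

#' Distance between two callsets under one metric
#'
#' `delta = 1 - q(a, b)` for `q` one of the four performance metrics.
#'
#' @param a,b [sv_callset()] objects; for `prec`/`rec`, `b` plays the truth
#'   role.
#' @param metric one of `"J"`, `"prec"`, `"rec"`, `"F1"`.
#' @param reciprocal_overlap passed to the event-based metrics.
#' @return Distance in `[0, 1]`.
#' @export
callset_distance <- function(a, b, metric = "J", reciprocal_overlap = 0) {
  1 - metric_value(a, b, metric, reciprocal_overlap)
}

#' Pooled weighted pairwise distance matrix
#'
#' Entry `(i, j)` is the weight-averaged distance `sum_y w_y *
#' delta(c_i^y, c_j^y) / sum_y w_y` over the observations. Only the symmetric
#' metrics (`J`, `F1`) are accepted, so the matrix is symmetric with zero
#' diagonal. With `include_truth` every observation must carry a truth
#' callset, which appears as the distinguished index `"t"`.
#'
#' @param observations list of [sv_observation()], all with the same caller
#'   index.
#' @param weights positive per-observation weights (default all 1).
#' @param metric `"J"` (default) or `"F1"`.
#' @param include_truth include the truth row/column `"t"`.
#' @param key optional partition key `"TYPE:bin"`; when given, callsets are
#'   restricted to that partition before computing distances.
#' @param bins bin scheme used when `key` is given.
#' @return Square matrix with dimnames caller ids (and `"t"`), attribute
#'   `metric`.
#' @export
pooled_distance_matrix <- function(observations, weights = NULL,
                                   metric = "J", include_truth = FALSE,
                                   key = NULL, bins = default_bins()) {
  if (!length(observations)) stop_data("no observations")
  if (!metric %in% c("J", "F1")) {
    stop_data("pooled matrix requires a symmetric metric (J or F1)")
  }
  ids <- obs_caller_ids(observations[[1]])
  for (o in observations) {
    if (!identical(obs_caller_ids(o), ids)) {
      stop_data("mixed caller sets across observations")
    }
    if (include_truth && is.null(o$truth)) {
      stop_data("include_truth requires a truth callset in every observation")
    }
  }
  weights <- weights %||% rep(1, length(observations))
  if (length(weights) != length(observations) || any(weights <= 0)) {
    stop_data("weights must be positive, one per observation")
  }
  labels <- c(as.character(ids), if (include_truth) "t")
  k <- length(labels)
  acc <- matrix(0, k, k, dimnames = list(labels, labels))
  restrict <- function(cs) {
    if (is.null(key)) return(cs)
    parts <- partition_callset(cs, bins)
    parts[[key]] %||% as_callset(cs[0, , drop = FALSE],
                                 caller_id_of(cs), sample_id_of(cs))
  }
  for (y in seq_along(observations)) {
    o <- observations[[y]]
    sets <- lapply(o$callsets, restrict)
    if (include_truth) sets <- c(sets, list(t = restrict(o$truth)))
    for (i in seq_len(k - 1)) {
      for (j in seq(i + 1, k)) {
        d <- callset_distance(sets[[i]], sets[[j]], metric)
        acc[i, j] <- acc[i, j] + weights[y] * d
      }
    }
  }
  acc <- acc / sum(weights)
  acc <- acc + t(acc)
  attr(acc, "metric") <- metric
  acc
}
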