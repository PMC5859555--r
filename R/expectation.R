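# Additive group expectation over the caller powerset.
#
# For a group G of callers and a pooled distance matrix D carrying a
# distinguished truth index "t", the expectation is
#
#   E(G) = prod_{i in G} (1 - D[i, t]) * max_{j in G \ {i}} D[j, i]
#
# i.e. each member contributes its performance against truth times its
# dissimilarity to the most dissimilar other member, so redundant (mutually
# similar) callers diminish the group's score. For a singleton the max runs
# over an empty set and is defined as 1, so E({i}) reduces to caller i's
# plain performance score. The product is order-invariant; the lexicographic
# ordering of the group by (distance-to-truth, similarity) is retained only
# as presentation order.

#' Group expectation for one caller subset
#'
#' @param G vector of caller ids (nonempty subset of the matrix index).
#' @param D square distance matrix with caller-id dimnames plus a truth
#'   row/column `"t"`, e.g. from [pooled_distance_matrix()] with
#'   `include_truth = TRUE`.
#' @return Expectation value in `[0, 1]`.
#' @export
group_expectation <- function(G, D) {
  G <- as.character(G)
  if (!length(G)) stop_data("group must be nonempty")
  if (!"t" %in% rownames(D)) stop_data("distance matrix lacks truth index 't'")
  if (!all(G %in% rownames(D))) stop_data("group member absent from matrix")
  f <- vapply(G, function(i) {
    others <- setdiff(G, i)
    mx <- if (length(others)) max(D[others, i]) else 1
    (1 - D[i, "t"]) * mx
  }, 0)
  min(max(prod(f), 0), 1)
}

group_key <- function(ids) paste(sort(as.integer(ids)), collapse = ",")

enumerate_subsets <- function(ids) {
  ids <- sort(as.integer(ids))
  n <- length(ids)
  out <- vector("list", 2^n - 1)
  for (m in seq_len(2^n - 1)) {
    out[[m]] <- ids[bitwAnd(m, bitwShiftL(1L, seq_len(n) - 1L)) != 0L]
  }
  out
}

#' Expectations for every nonempty caller subset
#'
#' Enumerates all `2^n - 1` nonempty subsets of the caller index and scores
#' each with [group_expectation()]. Refuses to enumerate beyond
#' `max_callers` (default 12) callers.
#'
#' @param D distance matrix with truth index `"t"`.
#' @param max_callers enumeration ceiling.
#' @return Named numeric vector; names are sorted caller ids joined by
#'   commas (e.g. `"1,3"`).
#' @export
all_group_expectations <- function(D, max_callers = 12) {
  ids <- setdiff(rownames(D), "t")
  if (length(ids) > max_callers) {
    stop_data("caller count ", length(ids), " exceeds the powerset ceiling (",
              max_callers, "); restrict the caller set")
  }
  subsets <- enumerate_subsets(ids)
  e <- vapply(subsets, group_expectation, 0, D = D)
  names(e) <- vapply(subsets, group_key, "")
  e
}

#' Update expectations with newly validated observations
#'
#' When truth is available for the new observations, the pooled distance
#' matrix is simply recomputed over the prior and new observations together
#' (with their weights) and the group expectations re-evaluated. With zero
#' new observations this reduces exactly to the prior expectations.
#'
#' @param prior_observations,new_observations lists of [sv_observation()]
#'   with truth; identical caller index.
#' @param prior_weights,new_weights per-observation weights.
#' @param metric,key,bins as in [pooled_distance_matrix()].
#' @return Named expectation vector as from [all_group_expectations()].
#' @export
update_expectation_with_truth <- function(prior_observations,
                                          new_observations = list(),
                                          prior_weights = NULL,
                                          new_weights = NULL,
                                          metric = "J", key = NULL,
                                          bins = default_bins()) {
  prior_weights <- prior_weights %||% rep(1, length(prior_observations))
  new_weights <- new_weights %||% rep(1, length(new_observations))
  if (length(new_observations)) {
    ids0 <- obs_caller_ids(prior_observations[[1]])
    if (!identical(ids0, obs_caller_ids(new_observations[[1]]))) {
      stop_data("caller index mismatch between prior and new observations")
    }
  }
  D <- pooled_distance_matrix(c(prior_observations, new_observations),
                              c(prior_weights, new_weights),
                              metric = metric, include_truth = TRUE,
                              key = key, bins = bins)
  all_group_expectations(D)
}

#' Update expectations with unvalidated observations (model mixture)
#'
#' When the new observations lack truth, the truth-involving distances are
#' computed over the prior observations only, while the caller-caller
#' distances are pooled over prior and new observations together; the group
#' expectation mixes the two:
#' `E(G) = prod_i (1 - D_prior[i, t]) * max_j D_all[j, i]`. With zero new
#' observations this reduces exactly to the prior expectations.
#'
#' @param prior_observations observations with truth.
#' @param new_observations observations without truth (same caller index).
#' @inheritParams update_expectation_with_truth
#' @return Named expectation vector.
#' @export
update_expectation_without_truth <- function(prior_observations,
                                             new_observations = list(),
                                             prior_weights = NULL,
                                             new_weights = NULL,
                                             metric = "J", key = NULL,
                                             bins = default_bins()) {
  prior_weights <- prior_weights %||% rep(1, length(prior_observations))
  new_weights <- new_weights %||% rep(1, length(new_observations))
  if (length(new_observations)) {
    ids0 <- obs_caller_ids(prior_observations[[1]])
    if (!identical(ids0, obs_caller_ids(new_observations[[1]]))) {
      stop_data("caller index mismatch between prior and new observations")
    }
  }
  Dt <- pooled_distance_matrix(prior_observations, prior_weights,
                               metric = metric, include_truth = TRUE,
                               key = key, bins = bins)
  Dcc <- pooled_distance_matrix(c(prior_observations, new_observations),
                                c(prior_weights, new_weights),
                                metric = metric, include_truth = FALSE,
                                key = key, bins = bins)
  ids <- setdiff(rownames(Dt), "t")
  subsets <- enumerate_subsets(ids)
  e <- vapply(subsets, function(G) {
    G <- as.character(G)
    f <- vapply(G, function(i) {
      others <- setdiff(G, i)
      mx <- if (length(others)) max(Dcc[others, i]) else 1
      (1 - Dt[i, "t"]) * mx
    }, 0)
    min(max(prod(f), 0), 1)
  }, 0)
  names(e) <- vapply(subsets, group_key, "")
  e
}
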