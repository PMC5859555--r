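#' Mantel permutation test between two distance matrices
#'
#' The statistic is the Pearson correlation of the upper-triangle entries;
#' the null distribution is obtained by applying the same random permutation
#' to rows and columns of `B`, and the one-sided p-value is
#' `(1 + #(permuted >= observed)) / (1 + permutations)`. With matrices of
#' order 2 there is a single off-diagonal value and the correlation is
#' undefined; the result is flagged degenerate with `statistic = NA`.
#'
#' @param A,B square symmetric distance matrices with identical dimnames
#'   order.
#' @param permutations number of permutations (>= 99).
#' @param seed RNG seed for reproducibility.
#' @return list with `statistic`, `p_value`, `permutations`, `degenerate`.
#' @export
mantel_test <- function(A, B, permutations = 999, seed = 1L) {
  if (!all(dim(A) == dim(B))) stop_data("matrices of different order")
  if (permutations < 99) stop_data("need at least 99 permutations")
  n <- nrow(A)
  ut <- upper.tri(A)
  a <- A[ut]
  b <- B[ut]
  if (n < 3 || stats::sd(a) == 0 || stats::sd(b) == 0) {
    return(list(statistic = NA_real_, p_value = NA_real_,
                permutations = permutations, degenerate = TRUE))
  }
  obs <- stats::cor(a, b)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed) %% .Machine$integer.max)
  count <- 0L
  for (k in seq_len(permutations)) {
    p <- sample.int(n)
    bp <- B[p, p][ut]
    if (stats::sd(bp) == 0) next
    if (stats::cor(a, bp) >= obs - 1e-12) count <- count + 1L
  }
  list(statistic = obs, p_value = (1 + count) / (1 + permutations),
       permutations = permutations, degenerate = FALSE)
}

#' Select the best-matching fusion model for a sample
#'
#' Computes the sample's pooled caller-caller distance matrix (per model
#' metric, restricted to the callers the sample and model share) and orders
#' the candidate models by their Mantel statistic against each model's
#' stored caller-caller matrix. The model with the highest statistic is
#' returned together with a diagnostics report; a divergence warning is
#' flagged when the best model's permutation p-value exceeds
#' `divergence_p` (guidance only, never a hard stop).
#'
#' @param models list of `sv_fusion_model` objects.
#' @param observation the new sample as an [sv_observation()].
#' @param permutations,seed passed to [mantel_test()].
#' @param divergence_p p-value threshold for the divergence warning.
#' @return list with `model` (the selected model), `index`, and `report`
#'   (per-model statistic/p, `chosen`, `divergent` flag).
#' @export
select_model <- function(models, observation, permutations = 999, seed = 1L,
                         divergence_p = 0.05) {
  if (!length(models)) stop_data("no models supplied")
  sample_ids <- as.character(obs_caller_ids(observation))
  rows <- lapply(seq_along(models), function(k) {
    m <- models[[k]]
    shared <- intersect(as.character(m$caller_ids), sample_ids)
    if (length(shared) < 2) {
      return(list(statistic = NA_real_, p_value = NA_real_,
                  shared = length(shared)))
    }
    if (length(shared) < length(m$caller_ids)) {
      svf_log(1L, "model ", k, ": sample missing caller(s) ",
              paste(setdiff(as.character(m$caller_ids), shared),
                    collapse = ","), "; rows dropped")
    }
    obs_sub <- sv_observation(observation$sample_id,
                              observation$callsets[shared])
    Ds <- pooled_distance_matrix(list(obs_sub), metric = m$metric)
    Dm <- m$dist_cc[shared, shared]
    mt <- mantel_test(Ds, Dm, permutations = permutations, seed = seed)
    list(statistic = mt$statistic, p_value = mt$p_value,
         shared = length(shared), degenerate = isTRUE(mt$degenerate))
  })
  stats_v <- vapply(rows, function(r) r$statistic, 0)
  if (all(is.na(stats_v))) {
    if (all(vapply(rows, function(r) r$shared, 0) < 2)) {
      stop_data("no model shares >= 2 callers with the sample")
    }
    # degenerate statistics (e.g. 2-caller matrices): fall back to first model
    best <- 1L
  } else {
    best <- which.max(stats_v)
  }
  divergent <- !is.na(rows[[best]]$p_value) &&
    rows[[best]]$p_value > divergence_p
  if (divergent) {
    svf_log(1L, "divergence warning: best model Mantel p = ",
            signif(rows[[best]]$p_value, 3), " > ", divergence_p,
            "; model may not fit this data")
  }
  list(model = models[[best]], index = best,
       report = list(models = rows, chosen = best, divergent = divergent))
}
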