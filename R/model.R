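MODEL_SCHEMA <- "svfusion-model"
MODEL_VERSION <- 1L

#' Train a fusion model
#'
#' For every (sv_type, size-bin) partition with training data, computes the
#' pooled weighted distance matrix including truth, the full powerset of
#' group expectations, and the fitted expectation cutoff; globally, estimates
#' per-caller breakpoint spreads and the pooled caller-caller distance matrix
#' used for model diagnostics. Training is deterministic given its inputs
#' and invariant to the order of the observations.
#'
#' Partitions with no calls on any side in any observation are omitted from
#' the model ("empty marker"): during discovery such partitions contribute no
#' calls.
#'
#' @param observations list of [sv_observation()], all with truth and the
#'   same caller index.
#' @param weights positive per-observation weights (default 1).
#' @param bins bin scheme, see [default_bins()].
#' @param metric training metric, `"J"` (default) or `"F1"`.
#' @param filter apply [standard_filter()] to all callsets first.
#' @param mask optional mask intervals applied to caller callsets (not truth)
#'   via [apply_mask()].
#' @param mask_threshold overlap fraction for [apply_mask()].
#' @param search cutoff search strategy, see [fit_cutoff()].
#' @return An object of class `sv_fusion_model`.
#' @export
train_model <- function(observations, weights = NULL, bins = default_bins(),
                        metric = "J", filter = TRUE, mask = NULL,
                        mask_threshold = 0.5,
                        search = "exhaustive") {
  if (!length(observations)) stop_data("no training observations")
  validate_bins(bins)
  ids <- obs_caller_ids(observations[[1]])
  for (o in observations) {
    if (is.null(o$truth)) stop_data("training requires truth in every observation")
    if (!identical(obs_caller_ids(o), ids)) {
      stop_data("mixed caller sets across observations")
    }
  }
  weights <- weights %||% rep(1, length(observations))
  # deterministic ordering regardless of input order
  ord <- order(vapply(observations, function(o) o$sample_id, ""))
  observations <- observations[ord]
  weights <- weights[ord]
  prep <- lapply(observations, function(o) {
    sets <- o$callsets
    if (filter) sets <- lapply(sets, standard_filter)
    if (!is.null(mask)) sets <- lapply(sets, apply_mask, mask, mask_threshold)
    truth <- if (filter) standard_filter(o$truth) else o$truth
    sv_observation(o$sample_id, sets, truth)
  })
  # partition everything once
  parts <- lapply(prep, function(o) {
    list(callers = lapply(o$callsets, partition_callset, bins),
         truth = partition_callset(o$truth, bins))
  })
  all_keys <- sort(unique(unlist(lapply(parts, function(p) {
    c(unlist(lapply(p$callers, names), use.names = FALSE), names(p$truth))
  }))))
  empty_cs <- function(id, sid) sv_callset(caller_id = id, sample_id = sid)
  partitions <- list()
  for (key in all_keys) {
    obs_sets <- lapply(seq_along(prep), function(y) {
      sets <- lapply(as.character(ids), function(id) {
        parts[[y]]$callers[[id]][[key]] %||%
          empty_cs(as.integer(id), prep[[y]]$sample_id)
      })
      names(sets) <- as.character(ids)
      sets
    })
    truth_sets <- lapply(seq_along(prep), function(y) {
      parts[[y]]$truth[[key]] %||% empty_cs(0L, prep[[y]]$sample_id)
    })
    key_obs <- lapply(seq_along(prep), function(y) {
      sv_observation(prep[[y]]$sample_id, obs_sets[[y]], truth_sets[[y]])
    })
    D <- pooled_distance_matrix(key_obs, weights, metric = metric,
                                include_truth = TRUE)
    expectations <- all_group_expectations(D)
    fit <- fit_cutoff(obs_sets, truth_sets, expectations,
                      weights = weights, metric = metric, search = search)
    n_calls <- sum(vapply(obs_sets, function(s) sum(vapply(s, nrow, 0L)), 0L))
    partitions[[key]] <- list(expectation = expectations,
                              alpha = fit$alpha,
                              distance = fit$distance,
                              n_calls = n_calls)
  }
  spreads <- estimate_breakpoint_spreads(prep)
  spreads <- lapply(spreads, function(s) s[c("sigma_l", "sigma_r", "n")])
  dist_cc <- pooled_distance_matrix(prep, weights, metric = metric,
                                    include_truth = FALSE)
  structure(list(schema = MODEL_SCHEMA, version = MODEL_VERSION,
                 metric = metric, caller_ids = as.integer(ids),
                 bins = bins, partitions = partitions, spreads = spreads,
                 dist_cc = dist_cc,
                 meta = list(samples = vapply(prep, function(o) o$sample_id, ""),
                             weights = weights,
                             masked = !is.null(mask))),
            class = "sv_fusion_model")
}

#' @export
print.sv_fusion_model <- function(x, ...) {
  cat(sprintf(paste0("<sv_fusion_model> %d callers, %d trained partitions, ",
                     "metric %s, %d training samples\n"),
              length(x$caller_ids), length(x$partitions), x$metric,
              length(x$meta$samples)))
  invisible(x)
}

#' Save a fusion model to versioned JSON
#'
#' @param model an `sv_fusion_model`.
#' @param path output path.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "sv_fusion_model"))
  obj <- list(
    schema = model$schema, version = model$version, metric = model$metric,
    caller_ids = model$caller_ids, bins = model$bins,
    partitions = lapply(model$partitions, function(p) {
      list(expectation = as.list(p$expectation), alpha = p$alpha,
           distance = p$distance, n_calls = p$n_calls)
    }),
    spreads = model$spreads,
    dist_cc = list(ids = rownames(model$dist_cc),
                   matrix = unname(apply(model$dist_cc, 1, as.list,
                                         simplify = FALSE))),
    meta = model$meta)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Load a fusion model from JSON
#'
#' @param path path to a file written by [save_model()].
#' @return An `sv_fusion_model`.
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stop_data("model file not found: ", path)
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(obj$schema, MODEL_SCHEMA)) {
    stop_data("not a svfusion model file: ", path)
  }
  if (!identical(as.integer(obj$version), MODEL_VERSION)) {
    stop_data("unsupported model version ", obj$version,
              " (this build reads version ", MODEL_VERSION, ")")
  }
  ids <- as.character(unlist(obj$dist_cc$ids))
  m <- do.call(rbind, lapply(obj$dist_cc$matrix, function(r)
    as.numeric(unlist(r))))
  dimnames(m) <- list(ids, ids)
  attr(m, "metric") <- obj$metric
  structure(list(
    schema = obj$schema, version = as.integer(obj$version),
    metric = obj$metric,
    caller_ids = as.integer(unlist(obj$caller_ids)),
    bins = lapply(obj$bins, function(e) as.numeric(unlist(e))),
    partitions = lapply(obj$partitions, function(p) {
      list(expectation = unlist(p$expectation), alpha = as.numeric(p$alpha),
           distance = if (is.null(p$distance)) NA_real_
                      else as.numeric(p$distance),
           n_calls = as.integer(p$n_calls))
    }),
    spreads = lapply(obj$spreads, function(s) {
      list(sigma_l = as.numeric(s$sigma_l), sigma_r = as.numeric(s$sigma_r),
           n = as.integer(s$n))
    }),
    dist_cc = m,
    meta = list(samples = as.character(unlist(obj$meta$samples)),
                weights = as.numeric(unlist(obj$meta$weights)),
                masked = isTRUE(obj$meta$masked))),
    class = "sv_fusion_model")
}

#' Export the per-partition expectation table as TSV
#'
#' One row per (partition, caller subset) with the subset's expectation
#' value, mirroring the shape of a per-bin E-value table.
#'
#' @param model an `sv_fusion_model`.
#' @param path output TSV path.
#' @export
export_expectation_table <- function(model, path) {
  rows <- do.call(rbind, lapply(names(model$partitions), function(key) {
    p <- model$partitions[[key]]
    data.frame(partition = key, callers = names(p$expectation),
               expectation = unname(p$expectation), alpha = p$alpha,
               stringsAsFactors = FALSE)
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
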