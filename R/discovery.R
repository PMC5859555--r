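# Discovery phase: apply a trained fusion model to a new sample.

#' Filter and fuse one partition of a new sample
#'
#' Projects the partition's callsets onto disjoint support segments, assigns
#' each segment its supporting set's trained expectation, discards segments
#' with expectation below the partition's fitted cutoff, and joins surviving
#' adjacent/overlapping segments into fused calls whose expectation is the
#' segment-length-weighted mean of the joined segments. Per-caller
#' contributing breakpoints (leftmost start / rightmost end of that caller's
#' calls inside the fused span) are recorded for breakpoint smoothing.
#'
#' @param partition_callsets named list caller id -> [sv_callset()] for one
#'   partition of the sample.
#' @param model an `sv_fusion_model`.
#' @param key partition key `"TYPE:bin"`.
#' @return data.frame of fused calls: `start`, `end`, `sv_type`,
#'   `expectation`, `support`, `key`, plus list-columns `cb_l`, `cb_r`
#'   (named per-caller contributing breakpoints).
#' @export
filter_and_fuse <- function(partition_callsets, model, key) {
  empty <- data.frame(start = numeric(0), end = numeric(0),
                      sv_type = character(0), expectation = numeric(0),
                      support = character(0), key = character(0),
                      stringsAsFactors = FALSE)
  empty$cb_l <- list()
  empty$cb_r <- list()
  part <- model$partitions[[key]]
  if (is.null(part)) {
    n <- sum(vapply(partition_callsets, nrow, 0L))
    if (n > 0) {
      svf_log(1L, "partition ", key, " absent from model; ", n,
              " call(s) dropped")
    }
    return(empty)
  }
  proj <- project_support(partition_callsets, part$expectation)
  proj <- proj[proj$expectation >= part$alpha, , drop = FALSE]
  fused <- fuse_segments(proj)
  if (nrow(fused) == 0) return(empty)
  sv_type <- parse_partition_key(key)$sv_type
  fused$sv_type <- sv_type
  fused$key <- key
  cb_l <- vector("list", nrow(fused))
  cb_r <- vector("list", nrow(fused))
  for (r in seq_len(nrow(fused))) {
    bl <- numeric(0)
    br <- numeric(0)
    for (id in names(partition_callsets)) {
      cs <- partition_callsets[[id]]
      if (nrow(cs) == 0) next
      hit <- cs$s_start <= fused$end[r] & cs$s_end >= fused$start[r]
      if (!any(hit)) next
      bl[id] <- min(cs$s_start[hit])
      br[id] <- max(cs$s_end[hit])
    }
    cb_l[[r]] <- bl
    cb_r[[r]] <- br
  }
  fused$cb_l <- cb_l
  fused$cb_r <- cb_r
  fused
}

#' Priority-merge fused partitions into one callset
#'
#' Within each sv_type, partitions are processed from the smallest size bin
#' to the largest; when an incoming call overlaps (shares at least one bp
#' with) an already-accepted call of the same type, the call with the lower
#' expectation is discarded in full. At equal expectation the
#' earlier-accepted (smaller-bin) call is kept. Cross-type overlaps coexist.
#'
#' @param fused_by_key named list, partition key -> fused-call data.frame
#'   from [filter_and_fuse()].
#' @return Single fused-call data.frame sorted by coordinate.
#' @export
priority_merge <- function(fused_by_key) {
  fused_by_key <- fused_by_key[vapply(fused_by_key, nrow, 0L) > 0]
  if (!length(fused_by_key)) {
    return(filter_and_fuse(list(), list(partitions = list()), "DEL:1"))
  }
  keys <- names(fused_by_key)
  info <- lapply(keys, parse_partition_key)
  types <- vapply(info, function(k) k$sv_type, "")
  bins <- vapply(info, function(k) k$bin, 0L)
  out <- list()
  for (ty in unique(types)) {
    acc <- NULL
    for (k in order(bins)[types[order(bins)] == ty]) {
      inc <- fused_by_key[[keys[k]]]
      for (r in seq_len(nrow(inc))) {
        if (is.null(acc) || nrow(acc) == 0) {
          acc <- inc[r, , drop = FALSE]
          next
        }
        ov <- which(acc$start <= inc$end[r] & acc$end >= inc$start[r])
        if (!length(ov)) {
          acc <- rbind(acc, inc[r, , drop = FALSE])
        } else if (all(acc$expectation[ov] < inc$expectation[r])) {
          acc <- rbind(acc[-ov, , drop = FALSE], inc[r, , drop = FALSE])
        }  # else: an accepted call with >= expectation wins; drop incoming
      }
    }
    out[[ty]] <- acc
  }
  res <- do.call(rbind, out)
  res <- res[order(res$start, res$end), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Smooth the breakpoints of a fused call
#'
#' With at least two contributing callers that have breakpoint-spread
#' estimates (>= 2 training overlaps), the smoothed left breakpoint is the
#' weighted combination of the contributing callers' left breakpoints, a
#' caller's weight being proportional to `1 - sigma_a / sum_b sigma_b`
#' (renormalized to sum to 1), so low-spread (historically precise) callers
#' dominate; when every eligible sigma is 0 the weights are equal, reducing
#' to the arithmetic mean. Right breakpoints are treated analogously.
#' Smoothed positions are rounded and clamped inside the call's evidence
#' span. With fewer than two eligible callers the call is unchanged.
#'
#' @param call one-row fused-call data.frame (with `cb_l`/`cb_r`).
#' @param spreads model breakpoint spreads (caller id -> sigma_l/sigma_r/n).
#' @return The call with `start`/`end` replaced by smoothed positions.
#' @export
smooth_breakpoints <- function(call, spreads) {
  smooth_side <- function(bps, side) {
    ids <- names(bps)
    elig <- ids[vapply(ids, function(id) {
      s <- spreads[[id]]
      !is.null(s) && s$n >= 2
    }, TRUE)]
    if (length(elig) < 2) return(NULL)
    sig <- vapply(elig, function(id) spreads[[id]][[side]], 0)
    w <- if (sum(sig) == 0) rep(1, length(elig)) else 1 - sig / sum(sig)
    if (sum(w) == 0) w <- rep(1, length(elig))
    w <- w / sum(w)
    round(sum(w * bps[elig]))
  }
  bl <- call$cb_l[[1]]
  br <- call$cb_r[[1]]
  sl <- smooth_side(bl, "sigma_l")
  sr <- smooth_side(br, "sigma_r")
  if (!is.null(sl)) call$start <- max(min(bl), min(sl, max(br)))
  if (!is.null(sr)) call$end <- min(max(br), max(sr, call$start))
  if (call$end < call$start) call$end <- call$start
  call
}

#' Apply a fusion model to one sample
#'
#' Full discovery pipeline: partition the sample's callsets with the model's
#' bin scheme, filter-and-fuse each partition at its trained cutoff,
#' priority-merge the partitions (smallest to largest bin), smooth
#' breakpoints, and return the sorted fused callset. Deterministic given the
#' model and input. The input is standard-filtered with the model's
#' conventions unless `filter = FALSE`.
#'
#' @param observation an [sv_observation()] (truth not required).
#' @param model an `sv_fusion_model`.
#' @param smooth apply breakpoint smoothing (default TRUE).
#' @param filter apply [standard_filter()] first.
#' @return data.frame of fused calls: `start`, `end`, `sv_type`,
#'   `expectation`, `support`, `key`.
#' @export
discover <- function(observation, model, smooth = TRUE, filter = TRUE) {
  stopifnot(inherits(model, "sv_fusion_model"))
  sets <- observation$callsets
  if (filter) sets <- lapply(sets, standard_filter)
  ids <- as.character(model$caller_ids)
  missing_ids <- setdiff(ids, names(sets))
  if (length(missing_ids)) {
    svf_log(1L, "sample lacks caller(s) ", paste(missing_ids, collapse = ","),
            "; treating as empty callsets")
    for (id in missing_ids) {
      sets[[id]] <- sv_callset(caller_id = as.integer(id),
                               sample_id = observation$sample_id)
    }
  }
  parts <- lapply(sets[ids], partition_callset, model$bins)
  keys <- sort(unique(unlist(lapply(parts, names), use.names = FALSE)))
  fused_by_key <- lapply(keys, function(key) {
    pc <- lapply(ids, function(id) {
      parts[[id]][[key]] %||% sv_callset(caller_id = as.integer(id),
                                         sample_id = observation$sample_id)
    })
    names(pc) <- ids
    filter_and_fuse(pc, model, key)
  })
  names(fused_by_key) <- keys
  fused_by_key <- fused_by_key[vapply(fused_by_key, nrow, 0L) > 0]
  if (!length(fused_by_key)) {
    out <- data.frame(start = numeric(0), end = numeric(0),
                      sv_type = character(0), expectation = numeric(0),
                      support = character(0), key = character(0),
                      stringsAsFactors = FALSE)
    return(out)
  }
  merged <- priority_merge(fused_by_key)
  if (smooth) {
    for (r in seq_len(nrow(merged))) {
      merged[r, ] <- smooth_breakpoints(merged[r, , drop = FALSE],
                                        model$spreads)
    }
    merged <- merged[order(merged$start, merged$end), , drop = FALSE]
    rownames(merged) <- NULL
  }
  merged$cb_l <- NULL
  merged$cb_r <- NULL
  merged
}

#' Convert fused discovery calls to a callset
#'
#' @param fused fused-call data.frame from [discover()].
#' @param sample_id sample identifier.
#' @param caller_id caller id to stamp on the fused calls (default 0).
#' @return An [sv_callset()].
#' @export
fused_to_callset <- function(fused, sample_id, caller_id = 0L) {
  sv_callset(fused$start, fused$end, fused$sv_type, caller_id, sample_id)
}
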