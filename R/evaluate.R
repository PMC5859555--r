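#' Evaluate a callset against a truth set
#'
#' Computes precision, recall, F1 and base-pair Jaccard overall and per
#' (sv_type, size-bin) partition.
#'
#' @param callset an [sv_callset()].
#' @param truth truth [sv_callset()].
#' @param bins bin scheme for the per-partition rows.
#' @param reciprocal_overlap optional reciprocal-overlap fraction for the
#'   event-based metrics.
#' @return data.frame with columns `partition`, `n_calls`, `n_truth`,
#'   `precision`, `recall`, `f1`, `jaccard`; first row is `overall`.
#' @export
evaluate_callset <- function(callset, truth, bins = default_bins(),
                             reciprocal_overlap = 0) {
  row_for <- function(label, cs, tr) {
    p <- precision(cs, tr, reciprocal_overlap)
    r <- recall(cs, tr, reciprocal_overlap)
    data.frame(partition = label, n_calls = nrow(cs), n_truth = nrow(tr),
               precision = p, recall = r, f1 = f1(p, r),
               jaccard = jaccard(cs, tr, type_match = TRUE),
               stringsAsFactors = FALSE)
  }
  pc <- partition_callset(callset, bins)
  pt <- partition_callset(truth, bins)
  keys <- sort(union(names(pc), names(pt)))
  empty <- function(cs) as_callset(cs[0, , drop = FALSE],
                                   caller_id_of(cs), sample_id_of(cs))
  rows <- lapply(keys, function(key) {
    row_for(key, pc[[key]] %||% empty(callset), pt[[key]] %||% empty(truth))
  })
  out <- rbind(row_for("overall", callset, truth), do.call(rbind, rows))
  rownames(out) <- NULL
  out
}
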