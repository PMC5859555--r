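SV_TYPES <- c("INS", "DEL", "DUP", "INV", "TRA")

#' Construct a callset
#'
#' A callset is the set of calls from one caller on one sample, held as a
#' data.frame with one row per call. Coordinates are 0-based inclusive
#' flattened positions (`s_start <= s_end`); the destination interval
#' (`d_start`, `d_end`) equals the source interval for non-translocation
#' calls. Rows are kept sorted by `(s_start, s_end)`.
#'
#' @param s_start,s_end numeric, 0-based inclusive flattened source interval.
#' @param sv_type character, one of INS, DEL, DUP, INV, TRA.
#' @param caller_id integer id of the producing caller.
#' @param sample_id sample identifier.
#' @param d_start,d_end destination interval (defaults to source).
#' @param a_seq alternate sequence text (INS), default "".
#' @param filter_value raw VCF FILTER text, default "PASS".
#' @return data.frame of class `sv_callset` with attributes `caller_id` and
#'   `sample_id`.
#' @export
sv_callset <- function(s_start = numeric(0), s_end = numeric(0),
                       sv_type = character(0), caller_id = 0L,
                       sample_id = "sample",
                       d_start = NULL, d_end = NULL,
                       a_seq = NULL, filter_value = NULL) {
  n <- length(s_start)
  s_start <- as.numeric(s_start)
  s_end <- as.numeric(s_end)
  sv_type <- as.character(sv_type)
  if (length(s_end) != n || length(sv_type) != n) {
    stop_data("s_start, s_end, sv_type must have equal length")
  }
  if (n && any(s_end < s_start)) stop_data("call with s_end < s_start")
  if (n && !all(sv_type %in% SV_TYPES)) {
    stop_data("unknown sv_type: ",
              paste(unique(setdiff(sv_type, SV_TYPES)), collapse = ","))
  }
  d_start <- if (is.null(d_start)) s_start else as.numeric(d_start)
  d_end <- if (is.null(d_end)) s_end else as.numeric(d_end)
  a_seq <- if (is.null(a_seq)) character(n) else as.character(a_seq)
  filter_value <- if (is.null(filter_value)) rep("PASS", n)
                  else as.character(filter_value)
  df <- data.frame(s_start = s_start, s_end = s_end, sv_type = sv_type,
                   d_start = d_start, d_end = d_end, a_seq = a_seq,
                   filter_value = filter_value, stringsAsFactors = FALSE)
  df <- df[order(df$s_start, df$s_end), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, caller_id = as.integer(caller_id),
            sample_id = as.character(sample_id),
            class = c("sv_callset", "data.frame"))
}

as_callset <- function(df, caller_id, sample_id) {
  sv_callset(df$s_start, df$s_end, df$sv_type, caller_id, sample_id,
             d_start = df$d_start, d_end = df$d_end, a_seq = df$a_seq,
             filter_value = df$filter_value)
}

caller_id_of <- function(cs) attr(cs, "caller_id")
sample_id_of <- function(cs) attr(cs, "sample_id")

call_sizes <- function(cs) {
  if (nrow(cs) == 0) return(numeric(0))
  cs$s_end - cs$s_start + 1
}

callset_intervals <- function(cs, type = NULL) {
  if (!is.null(type)) cs <- cs[cs$sv_type == type, , drop = FALSE]
  iv(cs$s_start, cs$s_end)
}

#' @export
print.sv_callset <- function(x, ...) {
  cat(sprintf("<sv_callset> caller %s, sample %s, %d calls\n",
              caller_id_of(x), sample_id_of(x), nrow(x)))
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 10))
  invisible(x)
}

#' Construct an observation (one sample's callsets plus optional truth)
#'
#' @param sample_id sample identifier shared by all callsets.
#' @param callsets list of [sv_callset()] objects, one per caller.
#' @param truth optional truth [sv_callset()].
#' @return An object of class `sv_observation` with the callsets keyed by
#'   caller id.
#' @export
sv_observation <- function(sample_id, callsets, truth = NULL) {
  if (!length(callsets)) stop_data("observation needs at least one callset")
  ids <- vapply(callsets, caller_id_of, 0L)
  samples <- vapply(callsets, sample_id_of, "")
  if (anyDuplicated(ids)) stop_data("duplicate caller ids in observation")
  if (!all(samples == sample_id)) {
    stop_data("all callsets must share sample_id '", sample_id, "'")
  }
  if (!is.null(truth) && sample_id_of(truth) != sample_id) {
    stop_data("truth callset sample_id mismatch")
  }
  callsets <- callsets[order(ids)]
  names(callsets) <- as.character(sort(ids))
  structure(list(sample_id = sample_id, callsets = callsets, truth = truth),
            class = "sv_observation")
}

obs_caller_ids <- function(obs) as.integer(names(obs$callsets))

#' @export
print.sv_observation <- function(x, ...) {
  cat(sprintf("<sv_observation> sample %s, %d callers%s\n", x$sample_id,
              length(x$callsets),
              if (is.null(x$truth)) "" else ", with truth"))
  invisible(x)
}

#' Default size-bin scheme
#'
#' Per SV type, an ordered vector of half-open size-bin edges in bp: a call of
#' size `s` falls in bin `k` when `edges[k] <= s < edges[k+1]`. The default
#' uses log-ish spacing over 50 bp - 100 Mbp for DEL/DUP/INV (and INS), so a
#' size of e.g. 2 kb lands in the [1 kb, 5 kb) bin.
#'
#' @return Named list, sv_type -> numeric edge vector.
#' @export
default_bins <- function() {
  edges <- c(50, 100, 250, 500, 1000, 5000, 10000, 50000, 100000, 1e6,
             100000001)
  list(DEL = edges, DUP = edges, INV = edges, INS = edges)
}

validate_bins <- function(bins) {
  for (ty in names(bins)) {
    e <- bins[[ty]]
    if (any(diff(e) <= 0)) stop_data("bin edges for ", ty, " not increasing")
    if (e[1] < 50) stop_data("first bin edge for ", ty, " must be >= 50")
    if (e[length(e)] < 1e8) {
      stop_data("last bin edge for ", ty, " must be >= 100,000,000")
    }
  }
  invisible(bins)
}

size_bin <- function(sizes, edges) {
  # half-open bins [e_k, e_{k+1}); returns NA outside [e_1, e_last)
  b <- findInterval(sizes, edges)
  b[b < 1 | b >= length(edges)] <- NA_integer_
  b
}

partition_key <- function(sv_type, bin) paste0(sv_type, ":", bin)

parse_partition_key <- function(key) {
  parts <- strsplit(key, ":", fixed = TRUE)[[1]]
  list(sv_type = parts[1], bin = as.integer(parts[2]))
}

#' Standard call filtering
#'
#' Retains calls with size >= `min_size`, sv_type in `types`, and a FILTER
#' value that is PASS, "." or empty; size-49 calls and translocations are
#' dropped under the defaults.
#'
#' @param callset an [sv_callset()].
#' @param min_size minimum size in bp (size = s_end - s_start + 1).
#' @param types allowed SV types.
#' @return Filtered [sv_callset()].
#' @export
standard_filter <- function(callset, min_size = 50,
                            types = c("DEL", "DUP", "INV")) {
  keep <- call_sizes(callset) >= min_size &
    callset$sv_type %in% types &
    callset$filter_value %in% c("PASS", ".", "")
  as_callset(callset[keep, , drop = FALSE],
             caller_id_of(callset), sample_id_of(callset))
}

#' Apply an exclusion mask to a callset
#'
#' Drops a call when the fraction of its span covered by the mask exceeds
#' `threshold` (default 0.5); surviving calls are left unmodified (no
#' clipping). Masking twice is a no-op.
#'
#' @param callset an [sv_callset()].
#' @param mask two-column matrix of sorted disjoint flattened intervals
#'   (0-based inclusive), e.g. from [read_bed_mask()].
#' @param threshold masked-bp / call-size fraction above which a call is
#'   removed.
#' @return Filtered [sv_callset()].
#' @export
apply_mask <- function(callset, mask, threshold = 0.5) {
  if (is.null(mask) || nrow(mask) == 0 || nrow(callset) == 0) return(callset)
  iv_validate_disjoint(mask, "mask intervals")
  ov <- iv_overlap_each(iv(callset$s_start, callset$s_end), mask)
  frac <- ov / call_sizes(callset)
  n_drop <- sum(frac > threshold)
  if (n_drop) svf_log(2L, "mask removed ", n_drop, " call(s)")
  as_callset(callset[frac <= threshold, , drop = FALSE],
             caller_id_of(callset), sample_id_of(callset))
}

#' Partition a callset by SV type and size bin
#'
#' Every call whose size lies inside its type's bin range appears in exactly
#' one partition; calls of types absent from `bins` or with out-of-range sizes
#' are assigned to no partition (counted and logged).
#'
#' @param callset an [sv_callset()] (already standard-filtered).
#' @param bins bin scheme as from [default_bins()].
#' @return Named list, partition key `"TYPE:bin"` -> [sv_callset()].
#' @export
partition_callset <- function(callset, bins = default_bins()) {
  validate_bins(bins)
  if (nrow(callset) == 0) return(list())
  sizes <- call_sizes(callset)
  keys <- rep(NA_character_, nrow(callset))
  for (ty in unique(callset$sv_type)) {
    sel <- callset$sv_type == ty
    if (!ty %in% names(bins)) next
    b <- size_bin(sizes[sel], bins[[ty]])
    keys[sel][!is.na(b)] <- partition_key(ty, b[!is.na(b)])
  }
  n_out <- sum(is.na(keys))
  if (n_out) svf_log(2L, n_out, " call(s) outside the bin scheme, dropped")
  out <- lapply(split(seq_len(nrow(callset))[!is.na(keys)], keys[!is.na(keys)]),
                function(idx) as_callset(callset[idx, , drop = FALSE],
                                         caller_id_of(callset),
                                         sample_id_of(callset)))
  out
}
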