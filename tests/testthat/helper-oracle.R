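# Literal base-pair-set oracles: every interval is expanded into an explicit
# vector of covered positions and metrics are computed with plain set
# algebra. Only usable on tiny genomes; the implementation under test never
# uses this route.

bp_set <- function(cs, type = NULL) {
  if (!is.null(type)) cs <- cs[cs$sv_type == type, , drop = FALSE]
  if (nrow(cs) == 0) return(numeric(0))
  unique(unlist(Map(seq, cs$s_start, cs$s_end)))
}

oracle_bp_intersection <- function(a, b, type_match = FALSE) {
  if (!type_match) return(length(intersect(bp_set(a), bp_set(b))))
  sum(vapply(intersect(unique(a$sv_type), unique(b$sv_type)), function(ty) {
    length(intersect(bp_set(a, ty), bp_set(b, ty)))
  }, 0))
}

oracle_jaccard <- function(a, b) {
  sa <- bp_set(a)
  sb <- bp_set(b)
  if (!length(sa) && !length(sb)) return(1)
  length(intersect(sa, sb)) / length(union(sa, sb))
}

oracle_precision <- function(c, truth) {
  if (nrow(c) == 0) return(1)
  hits <- vapply(seq_len(nrow(c)), function(i) {
    tb <- bp_set(truth, c$sv_type[i])
    length(intersect(seq(c$s_start[i], c$s_end[i]), tb)) > 0
  }, TRUE)
  mean(hits)
}

oracle_recall <- function(c, truth) oracle_precision(truth, c)

# random small callset on a flattened genome of `total` bp
random_callset <- function(n, total, caller_id = 1L, sample_id = "s",
                           types = "DEL", max_len = 200) {
  if (n == 0) return(sv_callset(caller_id = caller_id, sample_id = sample_id))
  s <- sample.int(total, n, replace = TRUE) - 1
  len <- sample.int(max_len, n, replace = TRUE)
  e <- pmin(s + len - 1, total - 1)
  sv_callset(s, e, sample(types, n, replace = TRUE), caller_id, sample_id)
}
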