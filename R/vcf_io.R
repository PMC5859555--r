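# VCF and BED input/output. Reading is backed by VariantAnnotation; writing
# emits VCF 4.2 text directly (symbolic ALT per type, SVTYPE/END/SVLEN INFO,
# plus SVEX/SVMETHOD on fused output). Internal coordinates are 0-based
# inclusive; VCF POS is 1-based and BED is 0-based half-open, converted at
# this boundary only.

first_or_na <- function(x) {
  # collapse readVcf's scalar-or-List INFO columns to one value per record
  if (is.null(x)) return(NULL)
  if (is.atomic(x)) return(x)
  vapply(as.list(x), function(v) {
    if (length(v) == 0 || all(is.na(v))) NA_real_ else as.numeric(v[[1]])
  }, 0)
}

#' Read an SV callset from a VCF file
#'
#' One call is produced per record with a resolvable SVTYPE (INFO SVTYPE or
#' symbolic ALT) and a derivable end position, resolved in this order: INFO
#' END; then POS + |SVLEN| - 1; then POS + len(REF) - 1 for a non-symbolic
#' ALT. Records that resolve to none, or that sit on contigs absent from the
#' genome, are skipped and counted (never silently guessed). Coordinates are
#' flattened: a record POS=100, END=199 becomes the 0-based inclusive
#' interval [99, 198] (plus the contig offset).
#'
#' @param path VCF 4.x file path.
#' @param caller_id integer id to stamp on the calls.
#' @param genome an [sv_genome()] covering the contigs of interest.
#' @param sample_id sample identifier (default: file base name).
#' @return An [sv_callset()]; attribute `skipped` counts skipped records.
#' @export
read_vcf <- function(path, caller_id, genome, sample_id = NULL) {
  if (!file.exists(path)) stop_data("cannot read VCF: ", path)
  sample_id <- sample_id %||% sub("\\.vcf(\\.gz)?$", "", basename(path))
  vcf <- VariantAnnotation::readVcf(path)
  n <- length(vcf)
  if (n == 0) {
    out <- sv_callset(caller_id = caller_id, sample_id = sample_id)
    attr(out, "skipped") <- 0L
    return(out)
  }
  rr <- SummarizedExperiment::rowRanges(vcf)
  chrom <- as.character(GenomicRanges::seqnames(rr))
  pos <- as.numeric(BiocGenerics::start(rr))
  ref <- as.character(VariantAnnotation::ref(vcf))
  alt_l <- VariantAnnotation::alt(vcf)
  alt <- vapply(as.list(alt_l), function(v) {
    if (length(v) == 0) NA_character_ else as.character(v)[1]
  }, "")
  info <- VariantAnnotation::info(vcf)
  svtype <- if ("SVTYPE" %in% colnames(info)) as.character(info$SVTYPE)
            else rep(NA_character_, n)
  symbolic <- !is.na(alt) & grepl("^<.+>$", alt)
  sym_type <- toupper(sub(":.*$", "", gsub("[<>]", "", alt)))
  svtype[is.na(svtype) & symbolic & sym_type %in% SV_TYPES] <-
    sym_type[is.na(svtype) & symbolic & sym_type %in% SV_TYPES]
  end1 <- if ("END" %in% colnames(info)) first_or_na(info$END)
          else rep(NA_real_, n)
  svlen <- if ("SVLEN" %in% colnames(info)) first_or_na(info$SVLEN)
           else rep(NA_real_, n)
  use_svlen <- is.na(end1) & !is.na(svlen) & abs(svlen) >= 1
  end1[use_svlen] <- pos[use_svlen] + abs(svlen[use_svlen]) - 1
  use_ref <- is.na(end1) & !symbolic & !is.na(ref) & nchar(ref) >= 1
  end1[use_ref] <- pos[use_ref] + nchar(ref[use_ref]) - 1
  filt <- VariantAnnotation::filt(vcf)
  on_genome <- chrom %in% genome$names
  ok <- on_genome & !is.na(svtype) & svtype %in% SV_TYPES & !is.na(end1)
  ok[ok] <- end1[ok] >= pos[ok] &
    end1[ok] <= genome$lengths[chrom[ok]]
  n_skip <- sum(!ok)
  if (n_skip) {
    svf_log(2L, "skipped ", n_skip, " record(s) in ", basename(path),
            " (off-genome contig, unresolvable type or end)")
  }
  s_start <- flatten_pos(genome, chrom[ok], pos[ok] - 1)
  s_end <- flatten_pos(genome, chrom[ok], end1[ok] - 1)
  a_seq <- ifelse(!symbolic[ok] & svtype[ok] == "INS", alt[ok], "")
  out <- sv_callset(s_start, s_end, svtype[ok], caller_id, sample_id,
                    a_seq = a_seq, filter_value = as.character(filt[ok]))
  attr(out, "skipped") <- n_skip
  out
}

vcf_header_lines <- function(genome, fused = FALSE) {
  c("##fileformat=VCFv4.2",
    paste0("##source=svfusion-", as.character(utils::packageVersion("svfusion"))),
    sprintf("##contig=<ID=%s,length=%.0f>", genome$names, genome$lengths),
    "##ALT=<ID=DEL,Description=\"Deletion\">",
    "##ALT=<ID=DUP,Description=\"Duplication\">",
    "##ALT=<ID=INV,Description=\"Inversion\">",
    "##ALT=<ID=INS,Description=\"Insertion\">",
    "##ALT=<ID=TRA,Description=\"Translocation\">",
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"Type of structural variant\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End position of the variant\">",
    "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"Length of the variant\">",
    if (fused) c(
      "##INFO=<ID=SVEX,Number=1,Type=Float,Description=\"Fusion model expectation of the supporting caller set\">",
      "##INFO=<ID=SVMETHOD,Number=.,Type=String,Description=\"Supporting caller ids\">"),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">")
}

#' Write a callset to a VCF 4.2 file
#'
#' Records carry SVTYPE, END and SVLEN INFO keys and a symbolic ALT per type;
#' optional per-call annotations add the fusion-specific SVEX (expectation)
#' and SVMETHOD (supporting caller ids) keys. Genotypes are emitted as the
#' "./1" placeholder. Reading the file back with [read_vcf()] reproduces the
#' interval/type content exactly.
#'
#' @param callset an [sv_callset()].
#' @param genome the [sv_genome()] used to unflatten coordinates.
#' @param path output path.
#' @param annotations optional data.frame with `svex` and/or `svmethod`
#'   columns, one row per call in callset order.
#' @export
write_vcf <- function(callset, genome, path, annotations = NULL) {
  fused <- !is.null(annotations)
  lines <- vcf_header_lines(genome, fused = fused)
  sample_name <- sample_id_of(callset)
  lines <- c(lines, paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                            "FILTER", "INFO", "FORMAT", sample_name),
                          collapse = "\t"))
  n <- nrow(callset)
  if (n > 0) {
    loc_s <- unflatten_pos(genome, callset$s_start)
    loc_e <- unflatten_pos(genome, callset$s_end)
    if (any(loc_s$chrom != loc_e$chrom)) {
      stop_data("call spans a contig boundary; cannot serialize")
    }
    sizes <- call_sizes(callset)
    svlen <- ifelse(callset$sv_type == "DEL", -sizes, sizes)
    info <- sprintf("SVTYPE=%s;END=%.0f;SVLEN=%.0f", callset$sv_type,
                    loc_e$pos + 1, svlen)
    if (fused) {
      if (!is.null(annotations$svex)) {
        info <- paste0(info, sprintf(";SVEX=%.6g", annotations$svex))
      }
      if (!is.null(annotations$svmethod)) {
        info <- paste0(info, ";SVMETHOD=", annotations$svmethod)
      }
    }
    filt <- ifelse(callset$filter_value %in% c("", "."), ".",
                   callset$filter_value)
    recs <- paste(loc_s$chrom, sprintf("%.0f", loc_s$pos + 1),
                  sprintf("svf_%d", seq_len(n)), "N",
                  sprintf("<%s>", callset$sv_type), ".", filt, info,
                  "GT", "./1", sep = "\t")
    lines <- c(lines, recs)
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Write fused discovery calls to VCF
#'
#' @param fused fused-call data.frame from [discover()].
#' @param genome an [sv_genome()].
#' @param path output path.
#' @param sample_id sample name for the VCF column.
#' @export
write_fused_vcf <- function(fused, genome, path, sample_id = "sample") {
  cs <- fused_to_callset(fused, sample_id)
  o <- order(fused$start, fused$end)
  write_vcf(cs, genome, path,
            annotations = data.frame(svex = fused$expectation[o],
                                     svmethod = fused$support[o],
                                     stringsAsFactors = FALSE))
}

#' Read a BED exclusion mask as flattened intervals
#'
#' BED intervals are 0-based half-open; they are flattened against the
#' genome, converted to the internal 0-based inclusive convention, and
#' merged (overlapping or abutting intervals become one). Intervals on
#' contigs absent from the genome are skipped with a logged count.
#'
#' @param path BED3+ file path.
#' @param genome an [sv_genome()].
#' @return Two-column matrix of sorted disjoint intervals.
#' @export
read_bed_mask <- function(path, genome) {
  if (!file.exists(path)) stop_data("cannot read BED: ", path)
  if (file.size(path) == 0) return(iv_empty())
  gr <- tryCatch(rtracklayer::import(path, format = "bed"),
                 error = function(e) {
                   stop_data("malformed BED file ", path, ": ",
                             conditionMessage(e))
                 })
  if (length(gr) == 0) return(iv_empty())
  chrom <- as.character(GenomicRanges::seqnames(gr))
  keep <- chrom %in% genome$names
  if (any(!keep)) {
    svf_log(2L, "skipped ", sum(!keep), " mask interval(s) on unknown contigs")
  }
  if (!any(keep)) return(iv_empty())
  # rtracklayer imports BED as 1-based inclusive ranges
  s <- flatten_pos(genome, chrom[keep],
                   as.numeric(BiocGenerics::start(gr)[keep]) - 1)
  e <- flatten_pos(genome, chrom[keep],
                   as.numeric(BiocGenerics::end(gr)[keep]) - 1)
  iv_merge(iv(s, e))
}
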