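#' Flattened genome coordinate system
#'
#' A genome is an ordered set of contigs with lengths. Concatenating the
#' contigs end-to-end yields a single linear ("flattened") coordinate space in
#' which all calls are represented internally: position 0 is the first base of
#' the first contig. Coordinates are stored as doubles so that multi-Gbp
#' genomes (beyond the 32-bit integer range) are representable exactly
#' (doubles are exact up to 2^53).
#'
#' @param names character vector of contig names (unique).
#' @param lengths numeric vector of contig lengths in bp (all > 0).
#' @return An object of class `sv_genome` with fields `names`, `lengths` and
#'   `offsets` (cumulative 0-based start offset of each contig).
#' @examples
#' g <- sv_genome(c("chr1", "chr2"), c(1000, 500))
#' flatten_pos(g, "chr2", 10)  # 1010
#' @export
sv_genome <- function(names, lengths) {
  names <- as.character(names)
  lengths <- as.numeric(lengths)
  if (length(names) != length(lengths) || length(names) == 0) {
    stop_data("genome needs matching non-empty contig names and lengths")
  }
  if (anyDuplicated(names)) stop_data("duplicate contig names in genome")
  if (any(!is.finite(lengths)) || any(lengths <= 0)) {
    stop_data("contig lengths must be positive and finite")
  }
  offsets <- cumsum(c(0, lengths[-length(lengths)]))
  names(offsets) <- names
  names(lengths) <- names
  structure(list(names = names, lengths = lengths, offsets = offsets,
                 total = sum(lengths)),
            class = "sv_genome")
}

#' @export
print.sv_genome <- function(x, ...) {
  cat(sprintf("<sv_genome> %d contigs, %.0f bp total\n",
              length(x$names), x$total))
  invisible(x)
}

#' Convert per-contig positions to flattened coordinates
#'
#' @param genome an [sv_genome()].
#' @param chrom character vector of contig names.
#' @param pos numeric vector of 0-based positions within the contig.
#' @return Numeric vector of 0-based flattened positions.
#' @export
flatten_pos <- function(genome, chrom, pos) {
  stopifnot(inherits(genome, "sv_genome"))
  chrom <- as.character(chrom)
  bad <- !(chrom %in% genome$names)
  if (any(bad)) {
    stop_data("contig(s) not in genome: ",
              paste(unique(chrom[bad]), collapse = ", "))
  }
  pos <- as.numeric(pos)
  if (any(pos < 0) || any(pos >= genome$lengths[chrom])) {
    stop_data("position outside contig bounds")
  }
  unname(genome$offsets[chrom] + pos)
}

#' Convert flattened coordinates back to (contig, position)
#'
#' Inverse of [flatten_pos()]: `unflatten_pos(g, flatten_pos(g, c, p))`
#' recovers `(c, p)` for every valid position.
#'
#' @param genome an [sv_genome()].
#' @param fpos numeric vector of 0-based flattened positions.
#' @return data.frame with columns `chrom` and `pos` (0-based within contig).
#' @export
unflatten_pos <- function(genome, fpos) {
  stopifnot(inherits(genome, "sv_genome"))
  fpos <- as.numeric(fpos)
  if (any(fpos < 0) || any(fpos >= genome$total)) {
    stop_data("flattened position outside genome")
  }
  idx <- findInterval(fpos, genome$offsets)
  data.frame(chrom = genome$names[idx],
             pos = fpos - unname(genome$offsets[idx]),
             stringsAsFactors = FALSE)
}

#' Read a genome from a two-column TSV of contig names and lengths
#'
#' @param path path to a tab-separated file, columns: contig name, length (bp).
#'   Lines starting with `#` are ignored.
#' @return An [sv_genome()].
#' @export
read_genome <- function(path) {
  if (!file.exists(path)) stop_data("genome file not found: ", path)
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          comment.char = "#", stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop_data("genome TSV needs two columns (name, length)")
  sv_genome(df[[1]], df[[2]])
}
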