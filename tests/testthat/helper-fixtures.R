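# Shared fixtures, built in code at test time.

toy_genome <- function() sv_genome(c("chr1", "chr2"), c(1e6, 5e5))

# write VCF text lines to a temp file; returns the path
write_vcf_text <- function(records, contigs = c(chr1 = 1e6, chr2 = 5e5)) {
  path <- tempfile(fileext = ".vcf")
  hdr <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%.0f>", names(contigs), contigs),
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"t\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"e\">",
    "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"l\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"g\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "s1"), collapse = "\t"))
  writeLines(c(hdr, records), path)
  path
}

vcf_rec <- function(chrom, pos, info, alt = "<DEL>", filter = "PASS",
                    ref = "N") {
  paste(chrom, pos, ".", ref, alt, ".", filter, info, "GT", "0/1",
        sep = "\t")
}

# cohort of complementary callers: caller k is (near-)perfect exactly in its
# own set of size bins and blind elsewhere; optional jitter and FP noise.
complementary_spec <- function(n_samples = 9, n_truth = 400, seed = 11,
                               jitter = 0, fp_rate = 0,
                               sens_on = 1, sens_off = 0) {
  edges <- default_bins()$DEL
  nb <- length(edges) - 1
  owner <- rep(1:4, length.out = nb)  # bin k owned by caller (k mod 4)
  prof <- lapply(1:4, function(cid) {
    sens <- ifelse(owner == cid, sens_on, sens_off)
    caller_profile(cid,
                   sensitivity = list(DEL = sens, DUP = sens, INV = sens),
                   fp_rate = fp_rate, sigma_l = jitter, sigma_r = jitter)
  })
  cohort_spec(genome = sv_genome(c("c1", "c2"), c(3e7, 2e7)),
              n_samples = n_samples, n_truth = n_truth,
              profiles = prof, seed = seed)
}

# the one-perfect-caller / FP-laden-caller training fixture: caller 1 equals
# truth; caller 2 is truth plus coordinate-disjoint false calls whose sizes
# fall in bins that hold no truth calls (FP sizes 5-9 kb vs truth 100-999 bp)
perfect_plus_fp_obs <- function(sample_id = "fx1", seed = 3) {
  set.seed(seed)
  n <- 40
  sizes <- sample(100:999, n, replace = TRUE)
  starts <- cumsum(20000 + sizes)  # widely spaced, trivially disjoint
  truth <- sv_callset(starts, starts + sizes - 1, rep("DEL", n), 0L,
                      sample_id)
  fp_sizes <- sample(5000:9000, 12, replace = TRUE)
  fp_starts <- max(starts) + cumsum(30000 + fp_sizes)
  c2 <- sv_callset(c(starts, fp_starts),
                   c(starts + sizes - 1, fp_starts + fp_sizes - 1),
                   rep("DEL", n + 12), 2L, sample_id)
  c1 <- sv_callset(starts, starts + sizes - 1, rep("DEL", n), 1L, sample_id)
  sv_observation(sample_id, list(c1, c2), truth)
}
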