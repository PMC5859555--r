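# Synthetic cohort generator: a truth SV set with a stated type/size
# distribution, plus per-caller corrupted callsets with per-(type, size-bin)
# sensitivity, false-positive injection, Gaussian breakpoint jitter and
# tunable pairwise caller correlation through shared false-positive pools.
# Everything is a pure function of (spec, master seed).

#' Describe one simulated caller's error profile
#'
#' @param caller_id integer caller id.
#' @param sensitivity recovery probability per truth call: a scalar, or a
#'   named list sv_type -> scalar or per-bin vector (recycled across that
#'   type's bins).
#' @param fp_rate expected false-positive calls per Mbp per SV type.
#' @param sigma_l,sigma_r Gaussian breakpoint jitter scale in bp
#'   (left/right).
#' @param pool optional shared false-positive pool id; callers with the same
#'   pool id draw their false positives from one pregenerated set and are
#'   therefore correlated.
#' @param size_distortion multiplicative distortion of reported call sizes
#'   applied through the right breakpoint (default 1 = none).
#' @return An object of class `sv_caller_profile`.
#' @export
caller_profile <- function(caller_id, sensitivity = 0.8, fp_rate = 0.5,
                           sigma_l = 20, sigma_r = 20, pool = NA,
                           size_distortion = 1) {
  stopifnot(fp_rate >= 0, sigma_l >= 0, sigma_r >= 0, size_distortion > 0)
  structure(list(caller_id = as.integer(caller_id),
                 sensitivity = sensitivity, fp_rate = fp_rate,
                 sigma_l = sigma_l, sigma_r = sigma_r, pool = pool,
                 size_distortion = size_distortion),
            class = "sv_caller_profile")
}

sens_for <- function(profile, sv_type, bin, bins) {
  s <- profile$sensitivity
  if (is.numeric(s) && length(s) == 1) return(s)
  v <- s[[sv_type]]
  if (is.null(v)) return(0)
  if (length(v) == 1) return(v)
  nb <- length(bins[[sv_type]]) - 1
  v <- rep_len(v, nb)
  v[bin]
}

#' Describe a simulated cohort
#'
#' Defaults state the simulated world used throughout the test suite: a
#' 50 Mbp two-contig genome, 6 samples, 500 truth SVs per sample with a
#' 0.6/0.25/0.15 DEL/DUP/INV mix and log-uniform sizes over 50 bp - 100 kbp.
#'
#' @param genome an [sv_genome()] (default 2 contigs, 50 Mbp).
#' @param n_samples number of samples.
#' @param n_truth truth SV count per sample.
#' @param type_mix named proportions over SV types (sums to 1).
#' @param size_range log-uniform SV size range in bp.
#' @param profiles list of [caller_profile()] objects.
#' @param seed master seed (all randomness derives from it).
#' @param bins bin scheme used to resolve per-bin sensitivities.
#' @return An object of class `sv_cohort_spec`.
#' @export
cohort_spec <- function(genome = sv_genome(c("chr1", "chr2"), c(3e7, 2e7)),
                        n_samples = 6, n_truth = 500,
                        type_mix = c(DEL = 0.6, DUP = 0.25, INV = 0.15),
                        size_range = c(50, 1e5),
                        profiles = default_profiles(),
                        seed = 1L, bins = default_bins()) {
  if (n_samples <= 0 || n_truth <= 0) stop_data("counts must be positive")
  if (abs(sum(type_mix) - 1) > 1e-9) stop_data("type_mix must sum to 1")
  if (size_range[1] < 50) stop_data("minimum SV size is 50 bp")
  structure(list(genome = genome, n_samples = n_samples, n_truth = n_truth,
                 type_mix = type_mix, size_range = size_range,
                 profiles = profiles, seed = as.integer(seed), bins = bins),
            class = "sv_cohort_spec")
}

#' Default caller profiles for the simulated cohort
#'
#' Four callers with overlapping but distinct strengths: caller 1 is a
#' generalist; 2 favours small events; 3 favours large events; 4 is DEL-only
#' with tight breakpoints. Callers 3 and 4 share a false-positive pool, so
#' their false calls are correlated.
#'
#' @return list of [caller_profile()] objects.
#' @export
default_profiles <- function() {
  small_heavy <- c(0.95, 0.95, 0.9, 0.9, 0.8, 0.5, 0.3, 0.2, 0.1, 0.1)
  large_heavy <- rev(small_heavy)
  list(
    caller_profile(1, sensitivity = 0.8, fp_rate = 0.4,
                   sigma_l = 12, sigma_r = 12),
    caller_profile(2, sensitivity = list(DEL = small_heavy, DUP = small_heavy,
                                         INV = 0.6),
                   fp_rate = 0.8, sigma_l = 30, sigma_r = 30),
    caller_profile(3, sensitivity = list(DEL = large_heavy, DUP = large_heavy,
                                         INV = 0.5),
                   fp_rate = 0.6, sigma_l = 60, sigma_r = 60, pool = 1),
    caller_profile(4, sensitivity = list(DEL = 0.9),
                   fp_rate = 0.5, sigma_l = 5, sigma_r = 5, pool = 1))
}

rand_sizes <- function(n, size_range) {
  round(exp(stats::runif(n, log(size_range[1]), log(size_range[2] - 1))))
}

place_disjoint <- function(n, sizes, total, existing = iv_empty(),
                           max_tries = 50) {
  placed <- existing
  starts <- numeric(0)
  ends <- numeric(0)
  for (i in seq_len(n)) {
    ok <- FALSE
    for (tr in seq_len(max_tries)) {
      s <- floor(stats::runif(1, 0, total - sizes[i]))
      e <- s + sizes[i] - 1
      if (nrow(placed) == 0 ||
          iv_intersect_len(iv_merge(placed), iv(s, e)) == 0) {
        placed <- rbind(placed, iv(s, e))
        starts <- c(starts, s)
        ends <- c(ends, e)
        ok <- TRUE
        break
      }
    }
    if (!ok) {
      stop_data("could not place ", n, " disjoint events after ", max_tries,
                " tries each; use a larger genome or fewer/smaller events")
    }
  }
  list(start = starts, end = ends)
}

#' Simulate the truth callset for one sample
#'
#' Non-overlapping truth calls with the spec's type mix and log-uniform size
#' distribution; deterministic per (master seed, sample index).
#'
#' @param spec an [cohort_spec()].
#' @param sample_index 1-based sample index.
#' @return An [sv_callset()] with caller id 0.
#' @export
simulate_truth <- function(spec, sample_index) {
  set.seed(derive_seed(spec$seed, 1L, sample_index))
  n <- spec$n_truth
  types <- sample(names(spec$type_mix), n, replace = TRUE,
                  prob = spec$type_mix)
  sizes <- rand_sizes(n, spec$size_range)
  pos <- place_disjoint(n, sizes, spec$genome$total)
  sv_callset(pos$start, pos$end, types, caller_id = 0L,
             sample_id = sprintf("sim%02d", sample_index))
}

jitter_calls <- function(s, e, sigma_l, sigma_r, total, distortion = 1) {
  n <- length(s)
  js <- s + round(stats::rnorm(n, 0, sigma_l))
  je <- e + round(stats::rnorm(n, 0, sigma_r))
  if (distortion != 1) je <- js + round((je - js) * distortion)
  js <- pmax(0, pmin(js, total - 50))
  je <- pmin(total - 1, je)
  short <- je - js + 1 < 50
  je[short] <- js[short] + 49  # keep jittered calls in the supported domain
  list(s = js, e = je)
}

fp_pool_calls <- function(spec, sample_index, pool_id) {
  # pregenerated pool of candidate false positives shared by pool members
  set.seed(derive_seed(spec$seed, 3L, sample_index, pool_id))
  max_rate <- max(vapply(spec$profiles, function(p) {
    if (identical(p$pool, pool_id)) p$fp_rate else 0
  }, 0))
  mbp <- spec$genome$total / 1e6
  n_pool <- max(4L, ceiling(2 * max_rate * mbp * length(spec$type_mix)))
  types <- sample(names(spec$type_mix), n_pool, replace = TRUE,
                  prob = spec$type_mix)
  sizes <- rand_sizes(n_pool, spec$size_range)
  s <- floor(stats::runif(n_pool, 0, spec$genome$total - sizes))
  data.frame(s = s, e = s + sizes - 1, sv_type = types,
             stringsAsFactors = FALSE)
}

#' Simulate one caller's callset from a truth set
#'
#' Each truth call is emitted with the profile's (type, bin) sensitivity and
#' Gaussian breakpoint jitter; false positives are injected at the profile's
#' per-Mbp rate with sizes from the truth size distribution (so they land in
#' trained bins). Callers sharing a false-positive pool sample their false
#' calls from the same pregenerated set.
#'
#' @param truth truth [sv_callset()] from [simulate_truth()].
#' @param profile a [caller_profile()].
#' @param spec the [cohort_spec()].
#' @param sample_index 1-based sample index (seeds the caller stream).
#' @return An [sv_callset()] with the profile's caller id.
#' @export
simulate_caller <- function(truth, profile, spec, sample_index) {
  set.seed(derive_seed(spec$seed, 2L, sample_index, profile$caller_id))
  sizes <- call_sizes(truth)
  sens <- vapply(seq_len(nrow(truth)), function(i) {
    b <- size_bin(sizes[i], spec$bins[[truth$sv_type[i]]])
    if (is.na(b)) 0 else sens_for(profile, truth$sv_type[i], b, spec$bins)
  }, 0)
  keep <- stats::runif(nrow(truth)) < sens
  jt <- jitter_calls(truth$s_start[keep], truth$s_end[keep],
                     profile$sigma_l, profile$sigma_r, spec$genome$total,
                     profile$size_distortion)
  tp <- data.frame(s = jt$s, e = jt$e, sv_type = truth$sv_type[keep],
                   stringsAsFactors = FALSE)
  # false positives
  mbp <- spec$genome$total / 1e6
  n_fp <- stats::rpois(1, profile$fp_rate * mbp * length(spec$type_mix))
  if (n_fp > 0) {
    if (!is.na(profile$pool)) {
      pool <- fp_pool_calls(spec, sample_index, profile$pool)
      n_fp <- min(n_fp, nrow(pool))
      fp <- pool[sample.int(nrow(pool), n_fp), , drop = FALSE]
    } else {
      types <- sample(names(spec$type_mix), n_fp, replace = TRUE,
                      prob = spec$type_mix)
      fsz <- rand_sizes(n_fp, spec$size_range)
      fs <- floor(stats::runif(n_fp, 0, spec$genome$total - fsz))
      fp <- data.frame(s = fs, e = fs + fsz - 1, sv_type = types,
                       stringsAsFactors = FALSE)
    }
    tp <- rbind(tp, fp)
  }
  sv_callset(tp$s, tp$e, tp$sv_type, caller_id = profile$caller_id,
             sample_id = sample_id_of(truth))
}

#' Simulate a full cohort of observations
#'
#' @param spec a [cohort_spec()].
#' @param sample_indices which samples to generate (default all).
#' @return list of [sv_observation()] with truth, fully determined by the
#'   spec's master seed.
#' @export
simulate_cohort <- function(spec, sample_indices = seq_len(spec$n_samples)) {
  lapply(sample_indices, function(k) {
    truth <- simulate_truth(spec, k)
    sets <- lapply(spec$profiles, simulate_caller, truth = truth,
                   spec = spec, sample_index = k)
    sv_observation(sample_id_of(truth), sets, truth)
  })
}

#' Write a simulated cohort to per-caller VCFs
#'
#' Writes one VCF per caller per sample plus a truth VCF and a `spec.json`
#' manifest so the pipeline can be exercised through the CLI exactly as a
#' user would.
#'
#' @param spec a [cohort_spec()].
#' @param dir output directory (created if needed).
#' @return Invisibly, the manifest path.
#' @export
write_cohort <- function(spec, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  obs <- simulate_cohort(spec)
  samples <- list()
  for (o in obs) {
    entry <- list(truth = file.path(dir, paste0(o$sample_id, ".truth.vcf")))
    write_vcf(o$truth, spec$genome, entry$truth)
    entry$callers <- list()
    for (id in names(o$callsets)) {
      p <- file.path(dir, sprintf("%s.caller%s.vcf", o$sample_id, id))
      write_vcf(o$callsets[[id]], spec$genome, p)
      entry$callers[[id]] <- p
    }
    samples[[o$sample_id]] <- entry
  }
  gpath <- file.path(dir, "genome.tsv")
  utils::write.table(data.frame(spec$genome$names, spec$genome$lengths),
                     gpath, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  manifest <- file.path(dir, "spec.json")
  jsonlite::write_json(list(genome = gpath, seed = spec$seed,
                            samples = samples),
                       manifest, auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
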