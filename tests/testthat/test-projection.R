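test_that("projection decomposes overlapping calls into support segments", {
  a <- sv_callset(0, 99, "DEL", 1L, "s")
  b <- sv_callset(50, 149, "DEL", 2L, "s")
  e <- c("1" = 0.8, "2" = 0.6, "1,2" = 0.12)
  seg <- project_support(list("1" = a, "2" = b), e)
  expect_equal(seg$start, c(0, 50, 100))
  expect_equal(seg$end, c(49, 99, 149))
  expect_equal(seg$support, c("1", "1,2", "2"))
  expect_equal(seg$expectation, c(0.8, 0.12, 0.6))
  # single caller, single call
  one <- project_support(list("1" = a), e)
  expect_equal(nrow(one), 1)
  expect_equal(one$expectation, 0.8)
  # identical calls from three callers collapse to one segment
  tri <- project_support(list("1" = a,
                              "2" = sv_callset(0, 99, "DEL", 2L, "s"),
                              "3" = sv_callset(0, 99, "DEL", 3L, "s")))
  expect_equal(nrow(tri), 1)
  expect_equal(tri$support, "1,2,3")
  expect_error(project_support(list("1" = a, "2" = b), c("1" = 0.5)),
               "missing from expectation")
})

test_that("projection conserves base pairs and disjointness on random input", {
  set.seed(31)
  for (rep in 1:20) {
    sets <- lapply(1:3, function(id) {
      random_callset(sample(1:15, 1), 5000, id, max_len = 400)
    })
    names(sets) <- as.character(1:3)
    seg <- project_support(sets)
    # segments disjoint and sorted
    if (nrow(seg) > 1) {
      expect_true(all(seg$start[-1] > seg$end[-nrow(seg)]))
    }
    # union of segment lengths equals union coverage of all calls
    allm <- svfusion:::iv_merge(do.call(rbind, lapply(sets, function(cs)
      svfusion:::iv(cs$s_start, cs$s_end))))
    expect_equal(sum(seg$end - seg$start + 1),
                 svfusion:::iv_total_len(allm))
    # each segment's support is exact: every member covers it, no one else
    for (r in seq_len(nrow(seg))) {
      ids <- strsplit(seg$support[r], ",")[[1]]
      for (id in names(sets)) {
        m <- svfusion:::iv_merge(svfusion:::iv(sets[[id]]$s_start,
                                               sets[[id]]$s_end))
        cov <- svfusion:::iv_intersect_len(
          m, svfusion:::iv(seg$start[r], seg$end[r]))
        if (id %in% ids) expect_equal(cov, seg$end[r] - seg$start[r] + 1)
        else expect_equal(cov, 0)
      }
    }
  }
})

test_that("fuse_segments joins contiguous runs with length-weighted means", {
  seg <- data.frame(start = c(0, 50, 100, 300), end = c(49, 99, 149, 399),
                    support = c("1", "1,2", "2", "3"),
                    expectation = c(0.9, 0.3, 0.6, 0.5))
  f <- svfusion:::fuse_segments(seg)
  expect_equal(nrow(f), 2)
  expect_equal(f$start, c(0, 300))
  expect_equal(f$end, c(149, 399))
  expect_equal(f$expectation[1],
               (50 * 0.9 + 50 * 0.3 + 50 * 0.6) / 150)
  expect_equal(f$support, c("1,2", "3"))
})

test_that("fit_cutoff is optimal against a brute-force scan", {
  set.seed(91)
  for (rep in 1:20) {
    n_callers <- sample(3:4, 1)
    sid <- "fx"
    sets <- lapply(seq_len(n_callers), function(id) {
      random_callset(sample(3:10, 1), 20000, id, sample_id = sid,
                     max_len = 500)
    })
    names(sets) <- as.character(seq_len(n_callers))
    truth <- random_callset(6, 20000, 0L, sample_id = sid, max_len = 500)
    obs <- sv_observation(sid, sets, truth)
    D <- pooled_distance_matrix(list(obs), include_truth = TRUE)
    e <- all_group_expectations(D)
    fit <- fit_cutoff(list(sets), list(truth), e)
    # brute force: recompute the pooled distance for every candidate
    proj <- project_support(sets, e)
    bf <- vapply(fit$candidates, function(p) {
      keep <- proj$expectation >= p
      prop <- svfusion:::iv_merge(svfusion:::iv(proj$start[keep],
                                                proj$end[keep]))
      tm <- svfusion:::iv_merge(svfusion:::iv(truth$s_start, truth$s_end))
      inter <- svfusion:::iv_intersect_len(prop, tm)
      uni <- svfusion:::iv_total_len(prop) + svfusion:::iv_total_len(tm) -
        inter
      if (uni == 0) 0 else 1 - inter / uni
    }, 0)
    expect_equal(fit$distance, min(bf))
    # tie-break toward the largest optimal candidate
    expect_equal(fit$alpha, max(fit$candidates[bf == min(bf) + 1e-15 |
                                                 bf <= min(bf)]))
    # em refinement agrees with exhaustive search on small fixtures
    em <- fit_cutoff(list(sets), list(truth), e, search = "em")
    expect_equal(em$alpha, fit$alpha)
    expect_equal(em$distance, fit$distance)
  }
})

test_that("all callsets equal to truth: distance 0 at the largest cutoff", {
  sid <- "s"
  tr <- sv_callset(c(100, 5000), c(299, 5399), c("DEL", "DEL"), 0L, sid)
  sets <- lapply(1:3, function(id) sv_callset(tr$s_start, tr$s_end,
                                              tr$sv_type, id, sid))
  names(sets) <- as.character(1:3)
  D <- pooled_distance_matrix(list(sv_observation(sid, sets, tr)),
                              include_truth = TRUE)
  e <- all_group_expectations(D)
  fit <- fit_cutoff(list(sets), list(truth = tr), e)
  expect_equal(fit$distance, 0)
  # every segment is supported by the full set; the tie-break returns the
  # largest p that still keeps them
  expect_equal(fit$alpha, max(fit$candidates[fit$distances == 0]))
})

test_that("breakpoint spread estimation", {
  sid <- "s"
  tr <- sv_callset(c(1000, 5000, 9000), c(1999, 5999, 9999),
                   rep("DEL", 3), 0L, sid)
  # caller 1 exact; caller 2 offsets {-10, +10} left, {+5, +5} right
  c1 <- sv_callset(tr$s_start, tr$s_end, tr$sv_type, 1L, sid)
  c2 <- sv_callset(c(1000 - 10, 5000 + 10), c(1999 + 5, 5999 + 5),
                   c("DEL", "DEL"), 2L, sid)
  # caller 3 never overlaps truth
  c3 <- sv_callset(50000, 50999, "DEL", 3L, sid)
  obs <- sv_observation(sid, list(c1, c2, c3), tr)
  sp <- estimate_breakpoint_spreads(list(obs))
  expect_equal(sp[["1"]]$sigma_l, 0)
  expect_equal(sp[["1"]]$sigma_r, 0)
  expect_equal(sp[["1"]]$n, 3)
  expect_equal(sp[["2"]]$sigma_l, sd(c(-10, 10)))
  expect_equal(sp[["2"]]$sigma_r, sd(c(5, 5)))
  expect_equal(sp[["3"]]$n, 0)
  expect_equal(sp[["3"]]$sigma_l, 0)
})

test_that("spread matching picks the largest-overlap truth call", {
  sid <- "s"
  tr <- sv_callset(c(1000, 1900), c(1899, 2899), c("DEL", "DEL"), 0L, sid)
  # call overlaps both truth calls; 700 bp with the second, 200 with first
  c1 <- sv_callset(1700, 2599, "DEL", 1L, sid)
  sp <- estimate_breakpoint_spreads(
    list(sv_observation(sid, list(c1), tr)))
  expect_equal(sp[["1"]]$z_l, 1700 - 1900)
  expect_equal(sp[["1"]]$z_r, 2599 - 2899)
})

test_that("train produces a complete, order-invariant model", {
  spec <- cohort_spec(n_samples = 3, n_truth = 80,
                      genome = sv_genome("c1", 1e7), seed = 5)
  obs <- simulate_cohort(spec)
  m <- train_model(obs)
  expect_s3_class(m, "sv_fusion_model")
  expect_equal(m$caller_ids, 1:4)
  expect_gt(length(m$partitions), 0)
  for (p in m$partitions) {
    expect_length(p$expectation, 2^4 - 1)
    expect_true(all(p$expectation >= 0 & p$expectation <= 1))
    expect_true(p$alpha %in% c(0, p$expectation))
  }
  expect_length(m$spreads, 4)
  # permuting the observations yields the identical model
  m2 <- train_model(obs[c(3, 1, 2)])
  expect_equal(m, m2)
})

test_that("model save/load round-trips and rejects wrong versions", {
  spec <- cohort_spec(n_samples = 2, n_truth = 40,
                      genome = sv_genome("c1", 6e6), seed = 8)
  obs <- simulate_cohort(spec)
  m <- train_model(obs)
  path <- tempfile(fileext = ".json")
  save_model(m, path)
  m2 <- load_model(path)
  expect_equal(m2$caller_ids, m$caller_ids)
  expect_equal(m2$bins, m$bins)
  expect_equal(names(m2$partitions), names(m$partitions))
  for (key in names(m$partitions)) {
    expect_equal(m2$partitions[[key]]$expectation,
                 m$partitions[[key]]$expectation)
    expect_equal(m2$partitions[[key]]$alpha, m$partitions[[key]]$alpha)
  }
  expect_equal(m2$spreads, m$spreads)
  expect_equal(unclass(m2$dist_cc), unclass(m$dist_cc),
               ignore_attr = TRUE)
  # reloaded model drives identical discovery output
  test_obs <- simulate_cohort(spec, 2)[[1]]
  expect_equal(discover(test_obs, m2), discover(test_obs, m))
  # version / schema errors
  bad <- tempfile(fileext = ".json")
  jsonlite::write_json(list(schema = "svfusion-model", version = 99),
                       bad, auto_unbox = TRUE)
  expect_error(load_model(bad), "version")
  jsonlite::write_json(list(foo = 1), bad, auto_unbox = TRUE)
  expect_error(load_model(bad), "not a svfusion model")
})

test_that("perfect caller plus off-bin FP caller trains to a clean model", {
  obs <- perfect_plus_fp_obs()
  m <- train_model(list(obs))
  # truth bins: both callers carry the truth; alpha keeps their segments
  # FP bins: only FP calls; alpha drops everything (distance 0 to the empty
  # truth in those bins)
  fused <- discover(obs, m)
  out <- fused_to_callset(fused, "fx1")
  tr <- standard_filter(obs$truth)
  expect_equal(callset_distance(out, tr, "J"), 0)
  expect_equal(nrow(out), nrow(tr))
})
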