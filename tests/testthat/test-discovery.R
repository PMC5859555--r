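fake_model <- function(expectation, alpha, key = "DEL:2",
                       caller_ids = 1:2, spreads = NULL) {
  structure(list(schema = "svfusion-model", version = 1L, metric = "J",
                 caller_ids = caller_ids, bins = default_bins(),
                 partitions = setNames(
                   list(list(expectation = expectation, alpha = alpha,
                             distance = 0, n_calls = 0L)), key),
                 spreads = spreads %||% list(),
                 dist_cc = matrix(0, length(caller_ids), length(caller_ids),
                                  dimnames = list(as.character(caller_ids),
                                                  as.character(caller_ids))),
                 meta = list(samples = "x", weights = 1, masked = FALSE)),
            class = "sv_fusion_model")
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("filter_and_fuse splits runs at below-cutoff segments", {
  # three adjacent 100 bp calls with segment E = 0.9, 0.2, 0.8
  sid <- "s"
  a <- sv_callset(c(0, 200), c(99, 299), c("DEL", "DEL"), 1L, sid)
  b <- sv_callset(100, 199, "DEL", 2L, sid)
  e <- c("1" = 0.9, "2" = 0.2, "1,2" = 0.5)
  m <- fake_model(e, alpha = 0.5)
  out <- filter_and_fuse(list("1" = a, "2" = b), m, "DEL:2")
  expect_equal(nrow(out), 2)
  expect_equal(out$start, c(0, 200))
  expect_equal(out$end, c(99, 299))
  expect_equal(out$expectation, c(0.9, 0.9))
  # alpha = 0 keeps the whole union as one fused call
  m0 <- fake_model(e, alpha = 0)
  out0 <- filter_and_fuse(list("1" = a, "2" = b), m0, "DEL:2")
  expect_equal(nrow(out0), 1)
  expect_equal(out0$start, 0)
  expect_equal(out0$end, 299)
  expect_equal(out0$support, "1,2")
  expect_equal(out0$expectation, (100 * 0.9 + 100 * 0.2 + 100 * 0.9) / 300)
  # untrained partition drops everything
  out_missing <- filter_and_fuse(list("1" = a, "2" = b), m, "DUP:2")
  expect_equal(nrow(out_missing), 0)
})

test_that("fused calls record per-caller contributing breakpoints", {
  sid <- "s"
  a <- sv_callset(10, 250, "DEL", 1L, sid)
  b <- sv_callset(50, 300, "DEL", 2L, sid)
  m <- fake_model(c("1" = 0.8, "2" = 0.7, "1,2" = 0.4), alpha = 0)
  out <- filter_and_fuse(list("1" = a, "2" = b), m, "DEL:2")
  expect_equal(out$cb_l[[1]], c("1" = 10, "2" = 50))
  expect_equal(out$cb_r[[1]], c("1" = 250, "2" = 300))
})

test_that("priority merge keeps the higher-expectation call on overlap", {
  row <- function(s, e, ex, key) {
    d <- data.frame(start = s, end = e, sv_type = "DEL", expectation = ex,
                    support = "1", key = key, stringsAsFactors = FALSE)
    d$cb_l <- list(c("1" = s))
    d$cb_r <- list(c("1" = e))
    d
  }
  # small-bin call with E=0.9 overlapping large-bin call with E=0.4
  res <- priority_merge(list("DEL:1" = row(100, 199, 0.9, "DEL:1"),
                             "DEL:5" = row(150, 4999, 0.4, "DEL:5")))
  expect_equal(nrow(res), 1)
  expect_equal(res$expectation, 0.9)
  # large-bin call wins when its expectation is higher
  res2 <- priority_merge(list("DEL:1" = row(100, 199, 0.3, "DEL:1"),
                              "DEL:5" = row(150, 4999, 0.8, "DEL:5")))
  expect_equal(res2$expectation, 0.8)
  # equal expectations: the smaller-bin (earlier-accepted) call is kept
  res3 <- priority_merge(list("DEL:1" = row(100, 199, 0.5, "DEL:1"),
                              "DEL:5" = row(150, 4999, 0.5, "DEL:5")))
  expect_equal(res3$end, 199)
  # non-overlapping calls concatenate sorted
  res4 <- priority_merge(list("DEL:5" = row(5000, 10999, 0.4, "DEL:5"),
                              "DEL:1" = row(100, 199, 0.9, "DEL:1")))
  expect_equal(res4$start, c(100, 5000))
  # cross-type overlaps coexist
  inv <- row(150, 240, 0.1, "INV:1")
  inv$sv_type <- "INV"
  res5 <- priority_merge(list("DEL:1" = row(100, 199, 0.9, "DEL:1"),
                              "INV:1" = inv))
  expect_equal(nrow(res5), 2)
})

test_that("priority merge output is disjoint within each sv_type", {
  set.seed(13)
  mk <- function(n, key, lo, hi) {
    s <- sort(sample(seq(0, 49000, by = 7), n))
    e <- s + sample(lo:hi, n, replace = TRUE)
    d <- data.frame(start = s, end = e, sv_type = "DEL",
                    expectation = runif(n), support = "1", key = key,
                    stringsAsFactors = FALSE)
    d$cb_l <- as.list(s)
    d$cb_r <- as.list(e)
    d
  }
  res <- priority_merge(list("DEL:1" = mk(30, "DEL:1", 50, 99),
                             "DEL:3" = mk(20, "DEL:3", 250, 499),
                             "DEL:5" = mk(10, "DEL:5", 1000, 4999)))
  o <- order(res$start)
  expect_true(all(res$start[o][-1] > res$end[o][-nrow(res)]))
})

test_that("breakpoint smoothing weights follow the spread proportions", {
  spreads <- list("1" = list(sigma_l = 10, sigma_r = 10, n = 50),
                  "2" = list(sigma_l = 10, sigma_r = 10, n = 50),
                  "3" = list(sigma_l = 0, sigma_r = 0, n = 50),
                  "4" = list(sigma_l = 10, sigma_r = 10, n = 1))
  mk_call <- function(bl, br) {
    d <- data.frame(start = min(bl), end = max(br), sv_type = "DEL",
                    expectation = 0.5, support = paste(names(bl),
                                                       collapse = ","),
                    key = "DEL:2", stringsAsFactors = FALSE)
    d$cb_l <- list(bl)
    d$cb_r <- list(br)
    d
  }
  # equal sigmas -> arithmetic mean
  c1 <- mk_call(c("1" = 100, "2" = 140), c("1" = 300, "2" = 340))
  s1 <- smooth_breakpoints(c1, spreads)
  expect_equal(s1$start, 120)
  expect_equal(s1$end, 320)
  # a zero-sigma caller among sigma>0 callers dominates entirely
  c2 <- mk_call(c("1" = 100, "3" = 200), c("1" = 300, "3" = 400))
  s2 <- smooth_breakpoints(c2, spreads)
  expect_equal(s2$start, 200)
  expect_equal(s2$end, 400)
  # with three callers the weights are 1 - sigma/sum renormalized
  c3 <- mk_call(c("1" = 100, "2" = 160, "3" = 220),
                c("1" = 300, "2" = 360, "3" = 420))
  s3 <- smooth_breakpoints(c3, spreads)
  w <- (1 - c(10, 10, 0) / 20)
  w <- w / sum(w)
  expect_equal(s3$start, round(sum(w * c(100, 160, 220))))
  # single contributing caller: unchanged
  c4 <- mk_call(c("1" = 100), c("1" = 300))
  expect_equal(smooth_breakpoints(c4, spreads)$start, 100)
  # callers without spread data (n < 2) are ineligible
  c5 <- mk_call(c("1" = 100, "4" = 160), c("1" = 300, "4" = 360))
  expect_equal(smooth_breakpoints(c5, spreads)$start, 100)
})

test_that("mantel test: identity, permutation null, degeneracy", {
  set.seed(2)
  n <- 6
  m <- matrix(0, n, n)
  m[upper.tri(m)] <- runif(n * (n - 1) / 2)
  m <- m + t(m)
  r <- mantel_test(m, m, permutations = 199, seed = 4)
  expect_equal(r$statistic, 1)
  expect_lt(r$p_value, 0.05)
  # same seed reproduces exactly
  r2 <- mantel_test(m, m, permutations = 199, seed = 4)
  expect_identical(r, r2)
  # statistic/p against vegan's implementation on a noisy pair
  b <- m + matrix(rnorm(n * n, 0, 0.05), n, n)
  b <- (b + t(b)) / 2
  diag(b) <- 0
  r3 <- mantel_test(m, b, permutations = 999, seed = 9)
  vg <- vegan::mantel(as.dist(m), as.dist(b), permutations = 999)
  expect_equal(r3$statistic, unname(vg$statistic))
  expect_lt(abs(r3$p_value - vg$signif), 0.05)
  # 2x2 matrices have a single off-diagonal entry: flagged degenerate
  d2 <- matrix(c(0, 0.3, 0.3, 0), 2, 2)
  rd <- mantel_test(d2, d2, permutations = 99)
  expect_true(rd$degenerate)
  expect_true(is.na(rd$statistic))
  expect_error(mantel_test(m, d2), "different order")
  expect_error(mantel_test(m, m, permutations = 10), "99")
})

test_that("select_model picks the closer model and warns on divergence", {
  spec_a <- complementary_spec(n_samples = 3, n_truth = 150, seed = 21,
                               jitter = 10, fp_rate = 0.3,
                               sens_on = 0.95, sens_off = 0.05)
  spec_b <- cohort_spec(genome = spec_a$genome, n_samples = 3, n_truth = 150,
                        profiles = default_profiles(), seed = 22)
  m_a <- train_model(simulate_cohort(spec_a, 1:2))
  m_b <- train_model(simulate_cohort(spec_b, 1:2))
  held_a <- simulate_cohort(spec_a, 3)[[1]]
  sel <- select_model(list(m_b, m_a), held_a, permutations = 199, seed = 6)
  expect_equal(sel$index, 2)
  expect_false(is.null(sel$report))
  # single model passthrough
  sel1 <- select_model(list(m_a), held_a, permutations = 199, seed = 6)
  expect_equal(sel1$index, 1)
  # a sample sharing too few callers is rejected
  tiny <- sv_observation("t", list(sv_callset(0, 99, "DEL", 99L, "t")))
  expect_error(select_model(list(m_a), tiny), ">= 2 callers")
})

test_that("discover reproduces truth when callsets equal the truth", {
  sid <- "cl"
  set.seed(55)
  sizes <- sample(100:3000, 30)
  starts <- cumsum(sizes + 5000)
  tr <- sv_callset(starts, starts + sizes - 1,
                   sample(c("DEL", "DUP", "INV"), 30, TRUE), 0L, sid)
  sets <- lapply(1:3, function(id)
    sv_callset(tr$s_start, tr$s_end, tr$sv_type, id, sid))
  obs <- sv_observation(sid, sets, tr)
  model <- train_model(list(obs))
  fused <- discover(obs, model)
  out <- fused_to_callset(fused, sid)
  expect_equal(out$s_start, tr$s_start)
  expect_equal(out$s_end, tr$s_end)
  expect_equal(out$sv_type, tr$sv_type)
  # determinism
  expect_identical(discover(obs, model), fused)
  # empty input produces empty output
  empty_obs <- sv_observation(sid, lapply(1:3, function(id)
    sv_callset(caller_id = id, sample_id = sid)))
  expect_equal(nrow(discover(empty_obs, model)), 0)
})

test_that("fusion dominates single callers on a noisy complementary cohort", {
  spec <- complementary_spec(n_samples = 6, n_truth = 250, seed = 29,
                             jitter = 15, fp_rate = 0.2,
                             sens_on = 0.9, sens_off = 0.05)
  obs <- simulate_cohort(spec)
  model <- train_model(obs[1:4])
  held <- 5:6
  fused_f1 <- mean(vapply(held, function(k) {
    tr <- standard_filter(obs[[k]]$truth)
    out <- fused_to_callset(discover(obs[[k]], model), obs[[k]]$sample_id)
    f1(precision(out, tr), recall(out, tr))
  }, 0))
  best_single <- max(vapply(as.character(1:4), function(id) {
    mean(vapply(held, function(k) {
      tr <- standard_filter(obs[[k]]$truth)
      cs <- standard_filter(obs[[k]]$callsets[[id]])
      f1(precision(cs, tr), recall(cs, tr))
    }, 0))
  }, 0))
  expect_gte(fused_f1, best_single)
})

test_that("raising alpha never increases surviving segments", {
  set.seed(67)
  sets <- lapply(1:3, function(id)
    random_callset(8, 30000, id, sample_id = "s", max_len = 800))
  names(sets) <- as.character(1:3)
  tr <- random_callset(8, 30000, 0L, sample_id = "s", max_len = 800)
  D <- pooled_distance_matrix(list(sv_observation("s", sets, tr)),
                              include_truth = TRUE)
  e <- all_group_expectations(D)
  proj <- project_support(sets, e)
  alphas <- sort(unique(c(0, e, 1)))
  kept <- vapply(alphas, function(a) sum(proj$expectation >= a), 0)
  expect_true(all(diff(kept) <= 0))
})
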