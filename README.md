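# svfusion

Ensemble fusion of structural-variant (SV) callsets in R.

SV callers built on different evidence (read pairs, split reads, read
depth) have strong complementary biases by SV type and size, and callers
built on similar evidence make correlated mistakes. `svfusion` learns, from
a training cohort with a trusted truth set, an *additive group expectation*
model over the powerset of callers — stratified by SV type and size bin —
and applies it to new samples to produce one merged, filtered,
breakpoint-smoothed callset in VCF.

## The model in brief

All calls are represented on a flattened genome (chromosomes concatenated
with cumulative offsets; 0-based inclusive intervals) and partitioned by SV
type and size bin. Callset similarity is measured by base-pair Jaccard
`J = |a ∩ b| / |a ∪ b|` (precision/recall/F1 are also provided), pooled
over observations into a weighted distance matrix
`D(c_i, c_j, w) = Σ_y w_y δ(c_i^y, c_j^y) / Σ_y w_y` with `δ = 1 − q`. Every
nonempty caller subset `G` is scored per partition as

```
E(G) = ∏_{i∈G} [1 − D(c_i, c_t, w)] · max_{j∈G\{i}} D(c_j, c_i, w)
```

(performance against truth × dissimilarity to the most dissimilar group
mate; redundant callers annihilate, the empty max of a singleton is defined
as 1). Overlapping calls are projected onto maximal disjoint segments of
constant supporting-caller set, each scored by lookup `E(support)`; the
cutoff `α = argmin_{p∈{E(G)}} D(c_p, c_t, w)` is fitted per partition by
exhaustive search over the candidate grid, where proposal `c_p` keeps and
fuses segments with `E ≥ p`. Discovery applies the trained cutoffs,
priority-merges the partitions smallest-bin first (lower expectation loses
on same-type overlap), and smooths breakpoints with weights derived from
each caller's training breakpoint spread. A seeded Mantel permutation test
between the sample's and the model's caller–caller distance matrices
diagnoses model fit, and picks among several candidate models.

See `vignettes/svfusion-methods.Rmd` for the full account, including the
design decisions taken where the method description is ambiguous and the
known structural limits of the expectation formula.

## Worked example

Simulate a 4-caller cohort with known error structure, train on three
samples, fuse the held-out fourth:

```r
library(svfusion)
spec <- cohort_spec(genome = sv_genome(c("c1","c2"), c(1.5e7, 1e7)),
                    n_samples = 4, n_truth = 250, seed = 1)
obs   <- simulate_cohort(spec)
model <- train_model(obs[1:3])
model
#> <sv_fusion_model> 4 callers, 24 trained partitions, metric J, 3 training samples

fused <- discover(obs[[4]], model)
head(fused[, c("start","end","sv_type","expectation","support")], 3)
#>    start    end sv_type expectation support
#> 1   9753  63314     INV  0.08864355     1,3
#> 2 151031 196065     DEL  0.10683759     1,3
#> 3 287450 325684     DUP  0.17321788       2
```

Each fused call carries the model expectation of its supporting caller set
(`support` lists caller ids) — written to VCF as the `SVEX` and `SVMETHOD`
INFO keys. Scoring against the held-out truth:

```r
truth <- standard_filter(obs[[4]]$truth)
evaluate_callset(fused_to_callset(fused, "sim04"), truth)[1, ]
#>   partition n_calls n_truth precision recall    f1 jaccard
#> 1   overall     364     250     0.703  0.976 0.818   0.611
```

The fused callset recovers 97.6% of truth events at 70% event precision;
per-caller Jaccard against truth on the same sample ranges 0.33–0.73, so
fusion does not simply mirror one input. (On cohorts with by-construction
complementary callers the fused F1 strictly exceeds every single caller's —
see `tests/testthat/test-acceptance.R`, criterion 6.)

## Command line

```sh
svfusion simulate --out cohort/ --seed 7 --samples 6 --truth-count 500
svfusion train    --config cohort/spec.json --out model.json --report etab.tsv
svfusion apply    --model model.json --config cohort/spec.json \
                  --sample sim01 --out fused.vcf --diagnostics diag.json
svfusion evaluate --vcf fused.vcf --truth cohort/sim01.truth.vcf \
                  --genome cohort/genome.tsv
```

(`exec/svfusion` is installed with the package; the same entry point is
callable in-process as `svfusion_cli(c("train", ...))`.) Exit codes:
0 success, 2 usage/config error, 3 data error.

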