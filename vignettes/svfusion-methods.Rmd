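---
title: "Fusing structural-variant callsets with svfusion: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fusing structural-variant callsets with svfusion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(svfusion)
```

## The problem

Structural variants (SVs) — deletions, duplications, inversions, insertions
and translocations of 50 bp and more — are called from short-read data by
algorithms with strong, complementary biases: a read-pair caller may be
sensitive to mid-size deletions and blind to small ones, a split-read caller
the reverse, and two callers built on similar evidence will produce nearly
identical (and identically wrong) callsets. No single caller dominates, and
naive union or intersection of callsets trades precision against recall
wholesale.

`svfusion` learns, from a cohort where a trusted truth set exists, *which
combinations of callers to believe, for which SV type and size*, and applies
that model to new samples to emit a single merged, filtered,
breakpoint-smoothed callset.

## Data model

All calls live in a single linear coordinate space obtained by concatenating
the chromosomes with cumulative offsets ("flattened" coordinates, 0-based
inclusive intervals). Coordinates are held as doubles — exact for integers
up to $2^{53}$ — so multi-Gbp genomes do not hit the 32-bit limit of the
usual integer range containers; the interval primitives are consequently
implemented in-package and are verified against `IRanges` and a literal
base-pair-set oracle in the test suite.

A *callset* $c_i$ is the set of calls of caller $i$ on one sample; an
*observation* $S^y = \{c_1^y,\dots,c_n^y\}$ is one sample's callsets plus,
during training, a truth callset $c_t^y$. Calls are partitioned by the two
discriminating features — SV type and SV size — into bins (default
half-open edges 50, 100, 250, 500, 1000, 5000, 10⁴, 5·10⁴, 10⁵, 10⁶,
10⁸+1 bp for each type, so e.g. a 2 kb deletion falls in the [1 kb, 5 kb)
bin). Partitioning is fully discrete: every in-range call belongs to exactly
one bin. Standard filtering retains calls with size ≥ 50 bp, type in
{DEL, DUP, INV}, and FILTER in {PASS, ".", empty}.

## Performance metrics

For two callsets the package computes precision and recall (fraction of
calls in one set overlapped by at least one same-type call of the other),
their F-measure, and the base-pair Jaccard similarity
$J = |c_i \cap c_j| / |c_i \cup c_j|$ over base-pair sets. Each metric $q$
yields a distance $\delta = 1 - q$. Distances over a cohort are pooled as a
weighted mean per pair, giving the pooled distance matrix
$D(c_i, c_j, w) = \sum_y w_y\,\delta(c_i^y, c_j^y) / \sum_y w_y$, optionally
including the truth index $t$. Jaccard is the training default — base-pair
overlap is robust to one event being reported as several — and weights
default to 1 per observation.

Empty-set conventions: $J(\emptyset,\emptyset)=1$,
$\mathrm{prec}(\emptyset,\cdot)=1$, $\mathrm{rec}(\cdot,\emptyset)=1$, so a
sparse bin with no calls on either side registers as trivial agreement
rather than maximal disagreement. Overlap for the event metrics is any-bp by
default; a reciprocal-overlap fraction is available but not default.

## Additive group expectation

For each partition, every nonempty subset $G$ of the $n$ callers receives a
score from the pooled matrix $D$ (with truth index $t$):

$$E(G) = \prod_{i \in G}\Big( [1 - D(c_i, c_t, w)] \cdot
  \max_{j \in G \setminus \{i\}} D(c_j, c_i, w)\Big)$$

Each member contributes its performance against truth, times its
dissimilarity to the most dissimilar other member: high-performing but
mutually redundant callers are diminished, complementary ones promoted. For
singletons the maximum runs over an empty set and is **defined as 1**, so
$E(\{i\})$ is caller $i$'s plain performance — without this convention a
single-caller bin could never pass any cutoff. The product is
order-invariant; the enumeration is capped at $2^{12}-1$ subsets.

Two update forms extend a trained expectation table: with newly validated
observations the pooled matrix is simply recomputed over old and new
observations together; without truth for the new observations, the
truth-involving distances are kept from the prior while the caller–caller
distances are pooled over everything, which lowers the score of caller
pairs that have grown similar. Both reduce exactly to the base form when
there are no new observations.

### A structural consequence of the singleton convention

Because every factor is at most $1 - D(c_i,c_t,w) \le E(\{i\})$, the formula
implies $E(G) \le \min_{i \in G} E(\{i\})$: a multi-caller group can never
outscore the singleton score of any of its members. Consequently a segment
supported by a good caller *plus* a noisy one scores below the noisy
caller's own segments, and a cutoff cannot separate same-bin false-positive
segments of a caller from that caller's truth-supported overlaps with a
better caller. Per-partition fitting is what rescues filtering in practice:
noisy callers tend to dump their false calls into type/size bins where they
perform badly overall, and there the fitted cutoff learns to emit little or
nothing. The acceptance fixture for optimal filtering is built accordingly
(false calls in bins disjoint from the truth sizes), and the test suite
asserts the attainable direction of the complementarity property (a blind
partner annihilates the pair score; fusion still dominates single callers
because it unions each bin's best evidence).

## Cutoff fitting, projection and discovery

Within one partition the union of all call intervals is decomposed into
maximal disjoint *segments* of constant supporting-caller set; each segment
gets its supporting set's expectation by lookup. The fitted cutoff is

$$\alpha = \operatorname*{argmin}_{p \in \{E(G)\} \cup \{0\}}
  D(c_p, c_t, w)$$

where the proposal $c_p$ keeps segments with $E \ge p$ and fuses surviving
adjacent/overlapping segments. The search is exhaustive over the candidate
grid (exact; the grid has at most $2^n$ values); an iterative refinement
("em") over the sorted grid exists for large $n$ and must agree with the
exhaustive oracle on small fixtures. Ties break toward the **larger** cutoff
— the more conservative filter. Per-observation proposal distances are
pooled with the observation weights, matching the pooled matrix definition.
Partitions with no calls at all are omitted from the model and emit nothing
at discovery time (borrowing a neighbouring bin's cutoff was considered and
rejected as silently extrapolating the model).

Discovery applies the trained model to a new sample: partition with the
model's bins, project, drop segments below $\alpha$, fuse surviving runs
(expectation of a fused call = segment-length-weighted mean — "proportional
averaging" reads most plausibly as proportional to segment extent; a plain
mean is a one-line alternative), then merge partitions from the smallest
size bin to the largest. When two same-type calls overlap, the lower
expectation is discarded in full; at equal expectation the smaller-bin
(earlier-accepted) call is kept. Cross-type overlaps coexist — a deletion
may legitimately overlap an inversion.

## Breakpoint smoothing

During training, each caller's left/right breakpoint differentials against
matched truth calls (match = largest bp overlap, ties to the leftmost) give
spread estimates $\hat\sigma_{L,i}, \hat\sigma_{R,i}$ (sample SD; callers
with fewer than two matched calls are excluded). At discovery, a fused
call's breakpoint is re-estimated from the contributing callers' original
breakpoints with weight $\propto 1 - \hat\sigma_a / \sum_b \hat\sigma_b$,
renormalized. As printed, the source formula adds a weighted *sum of
positions* to an existing position, which is not dimensionally coherent; the
renormalized weighted combination implemented here matches the stated intent
(spread proportions as the weighting mechanism), reduces to the arithmetic
mean for equal spreads, and gives a zero-spread caller maximal weight.
Smoothed positions are clamped inside the call's evidence span. Note the
spread estimator is *not* robust to false-positive calls that graze truth
calls: such matches contribute differentials on the scale of the call sizes
and inflate $\hat\sigma$ far beyond the jitter scale. The parameter-recovery
experiment therefore uses jitter as the only breakpoint distortion.

## Model diagnostics

A stored pooled caller–caller distance matrix travels with each model. For
a new sample, a Mantel permutation test (Pearson correlation of
upper-triangle entries; $p = (1 + \#\{r_{perm} \ge r\})/(1+N)$, seeded)
compares the sample's caller-similarity structure with the model's; with
several candidate models the highest statistic wins, and $p > 0.05$ raises
a divergence *warning*, never a hard stop. Order-2 matrices have a single
off-diagonal entry and are flagged degenerate. Model selection is only
informative when the candidate models differ in correlation *structure*
(e.g. which callers share error modes); a cohort in which all pairwise
distances are near-constant carries no signal for the statistic.

## The synthetic cohort: what it emulates, what it does not

The generator states a world: a 50 Mbp two-contig genome, 6 samples,
500 non-overlapping truth SVs per sample, type mix 0.6/0.25/0.15
DEL/DUP/INV, log-uniform sizes over 50 bp–100 kb; callers with
per-(type, bin) sensitivity, Poisson false positives (per-Mbp rate, sizes
from the truth distribution so they land in trained bins), rounded Gaussian
breakpoint jitter truncated to keep calls ≥ 50 bp and on-genome, and
optional shared false-positive pools that make pool-mates' errors
correlated. Defaults were chosen once as a plausible desk-scale analogue of
a deep-coverage multi-caller cohort and are not tuned to test outcomes.

It does **not** emulate read-level artifacts, alignment context, complex or
nested events, genotype error, or the size/abundance distributions of any
particular study: a green test establishes that the estimators and the
pipeline behave as specified under known error structure, not that any
particular real-data performance number would be reproduced.

## Numerical and degenerate-input choices

* Internal coordinates 0-based inclusive; VCF POS (1-based) and BED
  (half-open) converted only at I/O boundaries. Size = end − start + 1.
* VCF end resolution order: INFO `END`, then `POS + |SVLEN| − 1`, then
  `POS + len(REF) − 1` for non-symbolic ALT; otherwise the record is
  skipped and counted, never guessed.
* The exclusion mask drops a call when more than half (configurable) of its
  span is masked, and applies to caller callsets only, not truth.
* Expectations are clamped to [0, 1]; Mantel permutation counting uses a
  1e−12 tolerance so exact ties count as exceedances.
* Genotypes are emitted as the `./1` placeholder — genotype inference is
  out of scope.
* All randomness (simulator, Mantel, CLI) derives from explicit seeds;
  training and discovery are deterministic and observation-order invariant.

## Known limitations

* The singleton-dominance property above limits what cutoff filtering can
  express within a bin; see that section.
* Breakpoint-spread estimation degrades under heavy false-positive overlap.
* Translocations are parsed but excluded by the standard filter; insertion
  handling is limited to interval bookkeeping.
* Model selection needs ≥ 3 shared callers for a non-degenerate Mantel
  statistic.
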