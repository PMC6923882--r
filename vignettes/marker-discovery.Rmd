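---
title: "Kernel MMD marker discovery and expression boundaries: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kernel MMD marker discovery and expression boundaries: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mmdmarker)
```

## The problem

Conventional differential-expression tests commit to a sampling model
(normal, negative binomial, ...) before looking at the data, and they
stop at a p-value: even a convincingly differential gene comes without
an expression cutoff usable for diagnosis. `mmdmarker` addresses both
points for a three-group tissue design — healthy normal, histologically
normal tissue adjacent to tumor (NAT), and tumor. NAT is treated as its
own group throughout: its transcriptome sits between healthy and tumor
tissue, and pooling it with either biases marker selection.

## The scoring model

For one gene and two groups X = {x1..xm}, Y = {y1..yn} drawn from
distributions p and q, the maximum mean discrepancy is the largest
difference in function means over the unit ball of an RKHS; with a
characteristic kernel it is zero iff p = q. The kernel form of the
squared discrepancy is estimated by the unbiased U-statistic

$$\widehat{MMD}^2_u = \tfrac{1}{m(m-1)}\sum_{i\neq j} k(x_i,x_j)
 + \tfrac{1}{n(n-1)}\sum_{i\neq j} k(y_i,y_j)
 - \tfrac{2}{mn}\sum_{i,j} k(x_i,y_j),$$

implemented in `mmd2_unbiased()` with the Gaussian kernel
$k(x,x') = \exp(-(x-x')^2/2\sigma^2)$. Because the diagonal terms are
excluded, the estimate is exactly unbiased for a fixed kernel, can dip
below zero under the null, and (for this kernel) never exceeds 2. No
distributional assumption on the expression values is needed; the cost
is $O((m+n)^2)$ per gene, trivially affordable for univariate per-gene
use even at cohort scale.

### Tunable parameters

- **Bandwidth σ** (expression units). Default: the median heuristic —
  the median nonzero pairwise absolute difference of the pooled
  two-group values, computed per gene and comparison
  (`median_heuristic_bandwidth()`). This adapts σ to each gene's scale,
  which matters because FPKM ranges span orders of magnitude across
  genes. A fixed global σ is available (`kernel_config("fixed", sigma)`)
  for reproducibility studies; note the median heuristic makes the
  kernel mildly data-dependent, so exact unbiasedness statements are
  made under a fixed σ.
- **Scale mode.** `"raw"` (default) reports MMD²\_u itself; `"m_scaled"`
  multiplies by the first group size, the convention behind
  sample-size-scaled test statistics whose magnitudes run into the
  hundreds on large cohorts. Group sizes are shared by all genes within
  a comparison, so the choice never changes a ranking.
- **Baselines.** `t_test_gene()` uses the pooled-variance two-sample
  t-test (`welch = TRUE` switches to Welch); `fold_change_gene()` is
  |log2(E1/E2)| of group means with a default pseudocount of 0 and a
  hard error on zero means — silent shrinkage of fold changes is worse
  than an explicit choice. Constant-vector degeneracies get documented
  conventions (equal constants: p = 1; unequal: p = 0) rather than NaN.

### Ranking and selection

Within one comparison genes receive fractional ranks (ties share the
mean of the spanned positions), so the rank sum is fixed at G(G+1)/2
and average ranks are comparable across comparisons with different
score scales. `average_rank()` supports both presets that matter in
practice: the tumor-focused pair (normal-vs-tumor, NAT-vs-tumor), since
detecting tumor is the clinically urgent task, and all three
comparisons for the final marker list. `top_k()` breaks average-rank
ties lexicographically on the gene id so a panel is reproducible.

## Expression boundaries

A binary boundary between two groups is found by sorting the pooled
expression values, taking midpoints between consecutive *distinct*
values as candidates (duplicated FPKM values would otherwise yield
zero-width intervals), and exhaustively maximizing the information gain

$$Gain(D,x) = Ent(D) - \sum_{v=1}^{2}\frac{|D^v|}{|D|}Ent(D^v),
\qquad Ent(D) = -\sum_k p_k \log_2 p_k.$$

The left child is {e ≤ x}; since candidates never coincide with data
values the choice of ≤ versus < is immaterial, but the convention is
fixed for serialization. Gain ties break toward the smallest threshold
(within a 1e−12 float tolerance) for determinism. When the classes are
perfectly separated the winning split is the midpoint of the gap, which
subsumes the common manual practice of using the gap's edge; the gain
then equals the parent entropy.

Three groups give two thresholds. `three_class_boundaries()` orders the
groups by median expression and solves the two *adjacent-pair* binary
problems. A joint exhaustive optimization of both thresholds is a
possible extension, but the adjacent-pair decomposition is simpler,
matches the interval structure markers display in practice (one group
low, one middle, one high), and makes each threshold interpretable as a
two-tissue boundary. Ordering by the data rather than a fixed tissue
sequence is deliberate: tumor-suppressed markers put tumor lowest,
while induced markers or NAT-peaking genes come out inverted. If the
two thresholds cross (possible for bimodal middle groups), the result
is flagged `monotone = FALSE` and returned as-is with a warning — never
silently reordered.

## Cross-validated evaluation

`cross_validate()` measures how well a selected panel distinguishes
tumor from all other samples (normal and NAT pooled as negatives).
Folds are stratified — with ~12% NAT samples an unstratified split can
easily produce single-class folds — and fully seeded. The classifier is
a 100-tree random forest with default hyperparameters, a deliberately
untuned reference model: the point is comparing gene panels, not
squeezing classifier performance. Both fold-averaged means (the
headline numbers) and pooled-count metrics are reported, since the two
aggregations differ slightly for imbalanced folds; any metric with a
zero denominator is reported as 0 with a degeneracy flag.

One caveat is reproduced on purpose and must be kept in mind: the panel
is selected on the full data *before* cross-validation, so the CV
metrics evaluate the selected genes, not the selection procedure; they
are optimistic about the full discovery-to-classifier pipeline.

## The synthetic-data generator

`simulate_expression()` provides ground truth no public cohort can:
which genes are differential and where the true class boundaries lie.
Null genes share one distribution across groups; DE genes receive
group-specific location shifts.

Choices, made once:

- **Baseline law**: lognormal, matching the right skew of FPKM data,
  with per-gene log-scale locations uniform on (0, 3) (FPKM roughly 1
  to 20) and within-group log-sd 0.5. Effects are applied on the log
  scale in within-group-sd units; a truncated-normal law (raw-scale
  effects) is available.
- **Default shape** (`default_study_spec()`): 500 genes, groups of
  75 normal / 12 NAT / 108 tumor — one fifth of the sample sizes of the
  large public lung cohorts this package targets, preserving their
  imbalance (NAT by far the smallest) — with 5% DE genes at effect
  size 2.
- **Ordering patterns** cycle 3:1:1 through normal-high (normal > NAT >
  tumor, the dominant marker profile), tumor-high (inverted) and
  NAT-high, so selection and boundary code face non-monotone group
  orders, which do occur among real markers.
- **Seeding**: each gene draws from its own substream derived from the
  master seed, so enlarging a simulation never perturbs earlier genes.
- **Truth record**: per-DE-gene population group means (data scale;
  exp(μ + s²/2) for the lognormal) and the midpoints between adjacent
  means — the targets boundary recovery is judged against.

What the simulator does **not** emulate: library-size and batch
effects, gene-gene correlation, zero inflation, count noise, and
outlier samples. Passing tests on it demonstrate correctness of the
algorithms and internal consistency of the pipeline — not that any
particular real-data marker list is right.

## Numerical conventions and edge cases

- Entropies use 0·log 0 := 0; gains are clamped only by construction
  (they lie in [0, Ent(D)] up to 1e−12 float slack, asserted in tests).
- The MMD estimator validates m, n ≥ 2 (the U-statistic denominators)
  and errors on an all-identical pooled sample, where the median
  heuristic is undefined.
- Negative MMD estimates are never clamped; rankings use signed values.
- Expression matrices must be finite and non-negative; missing values
  are a hard error with coordinates, not an imputation target.
- Problem sizes in the test-suite simulations (hundreds of genes,
  50-200 samples per group, 100-500 replicates for distributional
  checks) were chosen as the smallest at which the checked properties
  are comfortably non-marginal, keeping the default suite fast.

## Known limitations

- Univariate (per-gene) kernels only; no multivariate or linear-time
  MMD variants, and no permutation p-values — genes are ranked by
  score, not significance, so no multiple-testing correction applies.
- The boundary search emits at most two thresholds (three classes) and
  no MDL-style stopping rule or probability calibration.
- Selection-before-CV leakage, as discussed above.
- Functional interpretation of a panel (ontology or pathway enrichment)
  is out of scope; `top_genes.txt` from the pipeline is a plain gene
  list ready for external enrichment tools.

```{r session}
sessionInfo()
```
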