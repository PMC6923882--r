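# mmdmarker

Marker-gene discovery for three-group expression designs (healthy
normal, tumor-adjacent "NAT", and tumor tissue) using the kernel
two-sample statistic instead of a fixed parametric test, plus an
information-theoretic procedure that turns a selected marker into
concrete per-tissue expression cutoffs a clinician could apply.

## Who this is for

Analysts with an FPKM-scale gene-by-sample matrix and a sample-to-group
table who want (1) a ranking of genes by how differently they are
expressed between groups, without committing to a distributional
hypothesis, and (2) explicit expression-level boundaries separating the
groups for the selected markers — including when there is no clean gap
between the group distributions.

## The method

**Scoring.** For each gene and each pair of groups X = {x1..xm},
Y = {y1..yn}, the package computes the minimum-variance unbiased
estimator of the squared maximum mean discrepancy with a Gaussian
kernel k(x, x') = exp(−‖x−x'‖²/2σ²):

    MMD²_u = 1/(m(m−1)) Σ_{i≠j} k(xi, xj)
           + 1/(n(n−1)) Σ_{i≠j} k(yi, yj)
           − 2/(mn)     Σ_{i,j} k(xi, yj)

A larger score means a larger distributional difference; the U-statistic
form can be slightly negative under the null and is reported as-is.
Baselines: the pooled-variance two-sample t-test p-value and the fold
change |log2(E1/E2)| of group means.

**Selection.** Within each comparison, genes get fractional ranks
(rank 1 = strongest). A gene's average rank over a set of comparisons —
all three, or only the tumor-containing pair — orders the candidate
markers; the top k form the panel.

**Boundaries.** For a marker, the three groups are ordered by median
expression and each adjacent pair is split at the midpoint candidate
maximizing the information gain

    Gain(D, x) = Ent(D) − Σ_v |D^v|/|D| · Ent(D^v),  Ent(D) = −Σ p_k log2 p_k

yielding intervals of the form low: e ≤ t1, middle: t1 < e < t2,
high: e ≥ t2.

**Evaluation.** The selected panel's expression feeds a 100-tree random
forest classifying tumor vs all other samples under seeded stratified
10-fold cross-validation, reporting recall, F1, accuracy and Matthews
correlation coefficient.

## Worked example

```r
library(mmdmarker)

sim <- simulate_expression(default_study_spec(seed = 1))  # 500 genes,
# groups 75 normal / 12 NAT / 108 tumor, 25 true DE genes at effect 2 sd

tab  <- score_genes(sim$matrix, sim$labels, methods = c("mmd", "foldchange"))
avg  <- average_rank(tab, unique(tab$comparison), "mmd")
top  <- top_k(avg, 10)
sum(top %in% sim$truth$de_gene_ids)
#> [1] 10

cv <- cross_validate(sim$matrix[top, ], sim$labels, cv_config(k = 10, seed = 1))
cv
#> 10-fold stratified CV (random_forest, positive = tumor)
#> fold-averaged: recall 1.0000  F1 0.9957  accuracy 0.9947  MCC 0.9896
#> pooled-count:  recall 1.0000  F1 0.9954  accuracy 0.9949  MCC 0.9897

three_class_boundaries(sim$matrix, sim$labels, top[1])$intervals
#>    group    lower    upper
#> 1  tumor     -Inf  4.13749
#> 2    nat  4.13749 10.46739
#> 3 normal 10.46739      Inf
```

All ten selected genes are true spike-ins, the panel separates tumor
from non-tumor samples almost perfectly, and the recovered boundaries
bracket the simulated group locations. Real cohorts are noisier; see
the methods vignette for what the simulation does and does not emulate.

A command-line interface wrapping the same functions ships in
`inst/cli/mmdmarker.R` (`simulate`, `score`, `rank`, `boundary`,
`evaluate`, `run` subcommands).

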