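#' Two-sample t-test p-value for one gene
#'
#' Two-sided p-value for a difference in group mean expression.
#' Pooled-variance (equal variance) by default; Welch behind a flag.
#' Degenerate constant-vector genes get conventional values instead of
#' NaN: both groups constant and equal -> p = 1; both constant and
#' unequal -> p = 0.
#'
#' @param x,y Numeric vectors of length >= 2.
#' @param welch Use the Welch (unequal-variance) statistic.
#' @return p-value in \[0, 1\].
#' @export
t_test_gene <- function(x, y, welch = FALSE) {
  if (length(x) < 2L || length(y) < 2L) {
    stop("both groups need >= 2 samples", call. = FALSE)
  }
  if (stats::sd(x) == 0 && stats::sd(y) == 0) {
    return(if (mean(x) == mean(y)) 1 else 0)
  }
  stats::t.test(x, y, var.equal = !welch)$p.value
}

#' Absolute log2 fold change of group mean expression
#'
#' |log2((mean(x) + pseudocount) / (mean(y) + pseudocount))|, symmetric
#' under swapping groups.  The default pseudocount is 0, with a hard
#' error when a group mean is 0; set a positive pseudocount (1 is a
#' sensible value on FPKM scale) for genes silent in one group.
#'
#' @param x,y Numeric vectors (raw group values; means taken here).
#' @param pseudocount Non-negative value added to both means.
#' @return Non-negative fold change.
#' @export
fold_change_gene <- function(x, y, pseudocount = 0) {
  if (!is.numeric(pseudocount) || length(pseudocount) != 1L || pseudocount < 0) {
    stop("pseudocount must be a single non-negative number", call. = FALSE)
  }
  e1 <- mean(x) + pseudocount
  e2 <- mean(y) + pseudocount
  if (e1 == 0 || e2 == 0) {
    stop("a group mean (plus pseudocount) is 0; supply a positive pseudocount",
         call. = FALSE)
  }
  abs(log2(e1 / e2))
}

#' Define a pairwise group comparison
#'
#' @param group_a,group_b Distinct group tags.
#' @param name Label for the comparison (default `"a_vs_b"`).
#' @return A `comparison_spec` list.
#' @export
comparison_spec <- function(group_a, group_b,
                            name = paste0(group_a, "_vs_", group_b)) {
  if (identical(group_a, group_b)) {
    stop("comparison groups must differ", call. = FALSE)
  }
  structure(list(name = name, group_a = group_a, group_b = group_b),
            class = "comparison_spec")
}

#' The three canonical tissue comparisons
#'
#' Normal vs NAT, normal vs tumor, and NAT vs tumor, for the default
#' three-group design (normal / tumor-adjacent / tumor).
#'
#' @return List of three [comparison_spec()] objects.
#' @export
default_comparisons <- function() {
  list(comparison_spec("normal", "nat"),
       comparison_spec("normal", "tumor"),
       comparison_spec("nat", "tumor"))
}

#' Score one gene for one comparison
#'
#' Dispatches to the requested scorer on the gene's two group-restricted
#' value vectors.
#'
#' @param mat Expression matrix (genes x samples).
#' @param labels Named group labels.
#' @param gene Gene identifier.
#' @param comparison A [comparison_spec()].
#' @param method `"mmd"`, `"ttest"` or `"foldchange"`.
#' @param config [kernel_config()] used when `method = "mmd"`.
#' @param pseudocount Passed to [fold_change_gene()].
#' @param welch Passed to [t_test_gene()].
#' @return Scalar score (MMD^2 estimate, p-value, or |log2 FC|).
#' @export
score_gene <- function(mat, labels, gene, comparison,
                       method = c("mmd", "ttest", "foldchange"),
                       config = kernel_config(), pseudocount = 0,
                       welch = FALSE) {
  method <- match.arg(method)
  ts <- gene_two_sample(mat, labels, gene, comparison$group_a,
                        comparison$group_b)
  switch(method,
         mmd = mmd2_unbiased(ts$x, ts$y, config),
         ttest = t_test_gene(ts$x, ts$y, welch = welch),
         foldchange = fold_change_gene(ts$x, ts$y, pseudocount = pseudocount))
}

#' Fractional ranks of gene scores
#'
#' Rank 1 is the strongest signal.  Ties get the mean of the spanned
#' rank positions (fractional ranking), so the rank sum is always
#' G(G+1)/2 and average ranks stay comparable across comparisons.
#'
#' @param scores Named numeric vector of per-gene scores.
#' @param direction `"higher_is_stronger"` (MMD, fold change) or
#'   `"lower_is_stronger"` (p-values).
#' @return Named numeric vector of ranks.
#' @export
rank_genes <- function(scores,
                       direction = c("higher_is_stronger",
                                     "lower_is_stronger")) {
  direction <- match.arg(direction)
  bad <- names(scores)[!is.finite(scores)]
  if (length(bad) > 0L) {
    stop("non-finite score for gene(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  s <- if (direction == "higher_is_stronger") -scores else scores
  rank(s, ties.method = "average")
}

# Rank direction implied by each scoring method.
method_direction <- function(method) {
  switch(method,
         mmd = "higher_is_stronger",
         foldchange = "higher_is_stronger",
         ttest = "lower_is_stronger",
         stop("unknown method tag: ", method, call. = FALSE))
}

#' Score and rank all genes across comparisons and methods
#'
#' Builds the long-format gene score table: one row per gene,
#' comparison and method, with the score and its within-comparison
#' fractional rank.
#'
#' @inheritParams score_gene
#' @param comparisons List of [comparison_spec()] (default the three
#'   canonical tissue comparisons).
#' @param methods Character subset of `c("mmd", "ttest", "foldchange")`.
#' @return `data.frame` with columns `gene_id`, `comparison`, `method`,
#'   `score`, `rank`.
#' @export
score_genes <- function(mat, labels,
                        comparisons = default_comparisons(),
                        methods = c("mmd", "ttest", "foldchange"),
                        config = kernel_config(), pseudocount = 0,
                        welch = FALSE) {
  validate_expression_matrix(mat)
  check_samples_match(mat, labels)
  methods <- match.arg(methods, several.ok = TRUE)
  genes <- rownames(mat)
  out <- vector("list", length(comparisons) * length(methods))
  i <- 0L
  for (cmp in comparisons) {
    idx_a <- names(labels)[labels == cmp$group_a]
    idx_b <- names(labels)[labels == cmp$group_b]
    if (length(idx_a) < 2L || length(idx_b) < 2L) {
      stop(sprintf("comparison '%s': each group needs >= 2 samples",
                   cmp$name), call. = FALSE)
    }
    xs <- mat[, idx_a, drop = FALSE]
    ys <- mat[, idx_b, drop = FALSE]
    for (method in methods) {
      scores <- vapply(genes, function(g) {
        x <- xs[g, ]; y <- ys[g, ]
        switch(method,
               mmd = mmd2_unbiased(x, y, config),
               ttest = t_test_gene(x, y, welch = welch),
               foldchange = fold_change_gene(x, y, pseudocount = pseudocount))
      }, numeric(1))
      i <- i + 1L
      out[[i]] <- data.frame(
        gene_id = genes, comparison = cmp$name, method = method,
        score = unname(scores),
        rank = unname(rank_genes(scores, method_direction(method))),
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Average rank of each gene over a set of comparisons
#'
#' Arithmetic mean of the per-comparison fractional ranks for one
#' method.  Two presets matter in a three-group design: the
#' tumor-focused pair (normal-vs-tumor, NAT-vs-tumor) and all three
#' comparisons (final marker list).
#'
#' @param score_table Output of [score_genes()].
#' @param comparisons Character vector of comparison names to average
#'   over (non-empty; each must be present for every gene).
#' @param method Method tag to use.
#' @return Named numeric vector of average ranks.
#' @export
average_rank <- function(score_table, comparisons, method = "mmd") {
  if (length(comparisons) == 0L) {
    stop("at least one comparison is required", call. = FALSE)
  }
  sub <- score_table[score_table$method == method &
                       score_table$comparison %in% comparisons, ]
  missing <- setdiff(comparisons, unique(sub$comparison))
  if (length(missing) > 0L) {
    stop("comparison(s) absent from score table: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  genes <- unique(score_table$gene_id)
  wide <- vapply(comparisons, function(cc) {
    s <- sub[sub$comparison == cc, ]
    stats::setNames(s$rank, s$gene_id)[genes]
  }, numeric(length(genes)))
  wide <- matrix(wide, nrow = length(genes))
  if (anyNA(wide)) stop("ranks missing for some genes", call. = FALSE)
  stats::setNames(rowMeans(wide), genes)
}

#' Top-k genes by average rank
#'
#' Genes sorted by ascending average rank, ties broken by lexicographic
#' gene id for determinism; the first `k` are returned.
#'
#' @param average_ranks Named numeric vector from [average_rank()].
#' @param k Number of genes to keep (1 <= k <= length(average_ranks)).
#' @return Character vector of `k` gene ids, strongest first.
#' @export
top_k <- function(average_ranks, k) {
  if (!is.numeric(k) || length(k) != 1L || k <= 0) {
    stop("k must be a positive integer", call. = FALSE)
  }
  if (k > length(average_ranks)) {
    stop("k exceeds the number of genes", call. = FALSE)
  }
  ord <- order(average_ranks, names(average_ranks))
  names(average_ranks)[ord][seq_len(k)]
}
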