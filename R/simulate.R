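#' Specification for a synthetic three-group expression matrix
#'
#' Defines a null-plus-spike-in simulation: most genes share one
#' distribution across all groups; a fraction are differentially
#' expressed (DE) with group-specific location shifts of a stated effect
#' size, following one of three ordering patterns.  For the default
#' lognormal baseline (FPKM-like right skew) the shift is applied on the
#' log scale in units of the within-group log-sd; for the truncated
#' normal it is applied on the raw scale in units of the raw sd.
#'
#' @param n_genes Number of genes.
#' @param group_sizes Named integer vector `c(normal=, nat=, tumor=)`,
#'   each >= 2.
#' @param de_fraction Fraction of genes that are DE (rounded to a
#'   count).
#' @param effect_sizes Location shift(s) between adjacent groups in
#'   within-group sd units; recycled over DE genes.
#' @param within_sd Within-group sd (log scale for lognormal).
#' @param baseline_law `"lognormal"` or `"normal"` (normal truncated at
#'   0; negligible truncation for the default baselines).
#' @param ordering_patterns Per-DE-gene pattern, recycled:
#'   `"normal_high"` (normal > nat > tumor, the dominant marker
#'   profile), `"tumor_high"` (inverted) or `"nat_high"` (adjacent
#'   tissue peaks).
#' @param seed Integer seed; each gene draws from its own derived
#'   substream so adding genes leaves earlier genes unchanged.
#' @return A `simulation_spec` list.
#' @export
simulation_spec <- function(n_genes = 500L,
                            group_sizes = c(normal = 75L, nat = 12L,
                                            tumor = 108L),
                            de_fraction = 0.05,
                            effect_sizes = 2,
                            within_sd = 0.5,
                            baseline_law = c("lognormal", "normal"),
                            ordering_patterns = c("normal_high",
                                                  "normal_high",
                                                  "normal_high",
                                                  "tumor_high", "nat_high"),
                            seed = 1L) {
  baseline_law <- match.arg(baseline_law)
  if (n_genes < 1L) stop("n_genes must be >= 1", call. = FALSE)
  if (length(group_sizes) != 3L || is.null(names(group_sizes)) ||
      any(group_sizes < 2L)) {
    stop("group_sizes must be three named counts, each >= 2", call. = FALSE)
  }
  if (de_fraction < 0 || de_fraction > 1) {
    stop("de_fraction must lie in [0, 1]", call. = FALSE)
  }
  if (within_sd <= 0) stop("within_sd must be positive", call. = FALSE)
  if (any(!ordering_patterns %in% c("normal_high", "tumor_high", "nat_high"))) {
    stop("unknown ordering pattern", call. = FALSE)
  }
  structure(list(n_genes = as.integer(n_genes),
                 group_sizes = group_sizes,
                 de_fraction = de_fraction,
                 effect_sizes = effect_sizes,
                 within_sd = within_sd,
                 baseline_law = baseline_law,
                 ordering_patterns = ordering_patterns,
                 seed = as.integer(seed)),
            class = "simulation_spec")
}

#' Desk-scale default simulation shape
#'
#' A three-group design echoing the sample imbalance of the large public
#' lung cohorts this package targets (hundreds of tumors, a much smaller
#' tumor-adjacent set) at one fifth their size: groups of 75 normal,
#' 12 NAT and 108 tumor samples, 500 genes, 5% DE at effect size 2.
#'
#' @param seed Integer seed.
#' @return A [simulation_spec()].
#' @export
default_study_spec <- function(seed = 1L) {
  simulation_spec(seed = seed)
}

# Group offsets (in within-group sd units) for one DE gene.
pattern_offsets <- function(pattern, effect) {
  switch(pattern,
         normal_high = c(normal = 2, nat = 1, tumor = 0) * effect,
         tumor_high = c(normal = 0, nat = 1, tumor = 2) * effect,
         nat_high = c(normal = 1, nat = 2, tumor = 0) * effect,
         stop("unknown ordering pattern: ", pattern, call. = FALSE))
}

#' Simulate an expression matrix with known DE truth
#'
#' Generates a gene-by-sample matrix under `spec`, together with the
#' group labels and a truth record: which genes are DE, their per-group
#' population means (data scale) and the midpoint thresholds between
#' adjacent group means — the targets boundary recovery is judged
#' against.  Fully deterministic given `spec$seed`.
#'
#' @param spec A [simulation_spec()].
#' @return List with `matrix`, `labels` (named character vector) and
#'   `truth` (list: `de_gene_ids`, and per-DE-gene `group_means`,
#'   `thresholds`, `pattern`).
#' @export
simulate_expression <- function(spec) {
  if (!inherits(spec, "simulation_spec")) {
    stop("spec must be a simulation_spec", call. = FALSE)
  }
  groups <- names(spec$group_sizes)
  sample_ids <- unlist(lapply(groups, function(g) {
    sprintf("%s_%03d", g, seq_len(spec$group_sizes[[g]]))
  }))
  labels <- stats::setNames(rep(groups, spec$group_sizes), sample_ids)
  n_de <- round(spec$de_fraction * spec$n_genes)
  gene_ids <- sprintf("gene_%04d", seq_len(spec$n_genes))
  de_ids <- gene_ids[seq_len(n_de)]
  effects <- rep_len(spec$effect_sizes, max(n_de, 1L))
  patterns <- rep_len(spec$ordering_patterns, max(n_de, 1L))

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))

  mat <- matrix(0, nrow = spec$n_genes, ncol = length(sample_ids),
                dimnames = list(gene_ids, sample_ids))
  truth_genes <- vector("list", n_de)
  for (i in seq_len(spec$n_genes)) {
    # independent per-gene substream; stable under changes to n_genes
    set.seed((spec$seed + i * 10007L) %% .Machine$integer.max)
    base <- stats::runif(1, 0, 3)   # baseline location (log scale for lognormal)
    if (i <= n_de) {
      off <- pattern_offsets(patterns[i], effects[i]) * spec$within_sd
    } else {
      off <- c(normal = 0, nat = 0, tumor = 0)
    }
    locs <- base + off[labels]
    if (spec$baseline_law == "lognormal") {
      vals <- exp(stats::rnorm(length(labels), locs, spec$within_sd))
      group_means <- exp(base + off[groups] + spec$within_sd^2 / 2)
    } else {
      vals <- pmax(stats::rnorm(length(labels), locs, spec$within_sd), 0)
      group_means <- base + off[groups]
    }
    mat[i, ] <- vals
    if (i <= n_de) {
      gm <- sort(group_means)
      truth_genes[[i]] <- list(
        gene_id = gene_ids[i],
        group_means = stats::setNames(group_means, groups),
        thresholds = unname((gm[-3L] + gm[-1L]) / 2),
        pattern = patterns[i])
    }
  }
  validate_expression_matrix(mat)
  list(matrix = mat, labels = labels,
       truth = list(de_gene_ids = de_ids, genes = truth_genes))
}
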