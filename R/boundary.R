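#' Shannon entropy of class counts, in bits
#'
#' Ent = -sum p_k log2 p_k over classes with nonzero count (0 log 0 is
#' taken as 0).  0 for a pure set, log2(C) for C equally sized classes.
#'
#' @param counts Non-negative integer counts per class, total >= 1.
#' @return Entropy in bits.
#' @export
entropy_bits <- function(counts) {
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  total <- sum(counts)
  if (total < 1) stop("total count must be >= 1", call. = FALSE)
  p <- counts[counts > 0] / total
  -sum(p * log2(p))
}

#' Candidate split points for a continuous attribute
#'
#' Expression levels are continuous, so split candidates are the
#' midpoints between consecutive distinct sorted values: (#distinct - 1)
#' candidates, none colliding with a data value.
#'
#' @param values Numeric vector.
#' @return Ascending numeric vector of midpoints (empty when fewer than
#'   two distinct values).
#' @export
candidate_splits <- function(values) {
  u <- sort(unique(values))
  if (length(u) < 2L) return(numeric(0))
  (u[-length(u)] + u[-1L]) / 2
}

#' Information gain of a binary split on expression level
#'
#' Partitions the labelled values into \{v <= split\} and \{v > split\}
#' and returns Ent(D) minus the size-weighted child entropies.  Always
#' in \[0, Ent(D)\], attaining Ent(D) iff both children are pure.
#'
#' @param values Numeric expression levels.
#' @param labels Parallel class tags (any number of classes >= 2 among
#'   the data).
#' @param split Split point, strictly between min and max of `values`.
#' @return Gain in bits.
#' @export
information_gain <- function(values, labels, split) {
  if (length(values) != length(labels)) {
    stop("values and labels must have equal length", call. = FALSE)
  }
  if (split <= min(values) || split >= max(values)) {
    stop("split must lie strictly inside the data range", call. = FALSE)
  }
  classes <- unique(labels)
  left <- values <= split
  ent_parent <- entropy_bits(tabulate(factor(labels, classes)))
  n <- length(values)
  wl <- sum(left) / n
  ent_l <- entropy_bits(tabulate(factor(labels[left], classes)))
  ent_r <- entropy_bits(tabulate(factor(labels[!left], classes)))
  ent_parent - wl * ent_l - (1 - wl) * ent_r
}

#' Best expression boundary between two classes
#'
#' Exhaustively evaluates [information_gain()] at every midpoint
#' candidate and returns the argmax; gain ties are broken toward the
#' smallest threshold for determinism.  On perfectly separated classes
#' this is the midpoint of the gap between the class extremes.
#'
#' @inheritParams information_gain
#' @return List with `threshold` and `gain`.
#' @export
find_boundary <- function(values, labels) {
  if (length(unique(labels)) < 2L) {
    stop("both classes must be present", call. = FALSE)
  }
  splits <- candidate_splits(values)
  if (length(splits) == 0L) {
    stop("all values identical: no valid split point", call. = FALSE)
  }
  gains <- vapply(splits, function(s) information_gain(values, labels, s),
                  numeric(1))
  # ties (within float tolerance) break toward the smallest threshold
  best <- which(gains >= max(gains) - 1e-12)[1L]
  list(threshold = splits[best], gain = gains[best])
}

#' Per-class expression boundaries for a three-group design
#'
#' Orders the three groups by ascending median expression of the gene,
#' then solves two adjacent binary boundary problems: low-vs-middle
#' group giving t1 and middle-vs-high group giving t2.  When t1 < t2 the
#' class intervals partition the line as low: e <= t1, middle:
#' t1 < e < t2, high: e >= t2 (`monotone` is `TRUE`); crossed thresholds
#' are returned as-is with `monotone = FALSE` rather than silently
#' reordered.  The group sequence follows the data, not a fixed tissue
#' order: markers suppressed in tumor put tumor lowest, markers induced
#' in tumor or peaking in tumor-adjacent tissue come out inverted.
#'
#' @param mat Expression matrix.
#' @param labels Named group labels covering exactly `colnames(mat)`.
#' @param gene Gene identifier.
#' @param groups The three group tags (default normal / nat / tumor).
#' @return List of class `boundary_result`: `gene_id`, `group_order`
#'   (ascending median), `thresholds` (t1, t2), `gains`, `monotone`,
#'   and an `intervals` data.frame (`group`, `lower`, `upper`).
#' @export
three_class_boundaries <- function(mat, labels, gene,
                                   groups = c("normal", "nat", "tumor")) {
  if (length(groups) != 3L) stop("exactly three groups required", call. = FALSE)
  if (!gene %in% rownames(mat)) stop("unknown gene: ", gene, call. = FALSE)
  check_samples_match(mat, labels)
  v <- mat[gene, ]
  vals <- lapply(groups, function(g) unname(v[names(labels)[labels == g]]))
  names(vals) <- groups
  sizes <- lengths(vals)
  if (any(sizes < 2L)) {
    stop("group(s) with < 2 samples: ",
         paste(groups[sizes < 2L], collapse = ", "), call. = FALSE)
  }
  med <- vapply(vals, stats::median, numeric(1))
  ord <- groups[order(med, groups)]
  lo <- vals[[ord[1L]]]; mi <- vals[[ord[2L]]]; hi <- vals[[ord[3L]]]
  b1 <- find_boundary(c(lo, mi), rep(ord[1:2], c(length(lo), length(mi))))
  b2 <- find_boundary(c(mi, hi), rep(ord[2:3], c(length(mi), length(hi))))
  monotone <- b1$threshold < b2$threshold
  if (!monotone) {
    warning(sprintf(
      "gene '%s': adjacent-pair thresholds cross (%.6g >= %.6g); intervals not interpretable",
      gene, b1$threshold, b2$threshold), call. = FALSE)
  }
  intervals <- data.frame(
    group = ord,
    lower = c(-Inf, b1$threshold, b2$threshold),
    upper = c(b1$threshold, b2$threshold, Inf),
    stringsAsFactors = FALSE)
  structure(list(gene_id = gene, group_order = ord,
                 thresholds = c(b1$threshold, b2$threshold),
                 gains = c(b1$gain, b2$gain),
                 monotone = monotone, intervals = intervals),
            class = "boundary_result")
}

#' Boundary table for a set of genes
#'
#' One row per gene and group: the per-class expression interval
#' (`-Inf`/`Inf` for the open ends), the information gain of the
#' threshold adjacent to the class, and the monotonicity flag.
#'
#' @inheritParams three_class_boundaries
#' @param genes Character vector of gene ids.
#' @return `data.frame` with columns `gene_id`, `group`,
#'   `interval_lower`, `interval_upper`, `threshold_gain`,
#'   `monotone_flag`.
#' @export
boundary_table <- function(mat, labels, genes,
                           groups = c("normal", "nat", "tumor")) {
  rows <- lapply(genes, function(g) {
    b <- three_class_boundaries(mat, labels, g, groups)
    data.frame(gene_id = g, group = b$intervals$group,
               interval_lower = b$intervals$lower,
               interval_upper = b$intervals$upper,
               threshold_gain = c(b$gains[1L], NA_real_, b$gains[2L]),
               monotone_flag = b$monotone,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
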