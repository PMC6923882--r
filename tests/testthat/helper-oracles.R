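# Independent oracles, deliberately naive: these re-derive each quantity
# from its definition and never share code with the package internals.

# Unbiased MMD^2 by explicit double loops over the kernel sums.
naive_mmd2 <- function(x, y, sigma) {
  m <- length(x); n <- length(y)
  sxx <- 0
  for (i in seq_len(m)) for (j in seq_len(m)) {
    if (i != j) sxx <- sxx + exp(-(x[i] - x[j])^2 / (2 * sigma^2))
  }
  syy <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j) syy <- syy + exp(-(y[i] - y[j])^2 / (2 * sigma^2))
  }
  sxy <- 0
  for (i in seq_len(m)) for (j in seq_len(n)) {
    sxy <- sxy + exp(-(x[i] - y[j])^2 / (2 * sigma^2))
  }
  sxx / (m * (m - 1)) + syy / (n * (n - 1)) - 2 * sxy / (m * n)
}

# Entropy straight from the definition.
naive_entropy <- function(counts) {
  p <- counts / sum(counts)
  s <- 0
  for (pk in p) if (pk > 0) s <- s - pk * log2(pk)
  s
}

# Exhaustive best-midpoint scan, recomputing entropies from scratch.
naive_best_split <- function(values, labels) {
  u <- sort(unique(values))
  best_t <- NA_real_; best_g <- -Inf
  parent <- naive_entropy(table(labels))
  for (i in seq_len(length(u) - 1L)) {
    s <- (u[i] + u[i + 1L]) / 2
    left <- values <= s
    g <- parent -
      (sum(left) / length(values)) * naive_entropy(table(labels[left])) -
      (sum(!left) / length(values)) * naive_entropy(table(labels[!left]))
    if (g > best_g + 1e-12) { best_g <- g; best_t <- s }
  }
  list(threshold = best_t, gain = best_g)
}

# Confusion-table metrics written out longhand.
naive_metrics <- function(tp, fp, fn, tn) {
  rec <- if (tp + fn > 0) tp / (tp + fn) else 0
  pre <- if (tp + fp > 0) tp / (tp + fp) else 0
  f1 <- if (pre + rec > 0) 2 * pre * rec / (pre + rec) else 0
  acc <- (tp + tn) / (tp + fp + fn + tn)
  den <- sqrt(as.numeric(tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
  mcc <- if (den > 0) (tp * tn - fp * fn) / den else 0
  list(recall = rec, precision = pre, f1 = f1, accuracy = acc, mcc = mcc)
}

# Rank-sum (Mann-Whitney) AUROC: probability a true-signal gene scores
# stronger than a null gene.  `strong_small = TRUE` when smaller values
# mean stronger (ranks).
auroc <- function(signal, null, strong_small = FALSE) {
  if (strong_small) { signal <- -signal; null <- -null }
  r <- rank(c(signal, null))
  n1 <- length(signal); n2 <- length(null)
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n2)
}

# Small three-group matrix with hand-placed values for interface tests.
tiny_dataset <- function() {
  mat <- rbind(
    gene_a = c(9.0, 9.5, 10.0, 5.1, 4.9, 1.0, 1.2, 0.8),
    gene_b = c(2.0, 2.2, 1.8, 2.1, 1.9, 2.0, 2.3, 1.7),
    gene_c = c(0.5, 0.7, 0.6, 3.0, 3.2, 8.0, 8.5, 7.5))
  colnames(mat) <- c("n1", "n2", "n3", "a1", "a2", "t1", "t2", "t3")
  labels <- c(n1 = "normal", n2 = "normal", n3 = "normal",
              a1 = "nat", a2 = "nat",
              t1 = "tumor", t2 = "tumor", t3 = "tumor")
  list(matrix = mat, labels = labels)
}
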