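#' Classification metrics from confusion counts
#'
#' Recall, precision, F1, accuracy and Matthews correlation coefficient
#' for a binary confusion table (positive class = tumor by convention).
#' Any metric whose denominator is zero is reported as 0 and the result
#' flagged degenerate, so zero-positive folds never propagate NaN.
#'
#' @param tp,fp,fn,tn Non-negative integer counts.
#' @return List with `recall`, `precision`, `f1`, `accuracy`, `mcc`,
#'   `degenerate`.
#' @export
compute_metrics <- function(tp, fp, fn, tn) {
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  degenerate <- FALSE
  safe_div <- function(num, den) {
    if (den == 0) { degenerate <<- TRUE; 0 } else num / den
  }
  recall <- safe_div(tp, tp + fn)
  precision <- safe_div(tp, tp + fp)
  f1 <- safe_div(2 * precision * recall, precision + recall)
  accuracy <- safe_div(tp + tn, tp + fp + fn + tn)
  mcc_den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  mcc <- safe_div(tp * tn - fp * fn, mcc_den)
  list(recall = recall, precision = precision, f1 = f1,
       accuracy = accuracy, mcc = mcc, degenerate = degenerate)
}

#' Stratified k-fold test-set indices
#'
#' Partitions samples into k disjoint test sets preserving class
#' proportions: within each class, indices are shuffled (seeded) and
#' dealt round-robin, so per-fold class counts differ from exact
#' proportionality by at most 1.  Deterministic given the seed.
#'
#' @param binary_labels Vector of two-level labels (any types coercible
#'   to factor).
#' @param k Fold count; every class must have >= k members.
#' @param seed Integer RNG seed.
#' @return List of k integer index vectors (test sets).
#' @export
stratified_kfold_indices <- function(binary_labels, k, seed = 1L) {
  if (!is.numeric(k) || length(k) != 1L || k < 2) {
    stop("k must be an integer >= 2", call. = FALSE)
  }
  classes <- unique(binary_labels)
  small <- classes[vapply(classes, function(cl) sum(binary_labels == cl) < k,
                          logical(1))]
  if (length(small) > 0L) {
    stop("class(es) smaller than k: ", paste(small, collapse = ", "),
         call. = FALSE)
  }
  folds <- vector("list", k)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  for (cl in classes) {
    idx <- sample(which(binary_labels == cl))
    assign_to <- rep_len(seq_len(k), length(idx))
    for (f in seq_len(k)) {
      folds[[f]] <- c(folds[[f]], idx[assign_to == f])
    }
  }
  lapply(folds, sort)
}

# Save/restore the global RNG state so seeded helpers do not perturb the
# caller's random stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Cross-validation configuration
#'
#' @param k Fold count (default 10).
#' @param seed Integer seed driving fold assignment and the classifier.
#' @param classifier Classifier tag; `"random_forest"` (100 trees) is
#'   the default and currently the only built-in.
#' @param positive_class Group tag treated as the positive class; all
#'   other groups are pooled as negatives (tumor-vs-rest).
#' @param ntree Trees in the forest.
#' @return A `cv_config` list.
#' @export
cv_config <- function(k = 10L, seed = 1L, classifier = "random_forest",
                      positive_class = "tumor", ntree = 100L) {
  structure(list(k = as.integer(k), seed = as.integer(seed),
                 classifier = classifier,
                 positive_class = positive_class,
                 ntree = as.integer(ntree)),
            class = "cv_config")
}

#' Stratified k-fold cross-validated evaluation of a gene panel
#'
#' Binarizes the labels as `positive_class` vs all others, then for each
#' fold trains the classifier on the remaining k-1 folds using the
#' selected genes' expression as features and predicts the held-out
#' samples.  Every sample is predicted exactly once.  Reports per-fold
#' confusion counts and metrics, their fold-averaged means (the default
#' headline numbers) and the pooled-count metrics.  Note that the panel
#' is assumed to have been selected before this call, typically on the
#' full data; that selection is outside the cross-validation loop.
#'
#' @param mat Expression matrix restricted to the selected genes (rows).
#' @param labels Named group labels for `colnames(mat)`.
#' @param config A [cv_config()].
#' @return List of class `cv_metrics`: `per_fold` (data.frame of counts
#'   and metrics per fold), `mean` and `pooled` metric lists, and
#'   `config`.
#' @export
cross_validate <- function(mat, labels, config = cv_config()) {
  validate_expression_matrix(mat)
  check_samples_match(mat, labels)
  if (nrow(mat) == 0L) stop("no genes selected", call. = FALSE)
  labels <- labels[colnames(mat)]
  y <- factor(ifelse(labels == config$positive_class, "pos", "neg"),
              levels = c("neg", "pos"))
  folds <- stratified_kfold_indices(as.character(y), config$k, config$seed)
  feats <- t(mat)  # samples x genes for the classifier
  colnames(feats) <- make.names(colnames(feats))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  per_fold <- vector("list", config$k)
  for (f in seq_len(config$k)) {
    test <- folds[[f]]
    train <- setdiff(seq_along(y), test)
    if (length(unique(y[train])) < 2L) {
      stop("fold ", f, " has a single class in training; ",
           "use a smaller k or more data", call. = FALSE)
    }
    set.seed(config$seed + f)
    fit <- randomForest::randomForest(feats[train, , drop = FALSE], y[train],
                                      ntree = config$ntree)
    pred <- stats::predict(fit, feats[test, , drop = FALSE])
    tp <- sum(pred == "pos" & y[test] == "pos")
    fp <- sum(pred == "pos" & y[test] == "neg")
    fn <- sum(pred == "neg" & y[test] == "pos")
    tn <- sum(pred == "neg" & y[test] == "neg")
    m <- compute_metrics(tp, fp, fn, tn)
    per_fold[[f]] <- data.frame(fold = f, tp = tp, fp = fp, fn = fn, tn = tn,
                                recall = m$recall, precision = m$precision,
                                f1 = m$f1, accuracy = m$accuracy, mcc = m$mcc)
  }
  per_fold <- do.call(rbind, per_fold)
  mean_metrics <- as.list(colMeans(
    per_fold[, c("recall", "precision", "f1", "accuracy", "mcc")]))
  pooled <- compute_metrics(sum(per_fold$tp), sum(per_fold$fp),
                            sum(per_fold$fn), sum(per_fold$tn))
  structure(list(per_fold = per_fold, mean = mean_metrics, pooled = pooled,
                 config = config), class = "cv_metrics")
}

#' @export
print.cv_metrics <- function(x, ...) {
  cat(sprintf("%d-fold stratified CV (%s, positive = %s)\n",
              x$config$k, x$config$classifier, x$config$positive_class))
  cat(sprintf("fold-averaged: recall %.4f  F1 %.4f  accuracy %.4f  MCC %.4f\n",
              x$mean$recall, x$mean$f1, x$mean$accuracy, x$mean$mcc))
  cat(sprintf("pooled-count:  recall %.4f  F1 %.4f  accuracy %.4f  MCC %.4f\n",
              x$pooled$recall, x$pooled$f1, x$pooled$accuracy, x$pooled$mcc))
  invisible(x)
}
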