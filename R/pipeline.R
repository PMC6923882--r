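#' Pipeline configuration
#'
#' Bundles everything the end-to-end marker-discovery run needs: inputs,
#' comparisons, scoring methods, kernel settings, the average-rank
#' preset, panel size, CV settings and the output directory.
#'
#' @param matrix_path,labels_path Input TSV paths (may be `NULL` when a
#'   matrix and labels are passed to [run_pipeline()] directly).
#' @param comparisons List of [comparison_spec()].
#' @param methods Scoring methods to compute.
#' @param kernel A [kernel_config()].
#' @param rank_preset `"all"` (average over every comparison; final
#'   marker list) or `"tumor_focused"` (normal-vs-tumor and
#'   NAT-vs-tumor only).
#' @param top_k Panel size for marker selection and boundary tables.
#' @param cv A [cv_config()].
#' @param out_dir Output directory (created if missing).
#' @param log2_offset If non-`NULL`, log2(v + offset) transform applied
#'   on load; default `NULL` (raw FPKM).
#' @param pseudocount Fold-change pseudocount.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(matrix_path = NULL, labels_path = NULL,
                            comparisons = default_comparisons(),
                            methods = c("mmd", "ttest", "foldchange"),
                            kernel = kernel_config(),
                            rank_preset = c("all", "tumor_focused"),
                            top_k = 10L,
                            cv = cv_config(),
                            out_dir = ".",
                            log2_offset = NULL,
                            pseudocount = 0) {
  rank_preset <- match.arg(rank_preset)
  if (top_k < 1L) stop("top_k must be >= 1", call. = FALSE)
  structure(list(matrix_path = matrix_path, labels_path = labels_path,
                 comparisons = comparisons, methods = methods,
                 kernel = kernel, rank_preset = rank_preset,
                 top_k = as.integer(top_k), cv = cv, out_dir = out_dir,
                 log2_offset = log2_offset, pseudocount = pseudocount),
            class = "pipeline_config")
}

preset_comparisons <- function(config) {
  nm <- vapply(config$comparisons, `[[`, character(1), "name")
  if (config$rank_preset == "tumor_focused") {
    keep <- nm[grepl("tumor", nm) &
                 vapply(config$comparisons, function(cmp) {
                   cmp$group_a == "tumor" || cmp$group_b == "tumor"
                 }, logical(1))]
    if (length(keep) == 0L) stop("no tumor comparison in config", call. = FALSE)
    keep
  } else nm
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full marker-discovery pipeline
#'
#' Executes the four stages in order — per-gene scoring over all
#' comparisons and methods, per-comparison ranking with average-rank
#' aggregation, top-k marker selection, and boundary discovery plus
#' cross-validated evaluation of the selected panel — and writes every
#' artifact to `config$out_dir`:
#' \describe{
#'   \item{scores.tsv}{gene_id, comparison, method, score, rank}
#'   \item{average_ranks.tsv}{per gene and method, the preset average rank}
#'   \item{top_genes.txt}{one selected gene id per line (MMD ranking),
#'     suitable for external enrichment tools}
#'   \item{boundaries.tsv}{per-class expression intervals for the panel}
#'   \item{cv_report.json}{per-fold and aggregate CV metrics}
#'   \item{manifest.json}{config echo (seeds included)}
#'   \item{run.log}{stage-by-stage log}
#' }
#' Reruns with an identical config produce byte-identical artifacts.
#'
#' @param config A [pipeline_config()].
#' @param mat,labels Optional in-memory inputs overriding the config
#'   paths.
#' @return Invisibly, a list with the in-memory results (`score_table`,
#'   `average_ranks`, `top_genes`, `boundaries`, `cv`) and `paths` to
#'   the artifacts.
#' @export
run_pipeline <- function(config, mat = NULL, labels = NULL) {
  if (!inherits(config, "pipeline_config")) {
    stop("config must be a pipeline_config", call. = FALSE)
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character(0)
  note <- function(...) log_lines <<- c(log_lines, paste0(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE)
    })
  }

  if (is.null(mat)) {
    mat <- stage("load", read_expression(config$matrix_path))
  }
  if (is.null(labels)) {
    labels <- stage("load", read_group_labels(config$labels_path))
  }
  stage("load", check_samples_match(mat, labels))
  if (!is.null(config$log2_offset)) {
    mat <- log_transform(mat, config$log2_offset)
    note("load: applied log2(v + ", config$log2_offset, ")")
  }
  note("load: ", nrow(mat), " genes x ", ncol(mat), " samples")

  score_table <- stage("score",
    score_genes(mat, labels, config$comparisons, config$methods,
                config$kernel, pseudocount = config$pseudocount))
  write_tsv(score_table, file.path(config$out_dir, "scores.tsv"))
  note("score: ", nrow(score_table), " rows (",
       paste(config$methods, collapse = ", "), ")")

  cmp_names <- preset_comparisons(config)
  avg <- lapply(config$methods, function(mth)
    stage("rank", average_rank(score_table, cmp_names, mth)))
  names(avg) <- config$methods
  avg_df <- data.frame(gene_id = names(avg[[1L]]),
                       lapply(avg, unname),
                       check.names = FALSE, stringsAsFactors = FALSE)
  colnames(avg_df)[-1L] <- paste0("average_rank_", config$methods)
  write_tsv(avg_df, file.path(config$out_dir, "average_ranks.tsv"))
  note("rank: preset '", config$rank_preset, "' over ",
       paste(cmp_names, collapse = ", "))

  sel_method <- if ("mmd" %in% config$methods) "mmd" else config$methods[1L]
  top_genes <- stage("select", top_k(avg[[sel_method]], config$top_k))
  writeLines(top_genes, file.path(config$out_dir, "top_genes.txt"))
  note("select: top ", config$top_k, " genes by ", sel_method,
       " average rank")

  groups <- unique(unlist(lapply(config$comparisons,
                                 function(cmp) c(cmp$group_a, cmp$group_b))))
  boundaries <- stage("boundary",
    boundary_table(mat, labels, top_genes, groups = groups))
  write_tsv(boundaries, file.path(config$out_dir, "boundaries.tsv"))
  note("boundary: ", length(top_genes), " genes, ",
       sum(!boundaries$monotone_flag) / length(groups), " non-monotone")

  cv <- stage("evaluate",
    cross_validate(mat[top_genes, , drop = FALSE], labels, config$cv))
  cv_out <- list(config = list(k = cv$config$k, seed = cv$config$seed,
                               classifier = cv$config$classifier,
                               positive_class = cv$config$positive_class,
                               genes = top_genes),
                 per_fold = cv$per_fold,
                 mean = cv$mean,
                 pooled = cv$pooled[setdiff(names(cv$pooled), "degenerate")])
  jsonlite::write_json(cv_out, file.path(config$out_dir, "cv_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  note(sprintf("evaluate: mean accuracy %.4f, MCC %.4f",
               cv$mean$accuracy, cv$mean$mcc))

  manifest <- list(
    methods = config$methods,
    comparisons = lapply(config$comparisons, unclass),
    kernel = unclass(config$kernel),
    rank_preset = config$rank_preset,
    top_k = config$top_k,
    cv = unclass(config$cv),
    log2_offset = config$log2_offset,
    pseudocount = config$pseudocount)
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  writeLines(log_lines, file.path(config$out_dir, "run.log"))

  artifacts <- c("scores.tsv", "average_ranks.tsv", "top_genes.txt",
                 "boundaries.tsv", "cv_report.json", "manifest.json",
                 "run.log")
  invisible(list(score_table = score_table, average_ranks = avg,
                 top_genes = top_genes, boundaries = boundaries, cv = cv,
                 paths = file.path(config$out_dir, artifacts)))
}
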