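test_that("pooled-variance t-test matches the closed-form oracle", {
  # {1,2,3} vs {4,5,6}: t = -3/sqrt(2/3), df = 4
  p_oracle <- 2 * pt(-3 / sqrt(2 / 3), df = 4)
  expect_equal(t_test_gene(1:3, 4:6), p_oracle, tolerance = 1e-9)
  expect_equal(round(p_oracle, 6), 0.021312)
  expect_equal(t_test_gene(4:6, 1:3), t_test_gene(1:3, 4:6))
  expect_equal(t_test_gene(c(1, 2, 3), c(3, 1, 2)), 1)

  # random instances against an independently coded pooled-t formula
  set.seed(5)
  for (rep in 1:50) {
    x <- rnorm(sample(3:8, 1)); y <- rnorm(sample(3:8, 1), 0.5)
    m <- length(x); n <- length(y)
    sp2 <- ((m - 1) * var(x) + (n - 1) * var(y)) / (m + n - 2)
    tt <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / m + 1 / n))
    expect_equal(t_test_gene(x, y), 2 * pt(-abs(tt), m + n - 2),
                 tolerance = 1e-9)
  }
})

test_that("degenerate constant genes get conventional p-values", {
  expect_equal(t_test_gene(c(2, 2), c(2, 2)), 1)
  expect_equal(t_test_gene(c(2, 2), c(5, 5)), 0)
})

test_that("fold change is |log2| of the mean ratio, symmetric, guarded at 0", {
  expect_equal(fold_change_gene(c(8, 8), c(2, 2)), 2)
  expect_equal(fold_change_gene(c(2, 2), c(8, 8)), 2)
  expect_equal(fold_change_gene(c(0, 0), c(3, 3), pseudocount = 1), 2)
  expect_error(fold_change_gene(c(0, 0), c(3, 3)), "pseudocount")
  set.seed(6)
  for (rep in 1:50) {
    x <- runif(4, 0.1, 10); y <- runif(5, 0.1, 10)
    expect_equal(fold_change_gene(x, y), abs(log2(mean(x) / mean(y))),
                 tolerance = 1e-12)
  }
})

test_that("score_gene dispatches to the same result as the direct calls", {
  d <- tiny_dataset()
  cmp <- comparison_spec("normal", "tumor")
  cfg <- kernel_config("fixed", sigma = 1)
  x <- d$matrix["gene_a", c("n1", "n2", "n3")]
  y <- d$matrix["gene_a", c("t1", "t2", "t3")]
  expect_equal(score_gene(d$matrix, d$labels, "gene_a", cmp, "mmd", cfg),
               mmd2_unbiased(unname(x), unname(y), cfg))
  expect_equal(score_gene(d$matrix, d$labels, "gene_a", cmp, "ttest"),
               t_test_gene(x, y))
  expect_equal(score_gene(d$matrix, d$labels, "gene_a", cmp, "foldchange"),
               fold_change_gene(x, y))
  expect_error(score_gene(d$matrix, d$labels, "gene_a", cmp, "limma"))
  undersized <- replace(d$labels, "a2", "other")
  expect_error(
    score_gene(d$matrix, undersized, "gene_a",
               comparison_spec("normal", "nat"), "mmd"),
    "'nat' has < 2 samples.*gene_a")
})

test_that("fractional ranking handles ties and directions", {
  scores <- c(g1 = 5, g2 = 3, g3 = 3, g4 = 1)
  expect_equal(rank_genes(scores, "higher_is_stronger"),
               c(g1 = 1, g2 = 2.5, g3 = 2.5, g4 = 4))
  expect_equal(sum(rank_genes(scores, "higher_is_stronger")), 4 * 5 / 2)
  p <- c(a = 0.01, b = 0.5, c = 0.2)
  expect_equal(rank_genes(p, "lower_is_stronger"),
               rank_genes(-p, "higher_is_stronger"))
  expect_error(rank_genes(c(a = 1, b = NaN)), "non-finite.*b")
  # invariance under strictly monotone transforms
  set.seed(8)
  s <- setNames(runif(20), paste0("g", 1:20))
  expect_equal(rank_genes(exp(3 * s)), rank_genes(s))
})

test_that("average rank and top-k follow the documented conventions", {
  d <- tiny_dataset()
  tab <- score_genes(d$matrix, d$labels,
                     config = kernel_config("fixed", sigma = 1))
  avg_all <- average_rank(tab, unique(tab$comparison), "mmd")
  expect_equal(unname(avg_all["gene_b"]), 3)  # flat gene is weakest everywhere
  one <- average_rank(tab, "normal_vs_tumor", "mmd")
  expect_equal(one,
               setNames(tab$rank[tab$method == "mmd" &
                                   tab$comparison == "normal_vs_tumor"],
                        tab$gene_id[tab$method == "mmd" &
                                      tab$comparison == "normal_vs_tumor"]))
  expect_error(average_rank(tab, character(0)), "at least one")
  expect_error(average_rank(tab, "normal_vs_plasma"), "absent")

  expect_equal(top_k(c(b = 2, a = 2, c = 1), 2), c("c", "a"))
  expect_equal(top_k(avg_all, 3), names(sort(avg_all)))
  expect_error(top_k(avg_all, 0), "positive")
  expect_error(top_k(avg_all, 99), "exceeds")
})

test_that("MMD average ranking separates true DE genes from nulls", {
  sim <- simulate_expression(simulation_spec(
    n_genes = 200, group_sizes = c(normal = 40, nat = 10, tumor = 50),
    de_fraction = 0.1, effect_sizes = 2, seed = 314))
  tab <- score_genes(sim$matrix, sim$labels, methods = "mmd")
  avg <- average_rank(tab, unique(tab$comparison), "mmd")
  de <- names(avg) %in% sim$truth$de_gene_ids
  expect_gte(auroc(avg[de], avg[!de], strong_small = TRUE), 0.95)
})
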