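test_that("entropy matches hand values and the naive oracle", {
  expect_equal(entropy_bits(c(5, 5)), 1)
  expect_equal(entropy_bits(c(7, 0)), 0)
  expect_equal(entropy_bits(c(3, 1)), 0.811278, tolerance = 1e-6)
  expect_equal(entropy_bits(c(2, 2, 2)), log2(3))
  expect_error(entropy_bits(c(-1, 2)), "non-negative")
  set.seed(3)
  for (rep in 1:25) {
    counts <- rpois(sample(2:5, 1), 4)
    if (sum(counts) == 0) counts[1] <- 1
    expect_equal(entropy_bits(counts), naive_entropy(counts))
  }
})

test_that("candidate splits are midpoints of consecutive distinct values", {
  expect_equal(candidate_splits(c(1, 2, 3)), c(1.5, 2.5))
  expect_equal(candidate_splits(c(1, 1, 2)), 1.5)
  expect_equal(candidate_splits(c(2, 3, 1)), c(1.5, 2.5))
  expect_identical(candidate_splits(5), numeric(0))
  expect_identical(candidate_splits(rep(4, 6)), numeric(0))
  set.seed(4)
  v <- sample(rnorm(10), 30, replace = TRUE)
  expect_false(any(candidate_splits(v) %in% v))
})

test_that("information gain matches hand-worked splits and stays bounded", {
  vals <- c(1, 2, 10, 11); labs <- c("n", "n", "t", "t")
  expect_equal(information_gain(vals, labs, 6), 1)
  vals2 <- c(1, 2, 3, 6, 4, 5, 7, 8)
  labs2 <- rep(c("normal", "tumor"), each = 4)
  expect_equal(information_gain(vals2, labs2, 3.5), 0.548795,
               tolerance = 1e-6)
  # proportions equal on both sides -> zero gain
  expect_equal(information_gain(c(1, 2, 3, 4), c("n", "t", "n", "t"), 2.5), 0)
  expect_error(information_gain(vals, labs, 0.5), "strictly inside")
  expect_error(information_gain(vals, labs, 11), "strictly inside")

  set.seed(9)
  for (rep in 1:50) {
    v <- round(runif(12, 0, 5), 1)
    if (length(unique(v)) < 2) next
    l <- sample(c("a", "b"), 12, replace = TRUE)
    if (length(unique(l)) < 2) next
    ent <- entropy_bits(table(l))
    g <- vapply(candidate_splits(v),
                function(s) information_gain(v, l, s), numeric(1))
    expect_true(all(g >= -1e-12 & g <= ent + 1e-12))
  }
})

test_that("find_boundary equals the exhaustive scan oracle", {
  fb <- find_boundary(c(1, 2, 3, 4, 5, 6), rep(c("n", "t"), each = 3))
  expect_equal(fb$threshold, 3.5)
  expect_equal(fb$gain, 1)
  fb2 <- find_boundary(c(1, 2, 3, 6, 4, 5, 7, 8),
                       rep(c("n", "t"), each = 4))
  expect_equal(fb2$threshold, 3.5)
  expect_equal(fb2$gain, 0.548795, tolerance = 1e-6)
  expect_error(find_boundary(rep(3, 4), c("n", "n", "t", "t")), "identical")
  expect_error(find_boundary(1:4, rep("n", 4)), "both classes")

  set.seed(10)
  for (rep in 1:100) {
    n <- sample(4:30, 1)
    v <- round(runif(n, 0, 10), 1)
    l <- sample(c("x", "y"), n, replace = TRUE)
    if (length(unique(v)) < 2 || length(unique(l)) < 2) next
    got <- find_boundary(v, l)
    want <- naive_best_split(v, l)
    expect_equal(got$gain, want$gain, tolerance = 1e-12)
    expect_equal(got$threshold, want$threshold)
    expect_false(got$threshold %in% v)  # argmax is always a midpoint
  }
})

test_that("recovered thresholds are affine-equivariant", {
  set.seed(12)
  v <- c(rnorm(20, 2), rnorm(20, 6))
  l <- rep(c("lo", "hi"), each = 20)
  base <- find_boundary(v, l)
  expect_equal(find_boundary(v + 11.5, l)$threshold, base$threshold + 11.5)
  expect_equal(find_boundary(v * 2.5, l)$threshold, base$threshold * 2.5)
  expect_equal(find_boundary(v * 2.5, l)$gain, base$gain)
})

test_that("separated classes give the midpoint of the gap", {
  v <- c(0.2, 0.9, 1.4, 3.8, 4.4, 5.0)
  fb <- find_boundary(v, rep(c("lo", "hi"), each = 3))
  expect_equal(fb$threshold, (1.4 + 3.8) / 2)
  expect_equal(fb$gain, 1)
})

test_that("three-class boundaries order groups by median and partition the line", {
  d <- tiny_dataset()
  # gene_a: tumor lowest, nat middle, normal highest (the dominant pattern)
  b <- three_class_boundaries(d$matrix, d$labels, "gene_a")
  expect_identical(b$group_order, c("tumor", "nat", "normal"))
  expect_true(b$monotone)
  expect_true(b$thresholds[1] > 1.2 && b$thresholds[1] < 4.9)
  expect_true(b$thresholds[2] > 5.1 && b$thresholds[2] < 9.0)
  # perfect adjacent splits: gain equals the parent entropy of each pair
  expect_equal(b$gains, c(entropy_bits(c(3, 2)), entropy_bits(c(2, 3))))
  expect_equal(b$intervals$lower, c(-Inf, b$thresholds))
  expect_equal(b$intervals$upper, c(b$thresholds, Inf))

  # gene_c inverts the tissue order: normal lowest, tumor highest
  b2 <- three_class_boundaries(d$matrix, d$labels, "gene_c")
  expect_identical(b2$group_order, c("normal", "nat", "tumor"))
  expect_true(b2$monotone)
})

test_that("crossed adjacent thresholds are flagged, not reordered", {
  mat <- matrix(c(2, 3,            # grp_lo
                  0, 1, 100, 101,  # grp_hi: bimodal, median highest
                  4, 5, 6, 7),     # grp_mid
                nrow = 1,
                dimnames = list("g", paste0("s", 1:10)))
  labels <- setNames(rep(c("lo", "hi", "mid"), c(2, 4, 4)), colnames(mat))
  expect_warning(
    b <- three_class_boundaries(mat, labels, "g",
                                groups = c("lo", "mid", "hi")),
    "cross")
  expect_identical(b$group_order, c("lo", "mid", "hi"))
  expect_false(b$monotone)
  expect_equal(b$thresholds, c(3.5, 2.5))
})

test_that("boundary recovery on well-separated synthetic genes", {
  # adjacent group means 4 sd apart; threshold should land near the midpoint
  hits <- 0L
  for (rep in 1:30) {
    set.seed(600 + rep)
    v <- c(rnorm(100, 5), rnorm(100, 9))
    l <- rep(c("lo", "hi"), each = 100)
    fb <- find_boundary(pmax(v, 0), l)
    if (abs(fb$threshold - 7) <= 1) hits <- hits + 1L
  }
  expect_gte(hits / 30, 0.95)
})

test_that("boundary_table emits one interval row per gene and group", {
  d <- tiny_dataset()
  tab <- boundary_table(d$matrix, d$labels, c("gene_a", "gene_c"))
  expect_equal(nrow(tab), 6)
  expect_identical(unique(tab$gene_id), c("gene_a", "gene_c"))
  ga <- tab[tab$gene_id == "gene_a", ]
  expect_equal(ga$interval_lower[1], -Inf)
  expect_equal(ga$interval_upper[3], Inf)
  expect_true(all(ga$monotone_flag))
})
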