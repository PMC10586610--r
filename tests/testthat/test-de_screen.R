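test_that("normalization scales each cell to the target and log-transforms", {
  cm <- count_matrix(matrix(c(2, 2), nrow = 2), c("g1", "g2"), "c1")
  ne <- normalize_counts(cm, scale_target = 4, log_base = "2")
  expect_equal(unname(ne$values[, 1]), c(log2(3), log2(3)))

  # all-zero gene rows stay zero
  cm2 <- count_matrix(matrix(c(1, 0, 3, 0), nrow = 2), c("g1", "g2"),
                      c("c1", "c2"))
  ne2 <- normalize_counts(cm2, scale_target = 10)
  expect_equal(unname(ne2$values[2, ]), c(0, 0))

  # per-cell scaling: a gene at 10% of both cells' totals maps identically
  cm3 <- count_matrix(matrix(c(1, 9, 10, 90), nrow = 2), c("g1", "g2"),
                      c("c1", "c2"))
  ne3 <- normalize_counts(cm3, scale_target = 100)
  expect_equal(ne3$values[1, 1], ne3$values[1, 2])

  # zero-total cells are rejected by name
  cm4 <- count_matrix(matrix(c(1, 0, 0, 0), nrow = 2), c("g1", "g2"),
                      c("ok", "empty_cell"))
  expect_error(normalize_counts(cm4), "empty_cell")

  # default scale target is the median cell total
  ne5 <- normalize_counts(cm3)
  expect_equal(ne5$scale_target, median(c(10, 100)))
})

test_that("gene filter boundary is inclusive at min_cells", {
  vals <- rbind(c(rep(1, 19), rep(0, 6)),   # detected in 19 cells
                c(rep(1, 20), rep(0, 5)),   # detected in 20 cells
                rep(0.5, 25),               # detected everywhere
                rep(0, 25))                 # never detected
  rownames(vals) <- c("g19", "g20", "gAll", "gNever")
  expr <- as_norm_expr(vals)
  kept <- filter_genes(expr, min_cells = 20)
  expect_equal(kept$gene_ids, c("g20", "gAll"))
  kept1 <- filter_genes(expr, min_cells = 1)
  expect_equal(kept1$gene_ids, c("g19", "g20", "gAll"))
  expect_error(filter_genes(as_norm_expr(matrix(0, 1, 3)), 1), "all genes")
})

test_that("one-sided rank-sum p matches enumeration on the worked cases", {
  expr <- as_norm_expr(matrix(c(5, 6, 7, 1, 2, 3, 4), nrow = 1))
  ann <- simple_annotation(expr, c("A", "A", "A", "B", "B", "B", "B"))
  p <- rank_sum_upregulation(expr, ann, "A")
  expect_equal(unname(p), 1 / 35, tolerance = 1e-12)

  # complete ties carry no evidence of elevation
  expr_t <- as_norm_expr(matrix(rep(2, 6), nrow = 1))
  ann_t <- simple_annotation(expr_t, rep(c("A", "B"), each = 3))
  expect_equal(unname(rank_sum_upregulation(expr_t, ann_t, "A")), 1)

  # group with minimal ranks: p near 1
  expr_l <- as_norm_expr(matrix(c(1, 2, 5, 6, 7), nrow = 1))
  ann_l <- simple_annotation(expr_l, c("A", "A", "B", "B", "B"))
  expect_gte(unname(rank_sum_upregulation(expr_l, ann_l, "A")), 0.95)

  expect_error(rank_sum_upregulation(expr, ann, "nope"), "unknown identity")
})

test_that("exact rank-sum branch equals the pair-counting permutation oracle", {
  set.seed(11)
  for (case in 1:40) {
    n1 <- sample(1:5, 1)
    n2 <- sample(1:5, 1)
    # draw from a small alphabet so ties are frequent
    x <- sample(1:4, n1, replace = TRUE)
    y <- sample(1:4, n2, replace = TRUE)
    expr <- as_norm_expr(matrix(c(x, y), nrow = 1))
    ann <- simple_annotation(expr, rep(c("in", "out"), c(n1, n2)))
    got <- unname(rank_sum_upregulation(expr, ann, "in"))
    expect_equal(got, oracle_rank_sum_greater(x, y), tolerance = 1e-12)
  }
})

test_that("vectorised screen p-values agree with the per-gene routine", {
  set.seed(5)
  vals <- matrix(rpois(30 * 60, 2) + 0.1 * rnorm(30 * 60)^2, nrow = 30)
  expr <- as_norm_expr(vals)
  labels <- rep(c("A", "B", "C"), each = 20)
  ann <- simple_annotation(expr, labels)
  de <- de_screen(expr, ann)
  for (id in c("A", "B", "C")) {
    direct <- rank_sum_upregulation(expr, ann, id)
    expect_equal(de$p_raw[de$identity == id], unname(direct),
                 tolerance = 1e-12)
  }
})

test_that("horizontal BH corrects along each gene's row", {
  p1 <- matrix(c(0.01, 0.02, 0.03, 0.04), nrow = 1)
  expect_equal(unname(horizontal_bh(p1)[1, ]), rep(0.04, 4))

  # family of one: q equals p
  p_single <- matrix(c(0.3, 0.01), ncol = 1)
  expect_equal(unname(horizontal_bh(p_single)), unname(p_single))

  pm <- matrix(1, 3, 4)
  expect_true(all(horizontal_bh(pm) == 1))

  # invariant to permuting identity-group order
  set.seed(3)
  p <- matrix(runif(5 * 6, 0.001, 1), 5, 6)
  perm <- sample(6)
  expect_equal(horizontal_bh(p)[, perm], horizontal_bh(p[, perm]),
               ignore_attr = TRUE)

  # matches the hand step-up oracle in every family
  q <- horizontal_bh(p)
  for (i in 1:5) expect_equal(unname(q[i, ]), oracle_bh(p[i, ]))
  q_col <- horizontal_bh(p, family = "per_group")
  for (j in 1:6) expect_equal(unname(q_col[, j]), oracle_bh(p[, j]))
  q_glob <- horizontal_bh(p, family = "global")
  expect_equal(as.vector(q_glob), oracle_bh(as.vector(p)))

  # q never below p within a family
  expect_true(all(q >= p - 1e-15))
  expect_error(horizontal_bh(matrix(c(0, 0.5), 1)), "0, 1")
})

test_that("fold changes, detection percentages and reciprocal identity", {
  vals <- rbind(c(4, 4, 2, 2),     # mean_in 4, mean_out 2
                c(3, 3, 3, 3),     # equal means
                c(1, 0, 1, 1))
  rownames(vals) <- c("up", "flat", "pct")
  expr <- as_norm_expr(vals)
  ann <- simple_annotation(expr, c("A", "A", "B", "B"))
  fc <- compute_fc(expr, ann, "A", epsilon = 0)
  expect_equal(fc$fc[fc$gene == "up"], 2)
  expect_equal(fc$log2fc[fc$gene == "up"], 1)
  expect_equal(fc$fc[fc$gene == "flat"], 1)
  expect_equal(fc$log2fc[fc$gene == "flat"], 0)

  # 3 of 4 in-group cells detected -> 75%
  vals2 <- matrix(c(1, 1, 1, 0, 0, 0, 1, 0), nrow = 1)
  expr2 <- as_norm_expr(vals2)
  ann2 <- simple_annotation(expr2, rep(c("A", "B"), each = 4))
  expect_equal(compute_fc(expr2, ann2, "A")$pct_in, 75)

  # fc(A vs rest) * fc(rest vs A) = 1 at epsilon = 0
  fcA <- compute_fc(expr, ann, "A", epsilon = 0)
  fcB <- compute_fc(expr, ann, "B", epsilon = 0)
  expect_equal(fcA$fc * fcB$fc, rep(1, 3))
})

test_that("upregulation call is inclusive on q, strict on log2fc", {
  expect_true(call_upregulated(0.05, 1.5))
  expect_false(call_upregulated(0.04, 1.0))
  expect_false(call_upregulated(0.06, 3.0))
  expect_true(call_upregulated(0.01, 1.0 + 1e-9))
})

test_that("rank-sum p-values are approximately uniform under the null", {
  # Exchangeable continuous data (no ties): 10 independent datasets of
  # 200 genes, one in-group of 30 cells vs 270 -> 2000 independent p-values.
  set.seed(2024)
  p_all <- numeric(0)
  for (rep in 1:10) {
    vals <- matrix(rnorm(200 * 300), nrow = 200)
    expr <- as_norm_expr(vals)
    ann <- simple_annotation(expr, rep(c("grp", "rest"), c(30, 270)))
    p_all <- c(p_all, unname(rank_sum_upregulation(expr, ann, "grp")))
  }
  frac <- mean(p_all <= 0.05)
  mc <- sqrt(0.05 * 0.95 / length(p_all))
  expect_lt(abs(frac - 0.05), 3 * mc)
})

test_that("de_screen output respects its own contracts", {
  sim <- simulate_counts(n_genes = 120, n_identities = 4,
                         cells_per_identity = 40,
                         planted_identity = "ident02", seed = 99)
  expr <- filter_genes(normalize_counts(sim$counts), 20)
  de <- de_screen(expr, sim$annotation)
  expect_setequal(names(de), c("gene", "identity", "p_raw", "q", "fc",
                               "log2fc", "pct_in", "pct_out", "upregulated"))
  expect_true(all(de$q >= de$p_raw - 1e-15))          # within per-gene family
  expect_true(all(abs(de$fc - 2^de$log2fc) < 1e-9))
  expect_true(all(de$upregulated == (de$q <= 0.05 & de$log2fc > 1)))
  expect_true(all(de$pct_in >= 0 & de$pct_in <= 100))
})
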