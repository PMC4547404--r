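star_edges <- function(hub = "h", k = 4) {
  data.frame(gene_a = hub, gene_b = sprintf("%s_i%d", hub, seq_len(k)),
             evidence_count = 2, source = "literature")
}

test_that("AvgPCC equals the mean of per-interactor correlation differences", {
  set.seed(8)
  edges <- star_edges(k = 4)
  genes <- unique(c(edges$gene_a, edges$gene_b))
  net <- build_disease_network(edges, genes)
  samples <- c(sprintf("D%d", 1:6), sprintf("C%d", 1:6))
  expr <- matrix(rnorm(length(genes) * 12), nrow = length(genes),
                 dimnames = list(genes, samples))
  groups <- setNames(rep(c("disease", "control"), each = 6), samples)
  got <- hub_avg_pcc(expr, groups, net, "h")
  expect_equal(got$n_interactors, 4L)
  expect_equal(got$avg_pcc,
               oracle_avg_pcc(expr, groups, "h", sprintf("h_i%d", 1:4)),
               tolerance = 1e-12)
})

test_that("identical disease and control columns give AvgPCC exactly 0", {
  edges <- star_edges(k = 3)
  genes <- unique(c(edges$gene_a, edges$gene_b))
  net <- build_disease_network(edges, genes)
  set.seed(2)
  half <- matrix(rnorm(length(genes) * 5), nrow = length(genes))
  expr <- cbind(half, half)
  dimnames(expr) <- list(genes, c(sprintf("D%d", 1:5), sprintf("C%d", 1:5)))
  groups <- setNames(rep(c("disease", "control"), each = 5), colnames(expr))
  expect_equal(hub_avg_pcc(expr, groups, net, "h")$avg_pcc, 0, tolerance = 1e-12)
})

test_that("planted differential correlation is recovered on a 5-gene star", {
  # interactors correlate 0.9 with the hub in disease, 0 in control
  set.seed(21)
  edges <- star_edges(k = 4)
  genes <- unique(c(edges$gene_a, edges$gene_b))
  net <- build_disease_network(edges, genes)
  nd <- 50
  hub_d <- rnorm(nd); hub_c <- rnorm(nd)
  expr <- rbind(h = c(hub_d, hub_c))
  for (i in 1:4) {
    expr <- rbind(expr, c(0.9 * hub_d + sqrt(1 - 0.81) * rnorm(nd), rnorm(nd)))
  }
  rownames(expr) <- genes
  colnames(expr) <- c(sprintf("D%d", 1:nd), sprintf("C%d", 1:nd))
  groups <- setNames(rep(c("disease", "control"), each = nd), colnames(expr))
  got <- hub_avg_pcc(expr, groups, net, "h")
  expect_equal(got$avg_pcc, 0.9, tolerance = 0.15)
  expect_equal(got$avg_pcc,
               oracle_avg_pcc(expr, groups, "h", sprintf("h_i%d", 1:4)),
               tolerance = 1e-12)
})

test_that("constant interactors are dropped from n, hubs without any are excluded", {
  edges <- star_edges(k = 2)
  genes <- unique(c(edges$gene_a, edges$gene_b))
  net <- build_disease_network(edges, genes)
  set.seed(4)
  expr <- matrix(rnorm(3 * 8), nrow = 3,
                 dimnames = list(genes, c(sprintf("D%d", 1:4), sprintf("C%d", 1:4))))
  expr["h_i2", ] <- 5  # constant in both groups
  groups <- setNames(rep(c("disease", "control"), each = 4), colnames(expr))
  expect_equal(hub_avg_pcc(expr, groups, net, "h")$n_interactors, 1L)

  expr["h_i1", ] <- 7
  expect_message(out <- hub_avg_pcc(expr, groups, net, "h"), "excluded")
  expect_null(out)
})

test_that("permutation null is deterministic and exhaustive at 3+3 samples", {
  te <- tiny_expr(n_genes = 5, n_per_group = 3, seed = 6)
  edges <- data.frame(gene_a = "g1", gene_b = c("g2", "g3", "g4"),
                      evidence_count = 2, source = "literature")
  net <- build_disease_network(edges, rownames(te$expr))
  r1 <- permutation_null(te$expr, te$groups, net, "g1", n_perm = 100, seed = 3)
  r2 <- permutation_null(te$expr, te$groups, net, "g1", n_perm = 100, seed = 3)
  expect_identical(r1$null, r2$null)
  expect_true(r1$exhaustive)
  expect_equal(ncol(r1$null), choose(6, 3))
  # identity split is among the enumerated splits
  expect_true(any(abs(r1$null - r1$table$avg_pcc) < 1e-12))
})

test_that("p-value boundary cases behave as counted fractions", {
  tab <- data.frame(hub_id = "h", n_interactors = 3L, avg_pcc = 0.7)
  res <- structure(list(table = tab,
                        null = matrix(seq(-0.5, 0.5, length.out = 100), 1),
                        excluded = character(), exhaustive = FALSE),
                   class = "netvar_result")
  out <- hub_pvalues(res, sidedness = "two_sided")
  expect_equal(out$table$p_value, 0)
  expect_equal(out$table$p_adjusted, 0)
  expect_true(out$table$significant)

  res$table$avg_pcc <- 0.25
  lit <- hub_pvalues(res, sidedness = "one_sided")
  expect_equal(lit$table$p_value, mean(0.25 >= res$null[1, ]))

  res$null <- matrix(rep(0.7, 10), 1)
  res$table$avg_pcc <- 0.7
  expect_equal(hub_pvalues(res)$table$p_value, 1)

  sm <- hub_pvalues(res, smooth = TRUE)
  expect_equal(sm$table$p_value, (1 + 10) / (1 + 10))
})

test_that("label exchange flips AvgPCC sign and keeps two-sided p-values", {
  fx <- generate_fixture(fixture_spec(n_genes = 60, n_samples_per_group = 6,
                                      n_planted_hubs = 2, seed = 9))
  net <- build_disease_network(fx$edges, rownames(fx$expr))
  hubs <- fx$planted
  swapped <- setNames(ifelse(fx$groups == "disease", "control", "disease"),
                      names(fx$groups))
  a <- hub_pvalues(permutation_null(fx$expr, fx$groups, net, hubs, 50, seed = 2))
  b <- hub_pvalues(permutation_null(fx$expr, swapped, net, hubs, 50, seed = 2))
  expect_equal(a$table$avg_pcc, -b$table$avg_pcc, tolerance = 1e-12)
  expect_equal(a$table$p_value, b$table$p_value)
})
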