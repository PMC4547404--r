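test_that("semantic profiles follow the Wang recursion on hand-worked DAGs", {
  # root-only
  root <- go_dag(data.frame(id = "R", name = "r", namespace = "biological_process"),
                 data.frame(child = character(), parent = character(),
                            relation = character()))
  pr <- semantic_profile(root, "R")
  expect_equal(pr$s, c(R = 1))
  expect_equal(pr$sv, 1)

  # chain A is_a P is_a R with w = 0.8
  pa <- semantic_profile(toy_dag(), "A")
  expect_equal(pa$s[c("A", "P", "R")], c(A = 1, P = 0.8, R = 0.64),
               tolerance = 1e-12)
  expect_equal(pa$sv, 2.44, tolerance = 1e-12)

  # diamond: two length-2 routes to the root, max rule gives 0.64
  dia <- go_dag(
    data.frame(id = c("R", "P1", "P2", "A"), name = "x",
               namespace = "biological_process"),
    data.frame(child = c("P1", "P2", "A", "A"),
               parent = c("R", "R", "P1", "P2"), relation = "is_a"))
  expect_equal(semantic_profile(dia, "A")$s[["R"]], 0.64, tolerance = 1e-12)

  expect_error(semantic_profile(toy_dag(), "nope"), "unknown term")
})

test_that("term similarity reproduces the hand-evaluated examples", {
  dag <- toy_dag()
  expect_equal(term_similarity(dag, "A", "A"), 1)
  # siblings B and P under R: shared {R}
  expect_equal(term_similarity(dag, "B", "P"), (0.8 + 0.8) / (1.8 + 1.8),
               tolerance = 1e-12)
  # term vs its parent: shared {P, R}
  expect_equal(term_similarity(dag, "A", "P"),
               (0.8 + 1 + 0.64 + 0.8) / (2.44 + 1.8), tolerance = 1e-12)
})

test_that("profile recursion equals the path-product-max oracle on random DAGs", {
  set.seed(14)
  for (rep in 1:5) {
    # random DAG on <= 20 terms: edges only from higher to lower index
    n <- sample(8:20, 1)
    ids <- sprintf("t%02d", seq_len(n))
    edges <- do.call(rbind, lapply(2:n, function(i) {
      parents <- sample(seq_len(i - 1), min(sample(1:2, 1), i - 1))
      data.frame(child = ids[i], parent = ids[parents],
                 relation = sample(c("is_a", "part_of"), length(parents),
                                   replace = TRUE))
    }))
    dag <- go_dag(data.frame(id = ids, name = ids,
                             namespace = "biological_process"), edges)
    a <- ids[n]
    prof <- semantic_profile(dag, a)
    for (t in names(prof$s)) {
      expect_equal(prof$s[[t]], oracle_svalue(dag, a, t), tolerance = 1e-9)
    }
  }
})

test_that("similarity is symmetric and 1 on self for random term pairs", {
  set.seed(7)
  td <- tree_dag(depth = 3, branching = 3)
  for (i in 1:25) {
    ab <- sample(td$ids, 2)
    expect_equal(term_similarity(td$dag, ab[1], ab[2]),
                 term_similarity(td$dag, ab[2], ab[1]), tolerance = 1e-12)
    expect_equal(term_similarity(td$dag, ab[1], ab[1]), 1)
  }
})

test_that("gene similarity combines term pairs as documented", {
  dag <- toy_dag()
  ann <- list(g1 = "A", g2 = c("A", "B"), g3 = "A")
  expect_equal(gene_similarity(dag, ann, "g1", "g3"), 1)
  s_ab <- term_similarity(dag, "A", "B")
  expect_equal(gene_similarity(dag, ann, "g1", "g2"), (1 + s_ab) / 2,
               tolerance = 1e-12)
  # best-match average: g1's A matches itself (1); g2's A matches A (1),
  # g2's B best-matches A (s_ab); (1 + 1 + s_ab) / 3
  expect_equal(gene_similarity(dag, ann, "g1", "g2", combine = "best_match_avg"),
               (1 + 1 + s_ab) / 3, tolerance = 1e-12)
  expect_equal(gene_similarity(dag, ann, "g2", "g1"),
               gene_similarity(dag, ann, "g1", "g2"))
  expect_error(gene_similarity(dag, list(g1 = "A", g4 = character()),
                               "g1", "g4"), "unannotated")
})

test_that("adding a shared ancestor annotation never lowers singleton similarity", {
  td <- tree_dag()
  ann <- list(g1 = td$leaves[1], g2 = td$leaves[4])
  base <- gene_similarity(td$dag, ann, "g1", "g2")
  shared_anc <- "T001"  # the root's first child, ancestor of both subtrees?
  ann2 <- list(g1 = sort(c(ann$g1, "T001")), g2 = sort(c(ann$g2, "T001")))
  expect_gte(gene_similarity(td$dag, ann2, "g1", "g2"), base)
})

test_that("median-similarity selection separates coherent from background hubs", {
  cf <- coherence_fixture(n_hubs = 30, n_coherent = 10, seed = 1)
  res <- prioritize_by_semsim(cf$dag, cf$ann, cf$net, cf$hubs, threshold = 0.5)
  expect_setequal(res$hub_id[res$selected], cf$coherent)

  # boundary: median exactly at the threshold is NOT selected (strict >)
  expect_false(any(res$selected & res$median_similarity <= 0.5))
})

test_that("unannotated hubs or interactor sets are excluded, not scored", {
  dag <- toy_dag()
  edges <- data.frame(gene_a = "h", gene_b = c("i1", "i2"),
                      evidence_count = 2, source = "literature")
  net <- build_disease_network(edges, c("h", "i1", "i2"))
  ann <- list(h = character(), i1 = "A", i2 = "B")
  res <- prioritize_by_semsim(dag, ann, net, "h")
  expect_true(res$excluded)
  expect_false(res$selected)

  ann2 <- list(h = "A", i1 = "A", i2 = "B")
  res2 <- prioritize_by_semsim(dag, ann2, net, "h")
  expect_false(res2$excluded)
  expect_equal(res2$n_scored_interactors, 2L)
  expect_equal(res2$median_similarity,
               median(c(1, gene_similarity(dag, ann2, "h", "i2"))),
               tolerance = 1e-12)
})
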