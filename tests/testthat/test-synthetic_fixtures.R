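test_that("network growth arithmetic and determinism hold", {
  spec <- fixture_spec(n_genes = 10, attachment = 2, n_planted_hubs = 1,
                       seed = 3)
  net1 <- generate_network(spec)
  g <- igraph::graph_from_data_frame(net1[, 1:2], directed = FALSE)
  expect_equal(igraph::vcount(g), 10L)
  expect_equal(igraph::ecount(g), 2L * (10L - 2L))
  expect_identical(generate_network(spec), net1)
})

test_that("preferential attachment is heavier-tailed than Erdos-Renyi", {
  wins <- 0L
  for (s in 1:10) {
    spec <- fixture_spec(n_genes = 150, seed = s)
    pa <- generate_network(spec)
    gpa <- igraph::graph_from_data_frame(pa[, 1:2], directed = FALSE)
    set.seed(s + 1000)
    ger <- igraph::sample_gnm(igraph::vcount(gpa), igraph::ecount(gpa))
    if (max(igraph::degree(gpa)) > max(igraph::degree(ger))) wins <- wins + 1L
  }
  expect_gte(wins, 8L)
})

test_that("planted correlation structure matches its construction targets", {
  # same r in both groups: planted AvgPCC ~ 0
  spec0 <- fixture_spec(n_genes = 150, n_samples_per_group = 50,
                        r_control = 0.5, r_disease = 0.5, class_shift = 0,
                        n_planted_hubs = 3, seed = 2)
  fx0 <- generate_fixture(spec0)
  net0 <- build_disease_network(fx0$edges, rownames(fx0$expr))
  apc0 <- vapply(fx0$planted, function(h)
    hub_avg_pcc(fx0$expr, fx0$groups, net0, h)$avg_pcc, numeric(1))
  expect_lt(max(abs(apc0)), 0.15)

  # r_control 0.8 vs r_disease 0: planted AvgPCC near -0.8
  fx <- generate_fixture(fixture_spec(seed = 4))
  net <- build_disease_network(fx$edges, rownames(fx$expr))
  apc <- vapply(fx$planted, function(h)
    hub_avg_pcc(fx$expr, fx$groups, net, h)$avg_pcc, numeric(1))
  expect_true(all(abs(apc - (-0.8)) < 0.25))

  # a single generated pair at r = 0.9 over 200 samples
  spec9 <- fixture_spec(n_genes = 60, n_samples_per_group = 200,
                        r_control = 0.9, r_disease = 0.9, class_shift = 0,
                        n_planted_hubs = 1, seed = 6)
  fx9 <- generate_fixture(spec9)
  net9 <- igraph::simplify(igraph::graph_from_data_frame(fx9$edges[, 1:2],
                                                         directed = FALSE))
  h <- fx9$planted[1]
  i <- setdiff(igraph::neighbors(net9, h)$name, fx9$planted)[1]
  ctl <- names(fx9$groups)[fx9$groups == "control"]
  expect_lt(abs(cor(fx9$expr[h, ctl], fx9$expr[i, ctl]) - 0.9), 0.06)
})

test_that("planted hubs sit above the degree median and files round-trip", {
  fx <- generate_fixture(fixture_spec(seed = 8), dir = withr::local_tempdir())
  net <- igraph::graph_from_data_frame(fx$edges[, 1:2], directed = FALSE)
  deg <- igraph::degree(net)
  expect_true(all(deg[fx$planted] > median(deg)))

  eg <- read_expression(fx$paths$expr, fx$paths$groups)
  expect_equal(eg$expr, fx$expr[order(rownames(fx$expr)), ], tolerance = 1e-9)
  expect_identical(read_interactions(fx$paths$interactions, 2), fx$edges)
  back_dag <- read_obo(fx$paths$obo)
  expect_setequal(back_dag$terms$id, fx$dag$terms$id)
  expect_equal(nrow(back_dag$edges), nrow(fx$dag$edges))
  expect_identical(read_annotations(fx$paths$gaf, "P"), fx$ann[order(names(fx$ann))])
  expect_equal(read_tissue_table(fx$paths$tissues), fx$tissues, tolerance = 1e-9)
  expect_identical(read_gene_set(fx$paths$reference), fx$reference)
})

test_that("one seed fixes every generated file byte for byte", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  generate_fixture(fixture_spec(n_genes = 80, seed = 13), dir = d1)
  generate_fixture(fixture_spec(n_genes = 80, seed = 13), dir = d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
})

test_that("ontology and annotations separate planted from background coherence", {
  fx <- generate_fixture(fixture_spec(seed = 10))
  # reconstructing the DAG re-runs the acyclicity validation
  expect_silent(go_dag(fx$dag$terms, fx$dag$edges, fx$dag$weights))
  expect_equal(nrow(fx$dag$terms), 1 + 3 + 9 + 27)
  net <- build_disease_network(fx$edges, rownames(fx$expr))
  planted_med <- prioritize_by_semsim(fx$dag, fx$ann, net, fx$planted)
  bg_hubs <- setdiff(names(sort(igraph::degree(net), decreasing = TRUE)),
                     unique(c(fx$planted, unlist(lapply(fx$planted, function(h)
                       interactors_of(net, h))))))[1:6]
  bg_med <- prioritize_by_semsim(fx$dag, fx$ann, net, bg_hubs)
  expect_gt(min(planted_med$median_similarity),
            max(bg_med$median_similarity, na.rm = TRUE))
})

test_that("tissue table construction honors its stated contracts", {
  fx <- generate_fixture(fixture_spec(seed = 12))
  tf <- tissue_filter(fx$planted, fx$tissues,
                      c("whole brain", "prefrontal cortex"),
                      housekeeping = fx$housekeeping, fold = 1.5)
  expect_true(all(tf$status == "pass"))
  ratios <- apply(fx$tissues[fx$housekeeping, ], 1,
                  function(x) max(x) / median(x))
  expect_true(all(ratios < 1.5))
  expect_equal(length(intersect(fx$reference, fx$planted)),
               ceiling(length(fx$planted) / 2))
})
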