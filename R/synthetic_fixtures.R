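# Statistically controlled synthetic inputs for the whole pipeline: a
# scale-free interaction network, two-group expression with planted
# differentially co-expressed hubs, a toy ontology with coherent
# annotations for the planted neighborhoods, a tissue table, and reference
# and housekeeping gene lists.  One seed fixes every output.

#' Fixture specification
#'
#' Defaults define the standard study conditions used throughout the test
#' suite: 300 genes, 20+20 samples, 6 planted hubs whose interactor
#' correlation is 0.8 in controls and 0 in disease (the differential
#' co-expression signal), a mean shift of 1 on planted neighborhoods in
#' disease samples (the classification signal), and a depth-3 branching-3
#' toy ontology.
#'
#' @param n_genes number of genes (>= 10).
#' @param n_samples_per_group samples per group.
#' @param attachment edges added per node during preferential-attachment
#'   growth.
#' @param n_planted_hubs planted differentially co-expressed hubs.
#' @param r_control,r_disease hub-interactor correlation in each group.
#' @param class_shift mean expression shift of planted neighborhoods in
#'   disease samples.
#' @param ontology_depth,ontology_branching toy-ontology tree shape.
#' @param terms_per_gene annotation terms per gene.
#' @param n_perm default permutation count for pipeline runs on the fixture.
#' @param seed integer seed.
#' @return list of class \code{fixture_spec}.
#' @export
fixture_spec <- function(n_genes = 300, n_samples_per_group = 20,
                         attachment = 2, n_planted_hubs = 6,
                         r_control = 0.8, r_disease = 0, class_shift = 1,
                         ontology_depth = 3, ontology_branching = 3,
                         terms_per_gene = 2, n_perm = 200, seed = 1) {
  stopifnot(n_genes >= 10, n_samples_per_group >= 3,
            n_planted_hubs >= 1, n_planted_hubs <= n_genes,
            abs(r_control) < 1, abs(r_disease) < 1,
            attachment >= 1, ontology_depth >= 1, ontology_branching >= 2)
  structure(as.list(environment()), class = "fixture_spec")
}

#' Generate a scale-free interaction edge list
#'
#' Preferential-attachment growth: the first \code{attachment} nodes start
#' unconnected, and each subsequent node attaches to \code{attachment}
#' distinct existing nodes with probability proportional to degree + 1,
#' giving attachment * (n_genes - attachment) edges.  Roughly 70% of edges
#' are tagged "literature" with evidence counts of 2-5 (already passing the
#' default evidence filter); the rest are "screen" with a single evidence.
#'
#' @param spec a \code{fixture_spec}.
#' @return edge data.frame: gene_a, gene_b, evidence_count, source.
#' @export
generate_network <- function(spec) {
  set.seed(spec$seed)
  n <- spec$n_genes; m <- spec$attachment
  ids <- sprintf("G%04d", seq_len(n))
  deg <- integer(n)
  ea <- character(0); eb <- character(0)
  for (v in seq(m + 1, n)) {
    existing <- seq_len(v - 1)
    targets <- sample(existing, size = min(m, length(existing)),
                      prob = deg[existing] + 1)
    deg[targets] <- deg[targets] + 1L
    deg[v] <- deg[v] + length(targets)
    ea <- c(ea, ids[rep(v, length(targets))])
    eb <- c(eb, ids[targets])
  }
  n_edges <- length(ea)
  src <- ifelse(stats::runif(n_edges) < 0.7, "literature", "screen")
  ev <- ifelse(src == "literature", sample(2:5, n_edges, replace = TRUE), 1)
  filter_interactions(
    data.frame(gene_a = ea, gene_b = eb, evidence_count = ev, source = src,
               stringsAsFactors = FALSE),
    min_evidence = 2)
}

#' Generate two-group expression with planted rewired hubs
#'
#' Planted hubs are the top-degree nodes.  Hub profiles are i.i.d. standard
#' normal; each planted hub's (non-planted, unclaimed) interactor is the
#' linear mixture r * hub + sqrt(1 - r^2) * noise with r = r_control in
#' control samples and r_disease in disease samples, so the population
#' hub-interactor correlation equals r exactly.  Remaining genes are
#' independent noise.  \code{class_shift} is added to planted hubs and
#' their claimed interactors in disease samples, and a constant offset of 8
#' shifts everything to a positive log-intensity-like scale.
#'
#' @param spec a \code{fixture_spec}.
#' @param edges edge data.frame from \code{generate_network}.
#' @return list: \code{expr}, \code{groups}, \code{planted} (hub ids).
#' @export
generate_expression <- function(spec, edges) {
  set.seed(spec$seed + 1L)
  net <- igraph::simplify(igraph::graph_from_data_frame(
    edges[, c("gene_a", "gene_b")], directed = FALSE))
  deg <- igraph::degree(net)
  # planted hubs: greedily take the highest-degree nodes whose closed
  # neighborhoods are pairwise disjoint, so every interactor belongs to
  # exactly one planted hub and the planted correlation is not diluted by
  # overlapping neighborhoods
  planted <- character(0)
  taken <- character(0)
  for (v in names(sort(deg, decreasing = TRUE))) {
    if (length(planted) == spec$n_planted_hubs) break
    nb <- igraph::neighbors(net, v)$name
    if (v %in% taken || any(nb %in% taken)) next
    planted <- c(planted, v)
    taken <- c(taken, v, nb)
  }
  if (length(planted) < spec$n_planted_hubs) {
    stop("network too small to place ", spec$n_planted_hubs,
         " planted hubs with disjoint neighborhoods")
  }

  ns <- spec$n_samples_per_group
  samples <- c(sprintf("D%02d", seq_len(ns)), sprintf("C%02d", seq_len(ns)))
  groups <- stats::setNames(rep(c("disease", "control"), each = ns), samples)
  genes <- sprintf("G%04d", seq_len(spec$n_genes))
  expr <- matrix(stats::rnorm(length(genes) * length(samples)),
                 nrow = length(genes),
                 dimnames = list(genes, samples))
  d_col <- which(groups == "disease"); c_col <- which(groups == "control")

  claimed <- character(0)
  # low-degree hubs claim shared interactors first: the few interactors a
  # high-degree hub loses barely dilute its average
  for (h in planted[order(deg[planted])]) {
    hub_prof <- expr[h, ]
    ints <- setdiff(igraph::neighbors(net, h)$name, c(planted, claimed))
    for (i in ints) {
      eps <- expr[i, ]   # the gene's own independent noise
      expr[i, d_col] <- spec$r_disease * hub_prof[d_col] +
        sqrt(1 - spec$r_disease^2) * eps[d_col]
      expr[i, c_col] <- spec$r_control * hub_prof[c_col] +
        sqrt(1 - spec$r_control^2) * eps[c_col]
    }
    claimed <- c(claimed, ints)
  }
  shifted <- unique(c(planted, claimed))
  expr[shifted, d_col] <- expr[shifted, d_col] + spec$class_shift
  expr <- expr + 8
  list(expr = expression_matrix(expr), groups = groups, planted = planted)
}

#' Generate a toy ontology and gene annotations
#'
#' The ontology is a rooted complete tree of the specified depth and
#' branching (is_a edges) plus about 10% extra is_a edges from deeper to
#' strictly shallower terms (the graph stays acyclic).  Planted hubs and
#' their interactors are annotated coherently, with terms drawn from the
#' leaves of a single deepest-level subtree; all other genes draw terms
#' uniformly from all leaves.
#'
#' @param spec a \code{fixture_spec}.
#' @param edges edge data.frame (supplies the planted hubs' interactors).
#' @param planted planted hub ids.
#' @return list: \code{dag} (a \code{go_dag}), \code{ann} (annotation map).
#' @export
generate_ontology <- function(spec, edges, planted) {
  set.seed(spec$seed + 2L)
  B <- spec$ontology_branching; D <- spec$ontology_depth
  n_terms <- sum(B^(0:D))
  ids <- sprintf("GO:%07d", seq_len(n_terms))
  depth <- rep(0:D, times = B^(0:D))
  terms <- data.frame(id = ids, name = paste0("term ", seq_len(n_terms)),
                      namespace = "biological_process",
                      stringsAsFactors = FALSE)
  child <- ids[-1]
  parent <- ids[((seq_len(n_terms - 1) - 1) %/% B) + 1]
  edges_df <- data.frame(child = child, parent = parent, relation = "is_a",
                         stringsAsFactors = FALSE)
  n_extra <- max(1L, round(0.1 * nrow(edges_df)))
  for (i in seq_len(n_extra)) {
    c_i <- sample(which(depth >= 2), 1)
    p_cand <- which(depth < depth[c_i] & ids != parent[c_i - 1L])
    p_i <- sample(p_cand, 1)
    edges_df <- rbind(edges_df, data.frame(child = ids[c_i], parent = ids[p_i],
                                           relation = "is_a"))
  }
  edges_df <- unique(edges_df)
  dag <- go_dag(terms, edges_df, weights = c(is_a = 0.8, part_of = 0.6))

  leaves <- ids[depth == D]
  # coherent pool: the leaves below one depth-(D-1) term, plus that term
  first_parent <- parent[match(leaves, child)]
  coherent_pool <- leaves[first_parent == first_parent[1]]
  net <- igraph::simplify(igraph::graph_from_data_frame(
    edges[, c("gene_a", "gene_b")], directed = FALSE))
  coherent_genes <- unique(c(planted, unlist(lapply(planted, function(h)
    igraph::neighbors(net, h)$name))))
  genes <- sprintf("G%04d", seq_len(spec$n_genes))
  ann <- lapply(genes, function(g) {
    pool <- if (g %in% coherent_genes) coherent_pool else leaves
    sort(unique(sample(pool, spec$terms_per_gene, replace = TRUE)))
  })
  names(ann) <- genes
  list(dag = dag, ann = ann)
}

#' Generate a tissue table plus housekeeping and reference gene lists
#'
#' Ten tissues including "whole brain" and "prefrontal cortex".  Planted
#' genes are brain-enriched (5x their cross-tissue baseline); housekeeping
#' genes (a random tenth of the non-planted genes) are uniformly high with
#' max/median ratio below 1.5; all other genes fluctuate around a flat
#' baseline.  The reference list contains half the planted hubs (rounded
#' up) plus 20 random non-planted decoys.
#'
#' @param spec a \code{fixture_spec}.
#' @param planted planted hub ids.
#' @return list: \code{tissues} (matrix), \code{housekeeping},
#'   \code{reference} (character vectors).
#' @export
generate_tissue_table <- function(spec, planted) {
  set.seed(spec$seed + 3L)
  tissue_names <- c("whole brain", "prefrontal cortex", "liver", "kidney",
                    "heart", "lung", "spleen", "muscle", "pancreas", "thymus")
  genes <- sprintf("G%04d", seq_len(spec$n_genes))
  base <- matrix(stats::runif(length(genes) * 10, min = 8, max = 12),
                 nrow = length(genes), dimnames = list(genes, tissue_names))
  nonplanted <- setdiff(genes, planted)
  housekeeping <- sort(sample(nonplanted, max(1L, length(nonplanted) %/% 10)))
  base[housekeeping, ] <- matrix(
    rep(stats::runif(length(housekeeping), 40, 60), 10), ncol = 10)
  brain <- c("whole brain", "prefrontal cortex")
  for (g in planted) {
    base[g, brain] <- 5 * stats::median(base[g, ])
  }
  n_ref_planted <- ceiling(length(planted) / 2)
  reference <- sort(c(planted[seq_len(n_ref_planted)],
                      sample(setdiff(nonplanted, housekeeping), 20)))
  list(tissues = base, housekeeping = housekeeping, reference = reference)
}

#' Generate the complete fixture, optionally writing all files
#'
#' @param spec a \code{fixture_spec}.
#' @param dir optional output directory; when given, every component is
#'   written in its standard on-disk format (TSV, OBO, GAF, gene lists)
#'   plus \code{ground_truth.tsv} listing the planted hubs.
#' @return list of class \code{fixture}: edges, expr, groups, planted, dag,
#'   ann, tissues, housekeeping, reference, spec, and (if written) paths.
#' @export
generate_fixture <- function(spec = fixture_spec(), dir = NULL) {
  edges <- generate_network(spec)
  ex <- generate_expression(spec, edges)
  onto <- generate_ontology(spec, edges, ex$planted)
  tis <- generate_tissue_table(spec, ex$planted)
  fx <- structure(list(edges = edges, expr = ex$expr, groups = ex$groups,
                       planted = ex$planted, dag = onto$dag, ann = onto$ann,
                       tissues = tis$tissues,
                       housekeeping = tis$housekeeping,
                       reference = tis$reference, spec = spec),
                  class = "fixture")
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(
      expr = file.path(dir, "expression.tsv"),
      groups = file.path(dir, "groups.tsv"),
      interactions = file.path(dir, "interactions.tsv"),
      obo = file.path(dir, "ontology.obo"),
      gaf = file.path(dir, "annotations.gaf"),
      tissues = file.path(dir, "tissues.tsv"),
      housekeeping = file.path(dir, "housekeeping.txt"),
      reference = file.path(dir, "reference.txt"),
      ground_truth = file.path(dir, "ground_truth.tsv"))
    write_expression(fx$expr, fx$groups, paths$expr, paths$groups)
    write_interactions(fx$edges, paths$interactions)
    write_obo(fx$dag, paths$obo)
    write_gaf(fx$ann, paths$gaf)
    write_tissue_table(fx$tissues, paths$tissues)
    write_gene_set(fx$housekeeping, paths$housekeeping)
    write_gene_set(fx$reference, paths$reference)
    utils::write.table(data.frame(gene_id = fx$planted, planted = TRUE),
                       paths$ground_truth, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    fx$paths <- paths
  }
  fx
}

#' @export
print.fixture <- function(x, ...) {
  cat(sprintf(paste0("Synthetic fixture: %d genes, %d+%d samples, %d edges, ",
                     "%d planted hubs, %d GO terms (seed %d)\n"),
              x$spec$n_genes, x$spec$n_samples_per_group,
              x$spec$n_samples_per_group, nrow(x$edges),
              length(x$planted), nrow(x$dag$terms), x$spec$seed))
  invisible(x)
}
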