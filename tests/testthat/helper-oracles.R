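# Independent brute-force oracles used to cross-check the implementation.
# These deliberately avoid the code paths (and, where possible, the
# libraries) used by the package itself.

# Normalized betweenness by matrix-power path counting: walks of length
# equal to the graph distance are exactly the shortest paths, so A^L gives
# shortest-path counts at L = dist(s, t).
oracle_betweenness <- function(adj) {
  n <- nrow(adj)
  if (n < 3) return(rep(0, n))
  pows <- list(diag(n), adj)
  for (L in 2:n) pows[[L + 1]] <- pows[[L]] %*% adj
  dist <- matrix(Inf, n, n)
  for (L in 0:n) {
    newly <- pows[[L + 1]] > 0 & !is.finite(dist)
    dist[newly] <- L
  }
  npaths <- function(s, t) {
    if (!is.finite(dist[s, t])) return(0)
    pows[[dist[s, t] + 1]][s, t]
  }
  btw <- numeric(n)
  for (v in seq_len(n)) {
    for (s in seq_len(n - 1)) {
      for (t in seq(s + 1, n)) {
        if (s == v || t == v || !is.finite(dist[s, t])) next
        if (is.finite(dist[s, v]) && is.finite(dist[v, t]) &&
            dist[s, v] + dist[v, t] == dist[s, t]) {
          btw[v] <- btw[v] + npaths(s, v) * npaths(v, t) / npaths(s, t)
        }
      }
    }
  }
  btw / ((n - 1) * (n - 2) / 2)
}

# Wang S-value by exhaustive path enumeration: S_A(t) is the maximum over
# all directed paths from A to t of the product of edge weights.
oracle_svalue <- function(dag, a, t) {
  if (a == t) return(1)
  pe <- dag$parents[[a]]
  if (is.null(pe)) return(NA_real_)
  best <- NA_real_
  for (j in seq_len(nrow(pe))) {
    sub <- oracle_svalue(dag, pe$parent[j], t)
    if (!is.na(sub)) {
      cand <- dag$weights[[pe$relation[j]]] * sub
      if (is.na(best) || cand > best) best <- cand
    }
  }
  best
}

# AUC by exhaustive pairwise comparison, ties counted one half.
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == "disease"]
  neg <- scores[labels == "control"]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

# Pearson correlation from the definition (no stats::cor).
oracle_cor <- function(x, y) {
  xc <- x - mean(x); yc <- y - mean(y)
  sum(xc * yc) / sqrt(sum(xc^2) * sum(yc^2))
}

# AvgPCC by explicit per-interactor loops.
oracle_avg_pcc <- function(expr, groups, hub, interactors) {
  d <- names(groups)[groups == "disease"]
  co <- names(groups)[groups == "control"]
  mean(vapply(interactors, function(i) {
    oracle_cor(expr[hub, d], expr[i, d]) - oracle_cor(expr[hub, co], expr[i, co])
  }, numeric(1)))
}

# Regularized t from the definition, for the brute-force DE checks.
oracle_sam_d <- function(x_d, x_c, s0) {
  n1 <- length(x_d); n2 <- length(x_c)
  sp2 <- (sum((x_d - mean(x_d))^2) + sum((x_c - mean(x_c))^2)) / (n1 + n2 - 2)
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  (mean(x_d) - mean(x_c)) / (se + s0)
}

# ---- shared tiny fixtures -------------------------------------------------

# Chain A is_a P is_a R plus sibling B is_a R (w = 0.8): the hand-worked
# similarity examples live on this DAG.
toy_dag <- function() {
  go_dag(
    terms = data.frame(id = c("R", "P", "A", "B"),
                       name = c("root", "parent", "a", "b"),
                       namespace = "biological_process"),
    edges = data.frame(child = c("P", "A", "B"),
                       parent = c("R", "P", "R"),
                       relation = "is_a"),
    weights = c(is_a = 0.8, part_of = 0.6))
}

# Complete B-ary tree of is_a edges, depth D; returns the go_dag plus the
# leaf ids grouped by their parent.
tree_dag <- function(depth = 3, branching = 3, w = 0.8) {
  n_terms <- sum(branching^(0:depth))
  ids <- sprintf("T%03d", seq_len(n_terms))
  child <- ids[-1]
  parent <- ids[((seq_len(n_terms - 1) - 1) %/% branching) + 1]
  dag <- go_dag(
    terms = data.frame(id = ids, name = ids, namespace = "biological_process"),
    edges = data.frame(child = child, parent = parent, relation = "is_a"),
    weights = c(is_a = w, part_of = 0.6))
  depth_of <- rep(0:depth, times = branching^(0:depth))
  leaves <- ids[depth_of == depth]
  list(dag = dag, ids = ids, leaves = leaves,
       leaf_parent = parent[match(leaves, child)])
}

# Annotation-coherence fixture: n_hubs disjoint stars (k interactors each);
# the first n_coherent hubs and their interactors draw 2 terms from the
# 3 leaves under one deepest-level parent, all other genes draw 2 terms
# uniformly from all 27 leaves.
coherence_fixture <- function(n_hubs = 30, n_coherent = 10, k = 6, seed = 1) {
  set.seed(seed)
  td <- tree_dag()
  hubs <- sprintf("H%02d", seq_len(n_hubs))
  edges <- do.call(rbind, lapply(seq_len(n_hubs), function(i) {
    data.frame(gene_a = hubs[i],
               gene_b = sprintf("H%02d_I%d", i, seq_len(k)),
               evidence_count = 2, source = "literature")
  }))
  net <- build_disease_network(edges, unique(c(edges$gene_a, edges$gene_b)))
  pool <- td$leaves[td$leaf_parent == td$leaf_parent[1]]
  genes <- unique(c(edges$gene_a, edges$gene_b))
  coherent_genes <- unlist(lapply(seq_len(n_coherent), function(i)
    c(hubs[i], sprintf("H%02d_I%d", i, seq_len(k)))))
  ann <- lapply(genes, function(g) {
    p <- if (g %in% coherent_genes) pool else td$leaves
    sort(unique(sample(p, 2, replace = TRUE)))
  })
  names(ann) <- genes
  list(dag = td$dag, ann = ann, net = net, hubs = hubs,
       coherent = hubs[seq_len(n_coherent)])
}

# Random simple undirected graph as an igraph with G-names plus its
# adjacency matrix, for oracle comparisons.
random_graph <- function(n, p = 0.15) {
  adj <- matrix(0L, n, n)
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    if (stats::runif(1) < p) adj[i, j] <- adj[j, i] <- 1L
  }
  ids <- sprintf("N%02d", seq_len(n))
  dimnames(adj) <- list(ids, ids)
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  list(g = g, adj = adj, ids = ids)
}

# Small two-group expression fixture with optional planted mean shift.
tiny_expr <- function(n_genes = 6, n_per_group = 3, seed = 1, shift = 0) {
  set.seed(seed)
  samples <- c(sprintf("D%d", seq_len(n_per_group)),
               sprintf("C%d", seq_len(n_per_group)))
  expr <- matrix(rnorm(n_genes * 2 * n_per_group),
                 nrow = n_genes,
                 dimnames = list(sprintf("g%d", seq_len(n_genes)), samples))
  expr[1, seq_len(n_per_group)] <- expr[1, seq_len(n_per_group)] + shift
  groups <- setNames(rep(c("disease", "control"), each = n_per_group), samples)
  list(expr = expr, groups = groups)
}
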