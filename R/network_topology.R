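# Disease-specific network construction and hub detection.  Hubs are nodes
# whose degree exceeds mean + 2*sd of the degree distribution, or whose
# betweenness centrality lies in the top fraction (default 50%) of the
# nonzero betweenness values ("bottlenecks").

#' Build the disease-specific interaction network
#'
#' Takes the induced subgraph of the interaction edge list on the
#' differentially expressed genes (both endpoints must be DE), simplifies it
#' to an undirected simple graph, and removes isolated nodes.
#'
#' @param edges edge data.frame (columns gene_a, gene_b) from
#'   \code{read_interactions}.
#' @param de_genes character vector of DE gene ids.
#' @return an \code{igraph} undirected simple graph.
#' @export
build_disease_network <- function(edges, de_genes) {
  keep <- edges$gene_a %in% de_genes & edges$gene_b %in% de_genes
  sub <- edges[keep, c("gene_a", "gene_b"), drop = FALSE]
  if (nrow(sub) == 0L) {
    warning("disease-specific network is empty")
    return(igraph::make_empty_graph(0, directed = FALSE))
  }
  g <- igraph::graph_from_data_frame(sub, directed = FALSE)
  g <- igraph::simplify(g)
  igraph::delete_vertices(g, igraph::V(g)[igraph::degree(g) == 0])
}

#' Degree cutoff for hub selection
#'
#' The cutoff is mean(k) + 2 * sd(k) over all nodes of the network, with the
#' sample (n-1) standard deviation.  Degree hubs are nodes whose degree is
#' strictly greater than the cutoff, so a regular graph (sd = 0) yields none.
#'
#' @param net igraph network with at least 2 nodes, or a numeric degree
#'   vector.
#' @return numeric cutoff.
#' @export
degree_hub_cutoff <- function(net) {
  k <- if (is.numeric(net)) net else igraph::degree(net)
  if (length(k) < 2L) stop("degree cutoff needs at least 2 nodes")
  mean(k) + 2 * stats::sd(k)
}

#' Normalized betweenness centrality
#'
#' Shortest-path betweenness over unordered pairs, normalized by
#' (N-1)(N-2)/2 so values lie in [0, 1]; node pairs in different components
#' contribute no paths.
#'
#' @param net igraph network.
#' @return named numeric vector, one value per node.
#' @export
betweenness_norm <- function(net) {
  n <- igraph::vcount(net)
  if (n < 3L) return(stats::setNames(rep(0, n), igraph::V(net)$name))
  b <- igraph::betweenness(net, directed = FALSE, normalized = TRUE)
  stats::setNames(as.numeric(b), igraph::V(net)$name)
}

#' Select hub genes by degree and betweenness rules
#'
#' A node is a degree hub when its degree strictly exceeds
#' \code{degree_hub_cutoff}; a bottleneck when its normalized betweenness is
#' at least the (1 - bottleneck_quantile) quantile of the \emph{positive}
#' betweenness values (nodes with zero betweenness are never bottlenecks;
#' ties at the quantile all pass).  A hub is either.
#'
#' @param net igraph disease network.
#' @param bottleneck_quantile fraction of the positive betweenness
#'   distribution counted as "top" (default 0.5).
#' @return data.frame (one row per node): gene_id, degree, betweenness_norm,
#'   is_degree_hub, is_bottleneck, is_hub; with a \code{"summary"} attribute
#'   recording node/edge counts, mean and sd of degree, global clustering
#'   coefficient and mean betweenness.
#' @export
select_hubs <- function(net, bottleneck_quantile = 0.5) {
  stopifnot(bottleneck_quantile > 0, bottleneck_quantile < 1)
  k <- igraph::degree(net)
  btw <- betweenness_norm(net)
  cutoff <- if (length(k) >= 2L) degree_hub_cutoff(net) else Inf
  is_degree_hub <- k > cutoff
  pos <- btw[btw > 0]
  if (length(pos) > 0L) {
    thr <- stats::quantile(pos, probs = 1 - bottleneck_quantile,
                           names = FALSE, type = 7)
    is_bottleneck <- btw > 0 & btw >= thr
  } else {
    is_bottleneck <- rep(FALSE, length(btw))
  }
  out <- data.frame(
    gene_id = igraph::V(net)$name,
    degree = as.integer(k),
    betweenness_norm = as.numeric(btw),
    is_degree_hub = unname(is_degree_hub),
    is_bottleneck = unname(is_bottleneck),
    stringsAsFactors = FALSE, row.names = NULL)
  out$is_hub <- out$is_degree_hub | out$is_bottleneck
  attr(out, "summary") <- list(
    n_nodes = igraph::vcount(net),
    n_edges = igraph::ecount(net),
    avg_degree = mean(k),
    sd_degree = if (length(k) >= 2L) stats::sd(k) else NA_real_,
    degree_cutoff = cutoff,
    clustering_coefficient = igraph::transitivity(net, type = "global"),
    mean_betweenness = mean(btw))
  out
}

#' Interactors (first neighbors) of a node
#' @param net igraph network.
#' @param gene node name.
#' @return character vector of neighbor names.
#' @export
interactors_of <- function(net, gene) {
  if (!gene %in% igraph::V(net)$name) return(character())
  igraph::neighbors(net, gene)$name
}
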