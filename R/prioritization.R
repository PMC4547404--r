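# Combining the two hub-prioritization routes (differential co-expression
# and semantic similarity) and evaluating the resulting candidate list:
# reference overlap, tissue-specificity filtering, and hypergeometric GO
# over-representation with ancestor propagation.

#' Combine Step-1 and Step-2 hub selections
#'
#' The prioritized list is the union of the two selections, tagged with
#' provenance.  Ordering is deterministic: genes found by both routes first,
#' then descending |AvgPCC| where available, then gene id.
#'
#' @param netvar_sel gene ids selected by the network-variation test.
#' @param semsim_sel gene ids selected by semantic similarity.
#' @param avg_pcc optional named numeric vector of AvgPCC values used for
#'   ordering.
#' @return data.frame: gene_id, provenance ("both", "netvar", "semsim").
#' @export
combine_hubs <- function(netvar_sel, semsim_sel, avg_pcc = NULL) {
  netvar_sel <- unique(as.character(netvar_sel))
  semsim_sel <- unique(as.character(semsim_sel))
  all_genes <- union(netvar_sel, semsim_sel)
  prov <- ifelse(all_genes %in% netvar_sel & all_genes %in% semsim_sel, "both",
                 ifelse(all_genes %in% netvar_sel, "netvar", "semsim"))
  apc <- rep(NA_real_, length(all_genes))
  if (!is.null(avg_pcc)) apc <- unname(avg_pcc[all_genes])
  ord <- order(prov != "both", -abs(ifelse(is.na(apc), -Inf, apc)), all_genes)
  out <- data.frame(gene_id = all_genes, provenance = prov, avg_pcc = apc,
                    stringsAsFactors = FALSE)[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Overlap of the prioritized list with a reference gene set
#'
#' @param prioritized character vector (or combine_hubs data.frame) of
#'   prioritized gene ids.
#' @param reference character vector of reference disease genes.
#' @return character vector of shared genes, with attributes
#'   \code{n_prioritized} and \code{n_reference}.
#' @export
reference_overlap <- function(prioritized, reference) {
  if (is.data.frame(prioritized)) prioritized <- prioritized$gene_id
  hits <- intersect(prioritized, reference)
  attr(hits, "n_prioritized") <- length(unique(prioritized))
  attr(hits, "n_reference") <- length(unique(reference))
  hits
}

#' Tissue-specificity filter for prioritized genes
#'
#' A gene passes when, in at least one target tissue, its expression is at
#' least \code{fold} times its median expression across all tissues.
#' Housekeeping genes (broadly expressed) are reported separately and do not
#' pass as tissue-specific; genes absent from the table are flagged
#' unmeasured.
#'
#' @param prioritized character vector (or combine_hubs data.frame).
#' @param tissues genes x tissues matrix from \code{read_tissue_table}.
#' @param targets target tissue names (must be columns of \code{tissues}).
#' @param housekeeping character vector of housekeeping gene ids.
#' @param fold fold-change over the per-gene cross-tissue median (default 1.5).
#' @return data.frame: gene_id, status ("pass", "fail", "housekeeping",
#'   "unmeasured"), max_target_ratio.
#' @export
tissue_filter <- function(prioritized, tissues, targets,
                          housekeeping = character(), fold = 1.5) {
  if (is.data.frame(prioritized)) prioritized <- prioritized$gene_id
  stopifnot(fold > 0)
  missing_t <- setdiff(targets, colnames(tissues))
  if (length(missing_t) > 0L) {
    stop("target tissue(s) not in table: ", paste(missing_t, collapse = ", "))
  }
  rows <- lapply(prioritized, function(g) {
    if (!g %in% rownames(tissues)) {
      return(data.frame(gene_id = g, status = "unmeasured",
                        max_target_ratio = NA_real_, stringsAsFactors = FALSE))
    }
    prof <- tissues[g, ]
    med <- stats::median(prof)
    ratio <- if (med > 0) max(prof[targets]) / med else
      ifelse(max(prof[targets]) > 0, Inf, 0)
    status <- if (g %in% housekeeping) "housekeeping"
      else if (ratio >= fold) "pass" else "fail"
    data.frame(gene_id = g, status = status, max_target_ratio = ratio,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Annotation sets propagated to ancestors: a gene annotated to t is counted
# for every ancestor of t (the true-path rule).
propagate_annotations <- function(dag, ann) {
  terms <- unique(unlist(ann, use.names = FALSE))
  closure <- stats::setNames(lapply(terms, function(t)
    names(semantic_profile(dag, t)$s)), terms)
  lapply(ann, function(ts) {
    if (length(ts) == 0L) return(character())
    sort(unique(unlist(closure[ts], use.names = FALSE)))
  })
}

#' GO over-representation by the hypergeometric test
#'
#' Annotations are propagated to ancestor terms, then each term with at
#' least one background annotation is tested with the one-sided
#' hypergeometric upper tail (probability of observing at least the seen
#' number of list genes), followed by Benjamini-Hochberg adjustment.
#'
#' @param genes gene list to test (must be a subset of \code{background}).
#' @param background background gene ids (the "genome").
#' @param ann annotation map.
#' @param dag a \code{go_dag} (used for ancestor propagation).
#' @param alpha adjusted-p cutoff used for the \code{enriched} flag.
#' @return data.frame: term_id, list_count, list_size, background_count,
#'   background_size, p_value, adjusted_p, enriched; ordered by p_value.
#' @export
go_enrichment <- function(genes, background, ann, dag, alpha = 0.05) {
  genes <- unique(as.character(genes))
  background <- unique(as.character(background))
  if (length(setdiff(genes, background)) > 0L) {
    stop("gene list must be a subset of the background")
  }
  if (length(genes) == 0L) {
    return(data.frame(term_id = character(), list_count = integer(),
                      list_size = integer(), background_count = integer(),
                      background_size = integer(), p_value = numeric(),
                      adjusted_p = numeric(), enriched = logical()))
  }
  prop <- propagate_annotations(dag, ann[intersect(names(ann), background)])
  term_genes <- list()
  for (g in names(prop)) for (t in prop[[g]]) term_genes[[t]] <- c(term_genes[[t]], g)
  N <- length(background); n <- length(genes)
  rows <- lapply(names(term_genes), function(t) {
    tg <- unique(term_genes[[t]])
    K <- length(tg)
    k <- length(intersect(tg, genes))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term_id = t, list_count = k, list_size = n,
               background_count = K, background_size = N, p_value = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$adjusted_p <- stats::p.adjust(out$p_value, method = "BH")
  out$enriched <- out$adjusted_p <= alpha
  out <- out[order(out$p_value, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
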