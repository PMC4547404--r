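# Wang's semantic similarity on the GO DAG.  Each term A induces S-values
# over its ancestor closure T_A: S_A(A) = 1 and, moving rootward,
# S_A(t) = max over children c of t on paths toward A of w_e * S_A(c),
# with w_e the semantic contribution weight of the child->parent relation.
# Term similarity is the weight of the shared ancestors relative to the two
# terms' total semantic values; gene similarity aggregates term pairs.

#' Semantic profile (S-values) of a term
#'
#' @param dag a \code{go_dag}.
#' @param term term id.
#' @return list: \code{s} (named numeric, S_A(t) for every t in the ancestor
#'   closure of \code{term}, including itself) and \code{sv} (their sum, the
#'   term's semantic value).
#' @export
semantic_profile <- function(dag, term) {
  if (!term %in% dag$terms$id) stop("unknown term: ", term)
  s <- stats::setNames(1, term)
  queue <- term
  while (length(queue) > 0L) {
    child <- queue[[1]]; queue <- queue[-1]
    pe <- dag$parents[[child]]
    if (is.null(pe)) next
    for (j in seq_len(nrow(pe))) {
      p <- pe$parent[j]
      cand <- dag$weights[[pe$relation[j]]] * s[[child]]
      if (is.na(s[p]) || cand > s[[p]]) {
        s[p] <- cand
        queue <- c(queue, p)   # re-relax ancestors of p with the larger value
      }
    }
  }
  list(s = s, sv = sum(s))
}

#' Wang similarity between two terms
#'
#' S_GO(A, B) = sum over shared ancestors t of (S_A(t) + S_B(t)) divided by
#' (sv(A) + sv(B)); symmetric, 1 for identical terms, 0 (with a warning)
#' when the ancestor closures are disjoint (different roots).
#'
#' @param dag a \code{go_dag}.
#' @param a,b term ids.
#' @param profiles optional named list of precomputed semantic profiles.
#' @return similarity in [0, 1].
#' @export
term_similarity <- function(dag, a, b, profiles = NULL) {
  pa <- profiles[[a]] %||% semantic_profile(dag, a)
  pb <- profiles[[b]] %||% semantic_profile(dag, b)
  shared <- intersect(names(pa$s), names(pb$s))
  if (length(shared) == 0L) {
    warning("terms ", a, " and ", b, " share no ancestor (different roots)")
    return(0)
  }
  sum(pa$s[shared] + pb$s[shared]) / (pa$sv + pb$sv)
}

# Precompute profiles for a set of terms (one DP pass per term).
profile_cache <- function(dag, terms) {
  stats::setNames(lapply(terms, function(t) semantic_profile(dag, t)), terms)
}

#' Semantic similarity between two genes
#'
#' Combines term-level similarities over the genes' annotation sets:
#' \code{"all_pairs_avg"} averages S_GO over the full cross product of the
#' two term sets; \code{"best_match_avg"} averages each term's best match in
#' the other set (the rule used by common GO-similarity software).
#'
#' @param dag a \code{go_dag}.
#' @param ann annotation map (named list gene -> term ids).
#' @param g1,g2 gene ids; both must be annotated with at least one term.
#' @param combine "all_pairs_avg" (default) or "best_match_avg".
#' @param profiles optional precomputed profile cache.
#' @return similarity in [0, 1].
#' @export
gene_similarity <- function(dag, ann, g1, g2,
                            combine = c("all_pairs_avg", "best_match_avg"),
                            profiles = NULL) {
  combine <- match.arg(combine)
  t1 <- ann[[g1]]; t2 <- ann[[g2]]
  if (length(t1) == 0L || length(t2) == 0L) {
    stop("gene similarity undefined for unannotated gene: ",
         if (length(t1) == 0L) g1 else g2)
  }
  if (is.null(profiles)) profiles <- profile_cache(dag, unique(c(t1, t2)))
  m <- matrix(0, length(t1), length(t2))
  for (i in seq_along(t1)) {
    for (j in seq_along(t2)) {
      m[i, j] <- term_similarity(dag, t1[i], t2[j], profiles)
    }
  }
  if (combine == "all_pairs_avg") {
    mean(m)
  } else {
    (sum(apply(m, 1, max)) + sum(apply(m, 2, max))) / (length(t1) + length(t2))
  }
}

#' Prioritize hubs by median hub-interactor semantic similarity
#'
#' For each hub, the gene similarity to every annotated interactor is
#' computed (unannotated interactors are skipped) and the median taken; the
#' hub is selected when the median is strictly greater than the threshold.
#' Hubs that are unannotated, or whose interactors all are, are excluded
#' (flagged, median NA) rather than scored.
#'
#' @param dag a \code{go_dag}.
#' @param ann annotation map.
#' @param net igraph network supplying interactors.
#' @param hubs character vector of hub ids.
#' @param threshold selection cutoff on the median similarity (default 0.5,
#'   strict greater-than).
#' @param combine term-combination rule, see \code{gene_similarity}.
#' @return data.frame: hub_id, n_scored_interactors, median_similarity,
#'   selected, excluded.
#' @export
prioritize_by_semsim <- function(dag, ann, net, hubs, threshold = 0.5,
                                 combine = c("all_pairs_avg", "best_match_avg")) {
  stopifnot(threshold >= 0, threshold <= 1)
  combine <- match.arg(combine)
  annotated <- names(ann)[vapply(ann, length, 0L) > 0L]
  need <- unique(unlist(ann[intersect(
    annotated, unique(c(hubs, unlist(lapply(hubs, function(h)
      interactors_of(net, h))))))], use.names = FALSE))
  profiles <- profile_cache(dag, need)
  rows <- lapply(hubs, function(h) {
    ints <- setdiff(intersect(interactors_of(net, h), annotated), h)
    if (!h %in% annotated || length(ints) == 0L) {
      return(data.frame(hub_id = h, n_scored_interactors = 0L,
                        median_similarity = NA_real_, selected = FALSE,
                        excluded = TRUE, stringsAsFactors = FALSE))
    }
    sims <- vapply(ints, function(i) {
      gene_similarity(dag, ann, h, i, combine, profiles)
    }, numeric(1))
    med <- stats::median(sims)
    data.frame(hub_id = h, n_scored_interactors = length(ints),
               median_similarity = med, selected = med > threshold,
               excluded = FALSE, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
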