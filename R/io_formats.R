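# Readers and writers for every external format the pipeline touches:
# expression TSV + group labels, interaction edge lists (TSV or SIF),
# OBO 1.2 ontologies, GAF 2.x annotations, tissue tables and gene lists.
# All downstream modules operate on the in-memory types built here.

#' Construct a validated expression matrix
#'
#' An expression matrix is a plain numeric matrix with unique gene row names
#' and unique sample column names.  Values are taken as given (assumed
#' normalized, log-scale); the constructor only validates.
#'
#' @param values numeric matrix with rownames (genes) and colnames (samples).
#' @return the validated matrix, invisibly classed as given.
#' @export
expression_matrix <- function(values) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("expression values must be a numeric matrix")
  }
  if (nrow(values) == 0L || ncol(values) == 0L) stop("expression matrix is empty")
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("expression matrix needs gene rownames and sample colnames")
  }
  if (anyDuplicated(rownames(values))) {
    stop("duplicate gene identifiers: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  }
  if (anyDuplicated(colnames(values))) stop("duplicate sample identifiers")
  bad <- which(!is.finite(values), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf("non-finite expression value at gene '%s', sample '%s'",
                 rownames(values)[bad[1, 1]], colnames(values)[bad[1, 2]]))
  }
  values
}

#' Construct validated sample group labels
#'
#' @param labels named character vector, one entry per sample, values
#'   \code{"disease"} or \code{"control"}.
#' @param samples optional sample ids the labels must cover (typically the
#'   colnames of the expression matrix).
#' @return named character vector in the order of \code{samples} if given.
#' @export
sample_groups <- function(labels, samples = NULL) {
  if (is.null(names(labels))) stop("group labels must be named by sample id")
  bad <- setdiff(unique(labels), c("disease", "control"))
  if (length(bad) > 0L) {
    stop("unknown group label(s): ", paste(bad, collapse = ", "),
         " (expected 'disease' or 'control')")
  }
  if (!is.null(samples)) {
    missing <- setdiff(samples, names(labels))
    if (length(missing) > 0L) {
      stop("sample(s) without a group label: ", paste(missing, collapse = ", "))
    }
    labels <- labels[samples]
  }
  if (!all(c("disease", "control") %in% labels)) {
    stop("both a disease and a control group are required")
  }
  labels
}

#' Read an expression matrix and its sample groups
#'
#' The matrix file is TSV with a header row of sample ids and a first column
#' of gene (or probe) identifiers.  Rows sharing an identifier are collapsed
#' by the arithmetic mean, the standard treatment when several probes map to
#' one gene.  The groups file has two columns: sample id and group label.
#'
#' @param path_matrix path to the expression TSV.
#' @param path_groups path to the two-column group file (TSV, no header
#'   required; a header line \code{sample<TAB>group} is tolerated).
#' @return list with elements \code{expr} (genes x samples numeric matrix)
#'   and \code{groups} (named character vector).
#' @export
read_expression <- function(path_matrix, path_groups) {
  tab <- utils::read.delim(path_matrix, header = TRUE, check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (nrow(tab) == 0L || ncol(tab) < 2L) stop("empty expression matrix: ", path_matrix)
  ids <- as.character(tab[[1]])
  vals <- as.matrix(tab[, -1, drop = FALSE])
  if (!is.numeric(vals)) {
    num <- matrix(suppressWarnings(as.numeric(as.matrix(tab[, -1, drop = FALSE]))),
                  nrow = nrow(tab))
    bad <- which(is.na(num), arr.ind = TRUE)
    stop(sprintf("non-numeric expression cell at row %d (gene '%s'), column '%s'",
                 bad[1, 1], ids[bad[1, 1]], colnames(tab)[-1][bad[1, 2]]))
  }
  storage.mode(vals) <- "double"
  rownames(vals) <- ids
  vals <- collapse_probes(vals)

  gtab <- utils::read.delim(path_groups, header = FALSE, stringsAsFactors = FALSE)
  if (identical(tolower(as.character(gtab[1, 1])), "sample")) gtab <- gtab[-1, , drop = FALSE]
  labels <- stats::setNames(as.character(gtab[[2]]), as.character(gtab[[1]]))
  groups <- sample_groups(labels, samples = colnames(vals))
  list(expr = expression_matrix(vals), groups = groups)
}

# Collapse duplicate gene rows by the arithmetic mean.  Rows are sorted by
# gene id so the result is independent of input row order.
collapse_probes <- function(vals) {
  g <- factor(rownames(vals))
  out <- rowsum(vals, group = g) / as.vector(table(g))
  out[order(rownames(out)), , drop = FALSE]
}

#' Write an expression matrix and groups back to TSV
#' @param expr genes x samples numeric matrix.
#' @param groups named group vector.
#' @param path_matrix,path_groups output paths.
#' @export
write_expression <- function(expr, groups, path_matrix, path_groups) {
  df <- data.frame(gene = rownames(expr), expr, check.names = FALSE)
  utils::write.table(df, path_matrix, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(sample = names(groups), group = unname(groups)),
                     path_groups, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(NULL)
}

#' Read a protein-interaction edge list with evidence filtering
#'
#' TSV input has columns \code{gene_a}, \code{gene_b}, \code{evidence_count},
#' \code{source}; SIF input (extension \code{.sif}) has two or three
#' whitespace-separated columns (\code{a b} or \code{a relation b}) and is
#' imported with evidence count 1 and source \code{"sif"}.
#'
#' Self-loops are dropped.  Duplicate unordered pairs are merged: evidence
#' counts from the same source are summed; across sources the maximum count
#' is kept and the pair tagged \code{"both"}.  Literature-curated pairs
#' require \code{min_evidence} supporting pieces of evidence; pairs from
#' systematic screens (source \code{"screen"}, or merged \code{"both"}) are
#' retained regardless, as are SIF pairs (no evidence column exists there).
#'
#' @param path input file.
#' @param min_evidence minimum evidence count for literature pairs (default 2).
#' @return data.frame with columns gene_a, gene_b, evidence_count, source;
#'   gene_a < gene_b lexicographically.
#' @export
read_interactions <- function(path, min_evidence = 2) {
  stopifnot(min_evidence >= 0)
  if (grepl("\\.sif$", path, ignore.case = TRUE)) {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    parts <- strsplit(trimws(lines), "[ \t]+")
    raw <- do.call(rbind, lapply(seq_along(parts), function(i) {
      p <- parts[[i]]
      if (length(p) == 2L) {
        data.frame(gene_a = p[1], gene_b = p[2], evidence_count = 1,
                   source = "sif", stringsAsFactors = FALSE)
      } else if (length(p) >= 3L) {
        data.frame(gene_a = p[1], gene_b = p[3], evidence_count = 1,
                   source = "sif", stringsAsFactors = FALSE)
      } else {
        stop(sprintf("malformed SIF row at line %d of %s", i, path))
      }
    }))
  } else {
    raw <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
    need <- c("gene_a", "gene_b", "evidence_count", "source")
    if (!all(need %in% names(raw))) {
      stop("interaction TSV must have columns: ", paste(need, collapse = ", "))
    }
    ev <- suppressWarnings(as.numeric(raw$evidence_count))
    if (anyNA(ev) || any(ev < 0)) {
      stop(sprintf("malformed evidence count at line %d of %s",
                   which(is.na(ev) | ev < 0)[1] + 1L, path))
    }
    raw$evidence_count <- ev
  }
  filter_interactions(raw, min_evidence)
}

#' Merge and evidence-filter a raw edge table
#' @param raw data.frame gene_a, gene_b, evidence_count, source.
#' @param min_evidence minimum evidence for literature pairs.
#' @return canonicalized, filtered edge data.frame.
#' @export
filter_interactions <- function(raw, min_evidence = 2) {
  raw$gene_a <- as.character(raw$gene_a)
  raw$gene_b <- as.character(raw$gene_b)
  raw <- raw[raw$gene_a != raw$gene_b, , drop = FALSE]
  if (nrow(raw) == 0L) {
    return(data.frame(gene_a = character(), gene_b = character(),
                      evidence_count = numeric(), source = character(),
                      stringsAsFactors = FALSE))
  }
  a <- pmin(raw$gene_a, raw$gene_b)
  b <- pmax(raw$gene_a, raw$gene_b)
  key <- paste(a, b, raw$source, sep = "\r")
  within <- rowsum(raw$evidence_count, group = key)
  parts <- strsplit(rownames(within), "\r", fixed = TRUE)
  merged <- data.frame(gene_a = vapply(parts, `[`, "", 1),
                       gene_b = vapply(parts, `[`, "", 2),
                       evidence_count = as.vector(within),
                       source = vapply(parts, `[`, "", 3),
                       stringsAsFactors = FALSE)
  pkey <- paste(merged$gene_a, merged$gene_b, sep = "\r")
  out <- do.call(rbind, lapply(split(merged, pkey), function(d) {
    src <- if (length(unique(d$source)) > 1L) "both" else d$source[1]
    data.frame(gene_a = d$gene_a[1], gene_b = d$gene_b[1],
               evidence_count = max(d$evidence_count), source = src,
               stringsAsFactors = FALSE)
  }))
  keep <- out$source != "literature" | out$evidence_count >= min_evidence
  out <- out[keep, , drop = FALSE]
  out <- out[order(out$gene_a, out$gene_b), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write an edge list as TSV
#' @param edges edge data.frame as returned by \code{read_interactions}.
#' @param path output path.
#' @export
write_interactions <- function(edges, path) {
  utils::write.table(edges, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(NULL)
}

#' Read an OBO 1.2 ontology into a DAG
#'
#' Parses \code{[Term]} stanzas; keeps \code{is_a} and
#' \code{relationship: part_of} edges; skips obsolete terms; verifies
#' acyclicity.  The per-relation semantic contribution weights default to
#' the Wang measure's conventional 0.8 (is_a) and 0.6 (part_of).
#'
#' @param path OBO file.
#' @param weights named numeric vector of semantic contribution weights in
#'   (0,1) for \code{is_a} and \code{part_of}.
#' @return an object of class \code{go_dag}: list with \code{terms}
#'   (data.frame id, name, namespace), \code{edges} (data.frame child,
#'   parent, relation), \code{weights}, and a precomputed \code{parents}
#'   adjacency (named list of data.frames).
#' @export
read_obo <- function(path, weights = c(is_a = 0.8, part_of = 0.6)) {
  lines <- readLines(path)
  terms <- list(); edges <- list()
  cur <- NULL; in_term <- FALSE
  flush <- function(cur) {
    if (is.null(cur) || is.null(cur$id) || isTRUE(cur$obsolete)) return(NULL)
    cur
  }
  for (ln in lines) {
    ln <- trimws(ln)
    if (ln == "[Term]") {
      t <- flush(cur); if (!is.null(t)) terms[[t$id]] <- t
      cur <- list(); in_term <- TRUE
      next
    }
    if (grepl("^\\[", ln)) {  # [Typedef] or other stanza
      t <- flush(cur); if (!is.null(t)) terms[[t$id]] <- t
      cur <- NULL; in_term <- FALSE
      next
    }
    if (!in_term || !nzchar(ln)) next
    if (grepl("^id:", ln)) cur$id <- trimws(sub("^id:", "", ln))
    else if (grepl("^name:", ln)) cur$name <- trimws(sub("^name:", "", ln))
    else if (grepl("^namespace:", ln)) cur$namespace <- trimws(sub("^namespace:", "", ln))
    else if (grepl("^is_obsolete: *true", ln)) cur$obsolete <- TRUE
    else if (grepl("^is_a:", ln)) {
      tgt <- trimws(sub("!.*$", "", sub("^is_a:", "", ln)))
      cur$is_a <- c(cur$is_a, tgt)
    } else if (grepl("^relationship: *part_of", ln)) {
      tgt <- trimws(sub("!.*$", "", sub("^relationship: *part_of", "", ln)))
      cur$part_of <- c(cur$part_of, tgt)
    }
  }
  t <- flush(cur); if (!is.null(t)) terms[[t$id]] <- t

  ids <- names(terms)
  term_df <- data.frame(
    id = ids,
    name = vapply(terms, function(t) t$name %||% "", ""),
    namespace = vapply(terms, function(t) t$namespace %||% "biological_process", ""),
    stringsAsFactors = FALSE, row.names = NULL)
  edge_df <- do.call(rbind, c(list(
    data.frame(child = character(), parent = character(), relation = character(),
               stringsAsFactors = FALSE)),
    lapply(terms, function(t) {
      rbind(
        if (length(t$is_a)) data.frame(child = t$id, parent = t$is_a,
                                       relation = "is_a", stringsAsFactors = FALSE),
        if (length(t$part_of)) data.frame(child = t$id, parent = t$part_of,
                                          relation = "part_of", stringsAsFactors = FALSE))
    })))
  rownames(edge_df) <- NULL
  # edges into obsolete/unknown parents are dropped, as GO tools do
  edge_df <- edge_df[edge_df$parent %in% ids, , drop = FALSE]
  go_dag(term_df, edge_df, weights)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Construct a validated GO DAG
#' @param terms data.frame with columns id, name, namespace.
#' @param edges data.frame with columns child, parent, relation.
#' @param weights named semantic contribution weights for is_a / part_of.
#' @return object of class \code{go_dag}.
#' @export
go_dag <- function(terms, edges, weights = c(is_a = 0.8, part_of = 0.6)) {
  stopifnot(all(c("id", "name", "namespace") %in% names(terms)),
            all(c("child", "parent", "relation") %in% names(edges)))
  if (any(weights <= 0) || any(weights >= 1)) stop("semantic weights must lie in (0,1)")
  unknown <- setdiff(unique(c(edges$child, edges$parent)), terms$id)
  if (length(unknown) > 0L) stop("edge endpoint not a known term: ", unknown[1])
  check_acyclic(terms$id, edges)
  parents <- split(edges[, c("parent", "relation")], edges$child)
  structure(list(terms = terms, edges = edges, weights = weights,
                 parents = parents),
            class = "go_dag")
}

# Kahn topological sort over child -> parent edges; stop() on a cycle.
check_acyclic <- function(ids, edges) {
  out_deg <- stats::setNames(integer(length(ids)), ids)
  tab <- table(edges$child)
  out_deg[names(tab)] <- as.integer(tab)
  children_of <- split(edges$child, edges$parent)
  queue <- names(out_deg)[out_deg == 0L]
  seen <- 0L
  while (length(queue) > 0L) {
    v <- queue[[1]]; queue <- queue[-1]; seen <- seen + 1L
    for (c in children_of[[v]] %||% character()) {
      out_deg[c] <- out_deg[c] - 1L
      if (out_deg[c] == 0L) queue <- c(queue, c)
    }
  }
  if (seen < length(ids)) {
    stop("ontology contains a cycle involving term ",
         names(out_deg)[out_deg > 0L][1])
  }
  invisible(TRUE)
}

#' @export
print.go_dag <- function(x, ...) {
  cat(sprintf("GO DAG: %d terms, %d edges (%s)\n",
              nrow(x$terms), nrow(x$edges),
              paste(sprintf("%s w=%.2f", names(x$weights), x$weights),
                    collapse = ", ")))
  invisible(x)
}

#' Write a DAG to OBO 1.2
#' @param dag a \code{go_dag}.
#' @param path output path.
#' @export
write_obo <- function(dag, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines("format-version: 1.2", con)
  for (i in seq_len(nrow(dag$terms))) {
    id <- dag$terms$id[i]
    writeLines(c("", "[Term]",
                 paste0("id: ", id),
                 paste0("name: ", dag$terms$name[i]),
                 paste0("namespace: ", dag$terms$namespace[i])), con)
    e <- dag$edges[dag$edges$child == id, , drop = FALSE]
    for (j in seq_len(nrow(e))) {
      if (e$relation[j] == "is_a") {
        writeLines(paste0("is_a: ", e$parent[j]), con)
      } else {
        writeLines(paste0("relationship: part_of ", e$parent[j]), con)
      }
    }
  }
  invisible(NULL)
}

#' Read gene annotations from a GAF 2.x file
#'
#' Keeps rows of the requested aspect (P = biological process, F, or C),
#' drops rows with a NOT qualifier, and, when a DAG is supplied, drops
#' annotations to unknown terms with a warning stating how many were lost.
#'
#' @param path GAF file ("!" comment lines ignored).
#' @param namespace aspect filter, one of "P", "F", "C".
#' @param dag optional \code{go_dag} used to validate term ids.
#' @return named list: gene id -> character vector of term ids (possibly
#'   empty for genes whose rows were all filtered out).
#' @export
read_annotations <- function(path, namespace = "P", dag = NULL) {
  namespace <- match.arg(namespace, c("P", "F", "C"))
  lines <- readLines(path)
  lines <- lines[!grepl("^!", lines) & nzchar(lines)]
  if (length(lines) == 0L) return(stats::setNames(list(), character()))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- vapply(fields, length, 0L) < 9L
  if (any(short)) stop("GAF row with fewer than 9 columns at data line ", which(short)[1])
  gene <- vapply(fields, `[`, "", 2)
  qual <- vapply(fields, `[`, "", 4)
  term <- vapply(fields, `[`, "", 5)
  aspect <- vapply(fields, `[`, "", 9)
  keep <- aspect == namespace & !grepl("(^|\\|)NOT($|\\|)", qual)
  gene <- gene[keep]; term <- term[keep]
  if (!is.null(dag)) {
    known <- term %in% dag$terms$id
    if (any(!known)) {
      warning(sum(!known), " annotation(s) to unknown term ids dropped")
    }
    gene <- gene[known]; term <- term[known]
  }
  ann <- lapply(split(term, gene), function(x) sort(unique(x)))
  ann[order(names(ann))]
}

#' Write an annotation map as GAF 2.2
#' @param ann named list gene -> term ids.
#' @param path output path.
#' @param namespace aspect code written in column 9.
#' @export
write_gaf <- function(ann, path, namespace = "P") {
  con <- file(path, "w"); on.exit(close(con))
  writeLines("!gaf-version: 2.2", con)
  for (g in names(ann)) {
    for (t in ann[[g]]) {
      writeLines(paste(c("DB", g, g, "involved_in", t, "REF:0", "IEA", "",
                         namespace, "", "", "protein", "taxon:9606",
                         "20240101", "DB", "", ""), collapse = "\t"), con)
    }
  }
  invisible(NULL)
}

#' Read a gene-by-tissue expression table
#' @param path TSV: first column gene id, remaining columns tissues.
#' @return numeric matrix genes x tissues; all values finite and >= 0.
#' @export
read_tissue_table <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                           stringsAsFactors = FALSE)
  vals <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(vals) <- "double"
  rownames(vals) <- as.character(tab[[1]])
  if (anyDuplicated(colnames(vals))) stop("duplicate tissue names")
  if (any(!is.finite(vals))) stop("non-finite tissue expression value")
  if (any(vals < 0)) {
    bad <- which(vals < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative tissue expression for gene '%s' in tissue '%s'",
                 rownames(vals)[bad[1]], colnames(vals)[bad[2]]))
  }
  vals
}

#' Write a tissue table as TSV
#' @param tissues genes x tissues numeric matrix.
#' @param path output path.
#' @export
write_tissue_table <- function(tissues, path) {
  df <- data.frame(gene = rownames(tissues), tissues, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(NULL)
}

#' Read a newline-delimited gene list
#' @param path one identifier per line; duplicates removed.
#' @return character vector of unique identifiers.
#' @export
read_gene_set <- function(path) {
  ids <- trimws(readLines(path))
  unique(ids[nzchar(ids)])
}

#' Write a gene list
#' @param genes character vector.
#' @param path output path.
#' @export
write_gene_set <- function(genes, path) {
  writeLines(unique(as.character(genes)), path)
  invisible(NULL)
}
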