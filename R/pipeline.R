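# End-to-end orchestration: differential expression -> disease network ->
# hub detection -> network-variation test -> semantic similarity ->
# combined prioritized list -> tissue / reference / enrichment evaluation
# -> LOOCV classification.  A single config drives every stage; one global
# seed derives per-stage seeds by fixed offsets so stages are individually
# reproducible.

#' Build a pipeline configuration
#'
#' @param expr,groups,interactions,obo,gaf,tissues,housekeeping,reference
#'   input file paths (see the io readers for formats).
#' @param fdr_threshold DE q-value cutoff (default 0.98, the permissive
#'   seeding threshold).
#' @param direction DE sign constraint (default "positive").
#' @param de_n_perm permutations for the DE q-values.
#' @param min_evidence evidence filter for literature interaction pairs.
#' @param bottleneck_quantile top fraction of positive betweenness counted
#'   as bottlenecks.
#' @param n_perm permutations for the network-variation null.
#' @param alpha significance level for the Bonferroni-adjusted
#'   network-variation p-values.
#' @param sidedness "two_sided" or "one_sided" (see
#'   \code{hub_pvalues}).
#' @param semsim_threshold median-similarity cutoff (strict greater-than).
#' @param semsim_combine "all_pairs_avg" or "best_match_avg".
#' @param tissue_targets target tissue column names.
#' @param tissue_fold fold-change over the cross-tissue median.
#' @param enrich_alpha adjusted-p cutoff for enrichment.
#' @param n_trees random-forest size.
#' @param seed global integer seed.
#' @return list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(expr, groups, interactions, obo, gaf,
                            tissues = NULL, housekeeping = NULL,
                            reference = NULL,
                            fdr_threshold = 0.98, direction = "positive",
                            de_n_perm = 100, min_evidence = 2,
                            bottleneck_quantile = 0.5,
                            n_perm = 1000, alpha = 0.05,
                            sidedness = "two_sided",
                            semsim_threshold = 0.5,
                            semsim_combine = "all_pairs_avg",
                            tissue_targets = c("whole brain", "prefrontal cortex"),
                            tissue_fold = 1.5,
                            enrich_alpha = 0.05,
                            n_trees = 100, seed = 1) {
  cfg <- as.list(environment())
  stopifnot(cfg$fdr_threshold > 0, cfg$fdr_threshold <= 1,
            cfg$n_perm >= 1, cfg$alpha > 0, cfg$alpha < 1,
            cfg$semsim_threshold >= 0, cfg$semsim_threshold <= 1,
            cfg$tissue_fold > 0, cfg$n_trees >= 1)
  structure(cfg, class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#'
#' Keys mirror the arguments of \code{pipeline_config}; relative input
#' paths are resolved against the YAML file's directory.
#'
#' @param path YAML file.
#' @return a \code{pipeline_config}.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  path_keys <- c("expr", "groups", "interactions", "obo", "gaf",
                 "tissues", "housekeeping", "reference")
  for (k in intersect(path_keys, names(y))) {
    if (!is.null(y[[k]]) && !grepl("^/", y[[k]])) {
      y[[k]] <- file.path(dirname(path), y[[k]])
    }
  }
  cfg <- do.call(pipeline_config, y)
  missing <- Filter(function(k) !is.null(cfg[[k]]) && !file.exists(cfg[[k]]),
                    intersect(path_keys, names(cfg)))
  if (length(missing) > 0L) {
    stop("input file(s) not found: ",
         paste(unlist(cfg[missing]), collapse = ", "))
  }
  cfg
}

#' Run the full prioritization pipeline
#'
#' Executes every stage in order, writes each intermediate table as TSV
#' under \code{out_dir}, and returns (and writes) a machine-readable run
#' report with the counts at every stage.
#'
#' @param config a \code{pipeline_config}.
#' @param out_dir output directory for intermediate tables and
#'   \code{report.json}.
#' @return list of class \code{run_report} (also serialized to JSON):
#'   stage counts, AUC, parameters, seed.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- Sys.time()
  stage <- function(name) message(sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), name))

  stage("reading inputs")
  eg <- read_expression(config$expr, config$groups)
  edges <- read_interactions(config$interactions, config$min_evidence)
  dag <- read_obo(config$obo)
  ann <- read_annotations(config$gaf, namespace = "P", dag = dag)

  stage("differential expression")
  de_res <- permutation_fdr(eg$expr, eg$groups, n_perm = config$de_n_perm,
                            seed = config$seed + 101L)
  de_res$selected <- de_res$gene_id %in%
    select_de(de_res, config$fdr_threshold, config$direction)
  de_genes <- de_res$gene_id[de_res$selected]
  utils::write.table(de_res, file.path(out_dir, "de_genes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  stage("disease network and hubs")
  net <- build_disease_network(edges, de_genes)
  hub_tab <- select_hubs(net, config$bottleneck_quantile)
  hubs <- hub_tab$gene_id[hub_tab$is_hub]
  utils::write.table(hub_tab, file.path(out_dir, "hubs.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  stage("network variation (permutation test)")
  nv <- permutation_null(eg$expr, eg$groups, net, hubs,
                         n_perm = config$n_perm, seed = config$seed + 202L)
  nv <- hub_pvalues(nv, alpha = config$alpha, sidedness = config$sidedness)
  utils::write.table(nv$table, file.path(out_dir, "netvar.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  step1 <- nv$table$hub_id[nv$table$significant]

  stage("semantic similarity")
  ss <- prioritize_by_semsim(dag, ann, net, hubs,
                             threshold = config$semsim_threshold,
                             combine = config$semsim_combine)
  utils::write.table(ss, file.path(out_dir, "semsim.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  step2 <- ss$hub_id[ss$selected]

  stage("combining and evaluating the prioritized list")
  apc <- stats::setNames(nv$table$avg_pcc, nv$table$hub_id)
  prioritized <- combine_hubs(step1, step2, avg_pcc = apc)
  ref_hits <- character(); tissue_tab <- NULL
  if (!is.null(config$reference)) {
    ref_hits <- reference_overlap(prioritized, read_gene_set(config$reference))
  }
  if (!is.null(config$tissues)) {
    hk <- if (!is.null(config$housekeeping))
      read_gene_set(config$housekeeping) else character()
    tissue_tab <- tissue_filter(prioritized, read_tissue_table(config$tissues),
                                config$tissue_targets, hk, config$tissue_fold)
  }
  prioritized$reference_hit <- prioritized$gene_id %in% ref_hits
  prioritized$tissue_status <- if (is.null(tissue_tab)) NA_character_ else
    tissue_tab$status[match(prioritized$gene_id, tissue_tab$gene_id)]
  med_ss <- stats::setNames(ss$median_similarity, ss$hub_id)
  prioritized$median_semsim <- unname(med_ss[prioritized$gene_id])
  utils::write.table(prioritized, file.path(out_dir, "prioritized_genes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  stage("GO enrichment")
  background <- rownames(eg$expr)
  enr <- go_enrichment(intersect(prioritized$gene_id, background),
                       background, ann, dag, alpha = config$enrich_alpha)
  utils::write.table(enr, file.path(out_dir, "enrichment.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  stage("LOOCV classification")
  auc <- NA_real_
  if (nrow(prioritized) > 0L) {
    feats <- coediff_features(eg$expr, net, prioritized)
    utils::write.table(
      data.frame(sample = rownames(feats), feats, check.names = FALSE),
      file.path(out_dir, "features.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    report_cls <- loocv_evaluate(feats, eg$groups, n_trees = config$n_trees,
                                 seed = config$seed + 303L)
    auc <- report_cls$auc
  }

  report <- list(
    counts = list(
      n_genes = nrow(eg$expr),
      n_samples = ncol(eg$expr),
      n_de_genes = length(de_genes),
      n_network_nodes = igraph::vcount(net),
      n_network_edges = igraph::ecount(net),
      n_hubs = length(hubs),
      n_step1_netvar = length(step1),
      n_step2_semsim = length(step2),
      n_prioritized = nrow(prioritized),
      n_reference_hits = length(ref_hits),
      n_tissue_pass = if (is.null(tissue_tab)) NA_integer_ else
        sum(tissue_tab$status == "pass"),
      n_enriched_terms = sum(enr$enriched)),
    auc = auc,
    parameters = unclass(config)[setdiff(names(config),
      c("expr", "groups", "interactions", "obo", "gaf", "tissues",
        "housekeeping", "reference"))],
    seed = config$seed)
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  message(sprintf("pipeline finished in %.1f s",
                  as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  structure(report, class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat("Pipeline run report\n")
  for (k in names(x$counts)) cat(sprintf("  %-18s %s\n", k, x$counts[[k]]))
  cat(sprintf("  %-18s %.3f\n", "loocv_auc", x$auc))
  invisible(x)
}
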