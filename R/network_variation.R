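# Differential co-expression scoring of hubs.  For each hub, AvgPCC is the
# mean over its interactors of (Pearson correlation in disease samples minus
# Pearson correlation in control samples).  Significance is assessed by
# re-assigning sample labels at random (group sizes preserved, topology
# untouched), recomputing AvgPCC each time, and comparing the observed value
# to that permutation null, with Bonferroni correction across hubs.

# Row-wise z-scores of a matrix over the given columns; rows with zero
# variance get all-zero scores (their correlations contribute 0).
row_z <- function(expr, idx) {
  x <- expr[, idx, drop = FALSE]
  m <- ncol(x)
  xc <- x - rowMeans(x)
  s <- sqrt(rowSums(xc^2) / (m - 1))
  z <- xc / s
  z[s == 0, ] <- 0
  z
}

# AvgPCC for every hub given a pair index, for one disease/control split.
avg_pcc_for_split <- function(expr, pairs, d_idx, c_idx) {
  zd <- row_z(expr, d_idx)
  zc <- row_z(expr, c_idx)
  D <- rowSums(zd[pairs$hub_row, , drop = FALSE] *
                 zd[pairs$int_row, , drop = FALSE]) / (length(d_idx) - 1)
  C <- rowSums(zc[pairs$hub_row, , drop = FALSE] *
                 zc[pairs$int_row, , drop = FALSE]) / (length(c_idx) - 1)
  as.vector(rowsum(D - C, group = pairs$hub_id, reorder = FALSE)) / pairs$n_int
}

# Usable hub-interactor pairs: interactor present in the expression matrix
# and non-constant within both observed groups (constant profiles have no
# defined correlation and are dropped from n, not scored 0).
usable_pairs <- function(expr, groups, net, hubs) {
  d_idx <- which(groups == "disease")
  c_idx <- which(groups == "control")
  const_d <- apply(expr[, d_idx, drop = FALSE], 1, stats::var) == 0
  const_c <- apply(expr[, c_idx, drop = FALSE], 1, stats::var) == 0
  usable_gene <- rownames(expr)[!(const_d | const_c)]
  hub_list <- list(); int_list <- list(); excluded <- character()
  for (h in hubs) {
    ints <- intersect(interactors_of(net, h), usable_gene)
    ints <- setdiff(ints, h)
    if (!h %in% usable_gene || length(ints) == 0L) {
      excluded <- c(excluded, h)
      next
    }
    hub_list[[h]] <- rep(h, length(ints))
    int_list[[h]] <- ints
  }
  hub_id <- unlist(hub_list, use.names = FALSE)
  int_id <- unlist(int_list, use.names = FALSE)
  tested <- unique(hub_id)
  list(pairs = list(hub_row = match(hub_id, rownames(expr)),
                    int_row = match(int_id, rownames(expr)),
                    hub_id = factor(hub_id, levels = tested),
                    n_int = as.vector(table(factor(hub_id, levels = tested)))),
       hubs = tested, excluded = excluded)
}

#' Average differential hub-interactor correlation (AvgPCC)
#'
#' @param expr genes x samples matrix.
#' @param groups named group vector.
#' @param net igraph network supplying the hub's interactors.
#' @param hub hub gene id.
#' @return list: \code{avg_pcc}, \code{n_interactors}; or NULL (with a
#'   message) when the hub has no usable interactor.
#' @export
hub_avg_pcc <- function(expr, groups, net, hub) {
  groups <- sample_groups(groups, samples = colnames(expr))
  if (min(table(groups)) < 3L) stop("need >= 3 samples per group for correlations")
  up <- usable_pairs(expr, groups, net, hub)
  if (length(up$hubs) == 0L) {
    message("hub '", hub, "' excluded: no usable interactor")
    return(NULL)
  }
  v <- avg_pcc_for_split(expr, up$pairs,
                         which(groups == "disease"), which(groups == "control"))
  list(avg_pcc = v[1], n_interactors = up$pairs$n_int[1])
}

#' Permutation null of AvgPCC for a set of hubs
#'
#' Sample labels are shuffled with group sizes preserved and AvgPCC is
#' recomputed for every hub under each relabeling.  When \code{n_perm} is at
#' least the number of distinct label splits the full set of splits is
#' enumerated instead.
#'
#' @inheritParams hub_avg_pcc
#' @param hubs character vector of hub ids to test.
#' @param n_perm number of permutations (default 1000).
#' @param seed integer seed (mandatory for reproducibility).
#' @return object of class \code{netvar_result}: list with \code{table}
#'   (data.frame hub_id, n_interactors, avg_pcc), \code{null} (hubs x
#'   permutations matrix of RandomPCC values), \code{excluded}, and
#'   \code{exhaustive} flag.
#' @export
permutation_null <- function(expr, groups, net, hubs, n_perm = 1000, seed = 1) {
  stopifnot(n_perm >= 1)
  groups <- sample_groups(groups, samples = colnames(expr))
  if (min(table(groups)) < 3L) stop("need >= 3 samples per group for correlations")
  up <- usable_pairs(expr, groups, net, hubs)
  for (h in up$excluded) message("hub '", h, "' excluded: no usable interactor")
  d_idx <- which(groups == "disease")
  c_idx <- which(groups == "control")
  n <- ncol(expr); n1 <- length(d_idx)
  if (length(up$hubs) == 0L) {
    return(structure(list(table = data.frame(hub_id = character(),
                                             n_interactors = integer(),
                                             avg_pcc = numeric()),
                          null = matrix(numeric(), 0, 0),
                          excluded = up$excluded, exhaustive = FALSE),
                     class = "netvar_result"))
  }
  observed <- avg_pcc_for_split(expr, up$pairs, d_idx, c_idx)

  n_exact <- choose(n, n1)
  exhaustive <- n_perm >= n_exact
  if (exhaustive) {
    splits <- utils::combn(n, n1, simplify = FALSE)
  } else {
    set.seed(seed)
    splits <- lapply(seq_len(n_perm), function(i) sample.int(n, n1))
  }
  null <- vapply(splits, function(dd) {
    avg_pcc_for_split(expr, up$pairs, dd, setdiff(seq_len(n), dd))
  }, numeric(length(up$hubs)))
  null <- matrix(null, nrow = length(up$hubs),
                 dimnames = list(up$hubs, NULL))
  structure(list(table = data.frame(hub_id = up$hubs,
                                    n_interactors = up$pairs$n_int,
                                    avg_pcc = observed,
                                    stringsAsFactors = FALSE),
                 null = null, excluded = up$excluded, exhaustive = exhaustive),
            class = "netvar_result")
}

#' Permutation p-values and Bonferroni correction for hubs
#'
#' Default \code{"two_sided"} mode compares magnitudes,
#' p = #\{|RandomPCC| >= |AvgPCC|\} / n_perm, selecting hubs whose
#' differential co-expression is extreme in either direction.  The
#' \code{"one_sided"} mode computes p = #\{AvgPCC >= RandomPCC\} /
#' n_perm, the one-sided counting form sometimes quoted for this test.
#' Bonferroni multiplies by the number of hubs actually tested.
#'
#' @param result \code{netvar_result} from \code{permutation_null}.
#' @param alpha significance level on the adjusted p (default 0.05).
#' @param sidedness "two_sided" or "one_sided".
#' @param smooth if TRUE, use (1 + b) / (1 + n_perm) instead of b / n_perm.
#' @return the \code{netvar_result} with table columns p_value, p_adjusted,
#'   significant added.
#' @export
hub_pvalues <- function(result, alpha = 0.05,
                        sidedness = c("two_sided", "one_sided"),
                        smooth = FALSE) {
  stopifnot(inherits(result, "netvar_result"), alpha > 0, alpha < 1)
  sidedness <- match.arg(sidedness)
  tab <- result$table
  if (nrow(tab) == 0L) {
    tab$p_value <- numeric(); tab$p_adjusted <- numeric(); tab$significant <- logical()
    result$table <- tab
    return(result)
  }
  n_perm <- ncol(result$null)
  b <- vapply(seq_len(nrow(tab)), function(i) {
    if (sidedness == "two_sided") {
      sum(abs(result$null[i, ]) >= abs(tab$avg_pcc[i]))
    } else {
      sum(tab$avg_pcc[i] >= result$null[i, ])
    }
  }, numeric(1))
  p <- if (smooth) (1 + b) / (1 + n_perm) else b / n_perm
  tab$p_value <- p
  tab$p_adjusted <- pmin(1, p * nrow(tab))
  tab$significant <- tab$p_adjusted <= alpha
  result$table <- tab
  result$alpha <- alpha
  result$sidedness <- sidedness
  result
}

#' @export
print.netvar_result <- function(x, ...) {
  cat(sprintf("Network variation: %d hub(s) tested, %d excluded, %s null (%d draws)\n",
              nrow(x$table), length(x$excluded),
              if (isTRUE(x$exhaustive)) "exhaustive" else "sampled",
              ncol(x$null)))
  if ("significant" %in% names(x$table)) {
    cat(sprintf("  significant at adjusted p <= %.3g: %d\n",
                x$alpha, sum(x$table$significant)))
  }
  invisible(x)
}
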