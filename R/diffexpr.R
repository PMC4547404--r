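# SAM-style regularized two-sample statistic with a permutation FDR.
# d_i = (mean_disease - mean_control) / (se_i + s0), where se_i is the
# pooled two-sample standard error and s0 a small fudge constant that
# stabilizes genes with tiny variance.

#' Regularized t (SAM-style d) statistic per gene
#'
#' @param expr genes x samples numeric matrix.
#' @param groups named group vector ("disease"/"control") covering all
#'   samples of \code{expr}.
#' @param s0 non-negative exchangeability constant, or \code{"auto"} to use
#'   the median of the per-gene pooled standard errors.
#' @return data.frame (one row per gene): gene_id, d_statistic, pooled_se.
#' @export
sam_statistic <- function(expr, groups, s0 = "auto") {
  groups <- sample_groups(groups, samples = colnames(expr))
  d_idx <- which(groups == "disease")
  c_idx <- which(groups == "control")
  if (length(d_idx) < 2L || length(c_idx) < 2L) {
    stop("each group needs at least 2 samples")
  }
  d <- sam_d(expr, d_idx, c_idx, s0)
  data.frame(gene_id = rownames(expr), d_statistic = d$d, pooled_se = d$se,
             stringsAsFactors = FALSE, row.names = NULL)
}

# Core d computation for a given column split; reused by the permutations.
sam_d <- function(expr, d_idx, c_idx, s0) {
  n1 <- length(d_idx); n2 <- length(c_idx)
  m1 <- rowMeans(expr[, d_idx, drop = FALSE])
  m2 <- rowMeans(expr[, c_idx, drop = FALSE])
  ss1 <- rowSums((expr[, d_idx, drop = FALSE] - m1)^2)
  ss2 <- rowSums((expr[, c_idx, drop = FALSE] - m2)^2)
  sp2 <- (ss1 + ss2) / (n1 + n2 - 2)
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  if (identical(s0, "auto")) s0 <- stats::median(se)
  stopifnot(is.numeric(s0), s0 >= 0)
  list(d = (m1 - m2) / (se + s0), se = se, s0 = s0)
}

#' Permutation-based q-values for the SAM-style statistic
#'
#' For each threshold c taken from the observed |d| values, the estimated
#' FDR is (median over label permutations of the count of |d*| >= c)
#' divided by the observed count of |d| >= c.  A gene's q-value is the
#' minimum estimated FDR over the thresholds its |d| reaches, which makes
#' q non-increasing in |d|.  When the requested number of permutations is
#' at least the number of distinct label splits, all splits are enumerated
#' exactly instead of sampled.
#'
#' @inheritParams sam_statistic
#' @param n_perm number of label permutations (>= 1).
#' @param seed integer seed fixing the permutation stream.
#' @return data.frame: gene_id, d_statistic, pooled_se, q_value.
#' @export
permutation_fdr <- function(expr, groups, n_perm = 100, seed = 1, s0 = "auto") {
  stopifnot(n_perm >= 1)
  groups <- sample_groups(groups, samples = colnames(expr))
  obs <- sam_statistic(expr, groups, s0 = s0)
  d_idx <- which(groups == "disease")
  c_idx <- which(groups == "control")
  n <- ncol(expr); n1 <- length(d_idx)
  # freeze s0 at its observed value so permuted statistics are comparable
  s0_val <- if (identical(s0, "auto")) {
    sam_d(expr, d_idx, c_idx, "auto")$s0
  } else s0

  n_exact <- choose(n, n1)
  if (n_perm >= n_exact) {
    splits <- utils::combn(n, n1, simplify = FALSE)
  } else {
    set.seed(seed)
    splits <- lapply(seq_len(n_perm), function(i) sample.int(n, n1))
  }
  null_abs <- vapply(splits, function(dd) {
    abs(sam_d(expr, dd, setdiff(seq_len(n), dd), s0_val)$d)
  }, numeric(nrow(expr)))  # genes x perms

  nulls <- if (is.matrix(null_abs)) null_abs else
    matrix(null_abs, ncol = length(splits))
  obs_abs <- abs(obs$d_statistic)
  # observed count called at each gene's own threshold c = |d_i|
  n_called <- length(obs_abs) + 1L - rank(obs_abs, ties.method = "max")
  med_null <- vapply(obs_abs, function(c0) {
    stats::median(colSums(nulls >= c0))
  }, numeric(1))
  fdr_at <- pmin(1, med_null / pmax(n_called, 1L))
  # q = min estimated FDR over the thresholds the gene reaches (c <= |d_i|);
  # cummin over genes sorted by ascending |d| makes q non-increasing in |d|
  ord <- order(obs_abs)
  q <- numeric(length(obs_abs))
  q[ord] <- cummin(fdr_at[ord])
  obs$q_value <- q
  obs
}

#' Select differentially expressed genes
#'
#' @param result data.frame from \code{permutation_fdr}.
#' @param fdr_threshold q-value cutoff in (0, 1]; the pipeline default 0.98
#'   mirrors the extremely permissive selection used to seed the
#'   disease-specific network.
#' @param direction "positive" (up in disease), "negative", or "both".
#' @return character vector of selected gene ids.
#' @export
select_de <- function(result, fdr_threshold = 0.98, direction = "positive") {
  stopifnot(fdr_threshold > 0, fdr_threshold <= 1)
  direction <- match.arg(direction, c("positive", "negative", "both"))
  keep <- result$q_value <= fdr_threshold
  keep <- keep & switch(direction,
                        positive = result$d_statistic > 0,
                        negative = result$d_statistic < 0,
                        both = rep(TRUE, nrow(result)))
  sort(result$gene_id[keep])
}
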