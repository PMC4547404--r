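# Disease-outcome classification from co-expression-difference features.
# For sample s and prioritized hub G with interactors Im_1..Im_n, the
# feature is CoeDiff(G, s) = sum_i |expr(Im_i, s) - expr(G, s)| (a
# sign-preserving variant is available).  Samples are classified by a
# random forest under leave-one-out cross-validation; the held-out score is
# the fraction of trees voting "disease", and performance is summarized by
# the ROC curve and its area.

#' Per-sample co-expression-difference (CoeDiff) features
#'
#' @param expr genes x samples matrix.
#' @param net igraph network supplying interactors.
#' @param prioritized character vector (or combine_hubs data.frame) of hub
#'   ids; each must be present in \code{expr}.
#' @param absolute sum absolute differences (default) or signed differences.
#' @return samples x hubs numeric matrix; hubs without interactors in the
#'   network are dropped with a warning.
#' @export
coediff_features <- function(expr, net, prioritized, absolute = TRUE) {
  if (is.data.frame(prioritized)) prioritized <- prioritized$gene_id
  prioritized <- unique(as.character(prioritized))
  missing <- setdiff(prioritized, rownames(expr))
  if (length(missing) > 0L) {
    stop("prioritized hub(s) absent from the expression matrix: ",
         paste(missing, collapse = ", "))
  }
  cols <- list()
  for (h in prioritized) {
    ints <- intersect(interactors_of(net, h), rownames(expr))
    ints <- setdiff(ints, h)
    if (length(ints) == 0L) {
      warning("hub '", h, "' has no interactor in the network; feature dropped")
      next
    }
    diff <- sweep(expr[ints, , drop = FALSE], 2, expr[h, ], "-")
    if (absolute) diff <- abs(diff)
    cols[[h]] <- colSums(diff)
  }
  if (length(cols) == 0L) stop("no usable feature column")
  do.call(cbind, cols)
}

#' Leave-one-out cross-validated random-forest evaluation
#'
#' Each of the n samples is held out in turn, a random forest with
#' \code{n_trees} trees is trained on the remaining n-1 samples, and the
#' held-out sample's disease-vote fraction is recorded; the n held-out
#' scores yield the ROC curve and AUC.
#'
#' @param features samples x features numeric matrix.
#' @param labels named group vector ("disease"/"control") covering the
#'   feature rows.
#' @param n_trees trees per forest (default 100).
#' @param seed integer seed fixing all forests.
#' @return list of class \code{loocv_report}: \code{scores} (held-out
#'   disease scores), \code{labels}, \code{roc} (data.frame fpr, tpr),
#'   \code{auc}, \code{n_trees}, \code{seed}.
#' @export
loocv_evaluate <- function(features, labels, n_trees = 100, seed = 1) {
  labels <- sample_groups(labels, samples = rownames(features))
  y <- factor(labels, levels = c("control", "disease"))
  if (length(unique(y)) < 2L) stop("both classes are required")
  n <- nrow(features)
  scores <- numeric(n)
  for (i in seq_len(n)) {
    set.seed(seed + i)
    fit <- randomForest::randomForest(
      x = features[-i, , drop = FALSE], y = y[-i], ntree = n_trees)
    scores[i] <- stats::predict(fit, features[i, , drop = FALSE],
                                type = "prob")[, "disease"]
  }
  names(scores) <- rownames(features)
  r <- roc_auc(scores, labels)
  structure(list(scores = scores, labels = labels, roc = r$roc, auc = r$auc,
                 n_trees = n_trees, seed = seed),
            class = "loocv_report")
}

#' ROC curve and AUC from scores and binary labels
#'
#' The AUC equals the Mann-Whitney probability that a random disease sample
#' scores above a random control sample, ties counted one half.  The ROC is
#' traced by sweeping the threshold down the distinct scores, starting at
#' (0,0) and ending at (1,1).
#'
#' @param scores numeric scores (higher = more disease-like).
#' @param labels group vector aligned with \code{scores} ("disease" is the
#'   positive class).
#' @return list: \code{roc} (data.frame fpr, tpr), \code{auc}.
#' @export
roc_auc <- function(scores, labels) {
  pos <- scores[labels == "disease"]
  neg <- scores[labels == "control"]
  if (length(pos) == 0L || length(neg) == 0L) stop("both classes are required")
  r <- rank(c(pos, neg), ties.method = "average")
  auc <- (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
  thr <- sort(unique(scores), decreasing = TRUE)
  roc <- data.frame(
    fpr = c(0, vapply(thr, function(t) mean(neg >= t), numeric(1))),
    tpr = c(0, vapply(thr, function(t) mean(pos >= t), numeric(1))))
  list(roc = roc, auc = auc)
}

#' @export
print.loocv_report <- function(x, ...) {
  cat(sprintf("LOOCV random forest (%d trees, seed %d): %d folds, AUC = %.3f\n",
              x$n_trees, x$seed, length(x$scores), x$auc))
  invisible(x)
}
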