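#' Hierarchical precision, recall and F1
#'
#' For each cell, the predicted ancestor set \code{P} contains the
#' predicted population and all its ancestors (root excluded; empty for
#' rejected cells) and the true ancestor set \code{T} likewise for the true
#' population. Then
#' \deqn{hP = \sum_i |P_i \cap T_i| / \sum_i |P_i|,\quad
#'       hR = \sum_i |P_i \cap T_i| / \sum_i |T_i|}
#' and HF1 is their harmonic mean. Predicting an ancestor of the truth
#' keeps \code{hP} at 1 but lowers \code{hR}; rejection contributes nothing
#' to either numerator or to \code{\sum |P_i|}, so it hurts recall only.
#'
#' @param trueLabels Per-cell true populations (tree nodes).
#' @param predictedLabels Predictions: tree nodes or \code{"rejected"}.
#' @param tree The \code{ClassificationTree}.
#' @return Named list with \code{hP}, \code{hR}, \code{HF1}.
#' @export
hierarchicalF1 <- function(trueLabels, predictedLabels, tree) {
  trueLabels <- as.character(trueLabels)
  predictedLabels <- as.character(predictedLabels)
  if (!length(trueLabels)) stop("empty input")
  if (length(trueLabels) != length(predictedLabels))
    stop("label vectors must have equal length")
  nodes <- setdiff(nodeNames(tree), rootName(tree))
  bad <- setdiff(unique(trueLabels), nodes)
  if (length(bad))
    stop("true labels missing from tree: ", paste(bad, collapse = ", "))
  bad <- setdiff(unique(predictedLabels), c(nodes, "rejected"))
  if (length(bad))
    stop("predictions missing from tree: ", paste(bad, collapse = ", "))
  aset <- lapply(stats::setNames(nodes, nodes),
                 function(n) c(n, ancestors(tree, n)))
  aset[["rejected"]] <- character()
  pairs <- table(trueLabels, predictedLabels)
  num <- 0; denP <- 0; denT <- 0
  for (i in seq_len(nrow(pairs))) for (j in seq_len(ncol(pairs))) {
    cnt <- pairs[i, j]
    if (!cnt) next
    Ti <- aset[[rownames(pairs)[i]]]
    Pi <- aset[[colnames(pairs)[j]]]
    num <- num + cnt * length(intersect(Pi, Ti))
    denP <- denP + cnt * length(Pi)
    denT <- denT + cnt * length(Ti)
  }
  hP <- if (denP > 0) num / denP else 0
  hR <- num / denT
  HF1 <- if (hP + hR > 0) 2 * hP * hR / (hP + hR) else 0
  list(hP = hP, hR = hR, HF1 = HF1)
}

#' Median per-population F1 score
#'
#' The F1 score is computed per population over the cells, and the median
#' across populations is returned. Cells whose prediction is
#' \code{"rejected"} -- or an internal node of \code{tree}, when a tree is
#' supplied -- are excluded before computing the scores, mirroring how flat
#' classifiers are conventionally compared.
#'
#' @param trueLabels,predictedLabels Per-cell labels.
#' @param tree Optional \code{ClassificationTree} used to identify internal
#'   (non-leaf) predictions for exclusion.
#' @return The median F1 across the true populations.
#' @export
medianF1 <- function(trueLabels, predictedLabels, tree = NULL) {
  trueLabels <- as.character(trueLabels)
  predictedLabels <- as.character(predictedLabels)
  if (length(trueLabels) != length(predictedLabels))
    stop("label vectors must have equal length")
  drop <- predictedLabels == "rejected"
  if (!is.null(tree))
    drop <- drop | predictedLabels %in% c(treeInternal(tree), rootName(tree))
  tl <- trueLabels[!drop]; pl <- predictedLabels[!drop]
  if (!length(tl)) stop("no cells left after excluding rejected/internal")
  f1 <- vapply(unique(tl), function(p) {
    tp <- sum(tl == p & pl == p)
    fp <- sum(tl != p & pl == p)
    fn <- sum(tl == p & pl != p)
    if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  }, numeric(1L))
  stats::median(f1)
}

#' Stratified k-fold cross-validation of a hierarchical classifier
#'
#' Folds are assigned per population (stratified) with a user seed. Per
#' fold, a hierarchy is trained on the remaining cells and the held-out
#' fold is predicted; the hierarchical F1, the median F1, and the rejected
#' and internal-prediction fractions are reported.
#'
#' @param x Cell-by-gene matrix or \code{SummarizedExperiment}.
#' @param labels Per-cell labels (or \code{colData(x)$label}).
#' @param tree The \code{ClassificationTree} to train on.
#' @param kind Classifier kind.
#' @param k Number of folds (at least 2).
#' @param seed Seed for the fold assignment.
#' @param ... Passed to \code{\link{trainHierarchy}}.
#' @return \code{data.frame} with one row per fold: \code{fold},
#'   \code{HF1}, \code{medianF1}, \code{pctRejected}, \code{pctInternal}.
#' @export
kfoldEvaluate <- function(x, labels = NULL, tree, kind = c("linear",
                          "one_class"), k = 10L, seed = 1L, ...) {
  kind <- match.arg(kind)
  labels <- .getLabels(x, labels)
  x <- .asCellMatrix(x)
  if (k < 2L) stop("k must be at least 2")
  folds <- integer(length(labels))
  .withSeed(seed, for (p in unique(labels)) {
    idx <- which(labels == p)
    folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
  })
  if (any(table(labels, factor(folds, levels = seq_len(k))) == 0))
    stop("some fold lacks cells of a population; use a smaller k")
  res <- lapply(seq_len(k), function(f) {
    h <- trainHierarchy(x[folds != f, , drop = FALSE], labels[folds != f],
                        tree, kind = kind, ...)
    pred <- predictLabels(h, x[folds == f, , drop = FALSE])
    hf <- hierarchicalF1(labels[folds == f], pred, tree)
    data.frame(fold = f, HF1 = hf$HF1,
               medianF1 = medianF1(labels[folds == f], pred, tree),
               pctRejected = 100 * mean(pred == "rejected"),
               pctInternal = 100 * mean(pred %in% treeInternal(tree)))
  })
  do.call(rbind, res)
}
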