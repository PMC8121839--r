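#' Trained hierarchical classifier
#'
#' A classification tree together with one local classifier per non-root
#' node, a shared PCA projection, and a calibrated reconstruction-error
#' rejection model. Produced by \code{\link{trainHierarchy}}, consumed by
#' \code{\link{predictLabels}}.
#'
#' @slot tree The \code{ClassificationTree}.
#' @slot nodeModels Named list of \code{NodeClassifier} objects, one per
#'   non-root node.
#' @slot rejection The \code{RejectionModel}; its projection (fitted on the
#'   full training data) is also the component space the node classifiers
#'   live in.
#' @slot kind \code{"linear"} or \code{"one_class"}.
#'
#' @export
setClass("TrainedHierarchy",
         representation(tree = "ClassificationTree", nodeModels = "list",
                        rejection = "RejectionModel", kind = "character"))

setValidity("TrainedHierarchy", function(object) {
  want <- setdiff(nodeNames(object@tree), rootName(object@tree))
  if (!setequal(names(object@nodeModels), want))
    return("need exactly one node model per non-root node")
  TRUE
})

#' Train a hierarchical classifier on a labeled dataset and tree
#'
#' Fits a shared PCA (default 100 components) on the training data, then for
#' every node except the root: selects positive/negative cells (siblings
#' policy), picks informative components (Bonferroni-corrected Welch
#' t-tests, five-smallest fallback), and fits the local classifier.
#' The reconstruction-error rejection threshold is calibrated on the same
#' training data by nested five-fold cross-validation.
#'
#' @param x Cell-by-gene log-expression matrix, or a
#'   \code{SummarizedExperiment}/\code{SingleCellExperiment} (genes in rows,
#'   assay \code{"logcounts"}).
#' @param labels Per-cell population labels; every label must be a node of
#'   \code{tree}. May be omitted when \code{x} carries
#'   \code{colData(x)$label}.
#' @param tree A \code{ClassificationTree}.
#' @param kind Classifier kind, \code{"linear"} or \code{"one_class"}.
#' @param q Rejection percentile, default 0.99.
#' @param nComponents Shared PCA size, default 100.
#' @param alpha Significance level for component selection, default 0.05.
#' @return A \code{TrainedHierarchy}.
#' @export
trainHierarchy <- function(x, labels = NULL, tree, kind = c("linear",
                           "one_class"), q = 0.99, nComponents = 100L,
                           alpha = 0.05) {
  kind <- match.arg(kind)
  labels <- .getLabels(x, labels)
  x <- .asCellMatrix(x)
  if (nrow(x) != length(labels))
    stop("label count (", length(labels), ") does not match cell count (",
         nrow(x), ")")
  bad <- setdiff(unique(labels), setdiff(nodeNames(tree), rootName(tree)))
  if (length(bad))
    stop("labels missing from the tree: ",
         paste(utils::head(bad, 10L), collapse = ", "))
  rejection <- learnRejectionThreshold(x, q = q, nComponents = nComponents)
  scores <- .pcaScores(rejection@center, rejection@rotation, x)
  models <- list()
  for (node in setdiff(nodeNames(tree), rootName(tree))) {
    sets <- selectTrainingSets(tree, node, labels)
    sel <- selectInformativePCs(scores[sets$positive, , drop = FALSE],
                                scores[sets$negative, , drop = FALSE],
                                alpha = alpha)$selected
    models[[node]] <- fitNodeClassifier(
      kind,
      positives = scores[sets$positive, sel, drop = FALSE],
      negatives = scores[sets$negative, sel, drop = FALSE],
      pcIndices = sel, nodeName = node)
  }
  new("TrainedHierarchy", tree = tree, nodeModels = models,
      rejection = rejection, kind = kind)
}

#' Predict cell labels with a trained hierarchy
#'
#' Per cell, first the reconstruction-error filter: cells whose error
#' exceeds the calibrated threshold are rejected outright. Remaining cells
#' walk the tree from the root. At each node the children's classifiers are
#' scored: if all call the cell negative, the cell is rejected (at the
#' root) or labeled with the current node's name (an internal prediction);
#' if exactly one child is positive the cell descends into it; if several
#' are positive the cell descends into the positive child with the highest
#' signed score (ties broken by child order). Reaching a leaf emits the
#' leaf's name.
#'
#' @param h A \code{TrainedHierarchy}.
#' @param cells Cell-by-gene matrix (or \code{SummarizedExperiment}) in the
#'   training gene space.
#' @param applyRejection Apply the reconstruction-error filter first
#'   (default \code{TRUE}).
#' @return Character vector: a leaf name, an internal node name, or
#'   \code{"rejected"}, per cell.
#' @export
predictLabels <- function(h, cells, applyRejection = TRUE) {
  stopifnot(is(h, "TrainedHierarchy"))
  x <- .asCellMatrix(cells)
  n <- nrow(x)
  out <- rep(NA_character_, n)
  active <- seq_len(n)
  if (applyRejection) {
    err <- reconstructionError(h@rejection, x)
    out[err > h@rejection@threshold] <- "rejected"
    active <- which(is.na(out))
  }
  if (!length(active)) return(out)
  scores <- .pcaScores(h@rejection@center, h@rejection@rotation,
                       x[active, , drop = FALSE])
  root <- rootName(h@tree)
  walk <- function(node, idx) {
    ## idx: row indices into `scores` / `active`
    ch <- childrenOf(h@tree, node)
    if (!length(ch)) { out[active[idx]] <<- node; return(invisible()) }
    sc <- matrix(-Inf, length(idx), length(ch))
    for (k in seq_along(ch)) {
      m <- h@nodeModels[[ch[[k]]]]
      r <- scoreAndClassify(m, scores[idx, m@pcIndices, drop = FALSE])
      sc[, k] <- ifelse(r$call, r$score, -Inf)
    }
    nPos <- rowSums(sc > -Inf)
    stopHere <- nPos == 0L
    if (any(stopHere))
      out[active[idx[stopHere]]] <<- if (node == root) "rejected" else node
    go <- which(!stopHere)
    if (length(go)) {
      best <- max.col(sc[go, , drop = FALSE], ties.method = "first")
      for (k in unique(best))
        walk(ch[[k]], idx[go[best == k]])
    }
    invisible()
  }
  walk(root, seq_along(active))
  out
}

setMethod("show", "TrainedHierarchy", function(object) {
  cat("TrainedHierarchy (", object@kind, "), ",
      length(object@nodeModels), " node classifiers\n", sep = "")
  cat(" rejection threshold:", signif(object@rejection@threshold, 4L),
      "( q =", object@rejection@q, ")\n")
  cat(" tree:", writeNewick(object@tree), "\n")
})
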