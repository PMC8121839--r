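#' Local per-node classifier
#'
#' The decision unit attached to one node of the classification tree. The
#' \code{linear} kind is an L2-regularised linear max-margin classifier
#' (support vector machine with a linear kernel) trained on positive versus
#' negative cells; the \code{one_class} kind is a one-class SVM
#' (\code{nu = 0.05}, radial kernel with variance-scaled gamma) fitted on
#' positive cells only, so it can reject cells that fall outside the
#' population's boundary. Both operate on the node's selected informative
#' principal components.
#'
#' @slot kind \code{"linear"} or \code{"one_class"}.
#' @slot pcIndices Sorted component indices the model was trained on.
#' @slot fit The fitted \code{e1071::svm} object.
#' @slot flip +1 or -1, orienting decision values so positives score > 0.
#' @slot nodeName Label of the tree node the model belongs to.
#'
#' @export
setClass("NodeClassifier",
         representation(kind = "character", pcIndices = "integer",
                        fit = "ANY", flip = "numeric",
                        nodeName = "character"))

setValidity("NodeClassifier", function(object) {
  if (!object@kind %in% c("linear", "one_class"))
    return("kind must be 'linear' or 'one_class'")
  if (!length(object@pcIndices) || is.unsorted(object@pcIndices))
    return("pcIndices must be non-empty and sorted ascending")
  TRUE
})

#' Select positive and negative training cells for a node
#'
#' Positives are cells labeled with the node or any of its descendants.
#' Negatives follow the siblings policy: cells labeled under any sibling's
#' subtree (siblings share the node's parent; the parent itself is
#' excluded). If the node has no siblings, cells labeled exactly as the
#' parent -- but not under the node -- are the negatives.
#'
#' @param tree A \code{ClassificationTree}.
#' @param node A non-root node name.
#' @param labels Per-cell label vector (values must be tree node names).
#' @return List with integer index vectors \code{positive} and
#'   \code{negative}.
#' @export
selectTrainingSets <- function(tree, node, labels) {
  .checkNode(tree, node)
  if (node == rootName(tree)) stop("the root carries no classifier")
  labels <- as.character(labels)
  pos <- which(labels %in% subtreeLabels(tree, node))
  if (!length(pos))
    stop("no positive training cells for node '", node, "'")
  parent <- parentOf(tree, node)
  sibs <- setdiff(childrenOf(tree, parent), node)
  if (length(sibs)) {
    negLabels <- unlist(lapply(sibs, function(s) subtreeLabels(tree, s)))
    neg <- which(labels %in% negLabels)
  } else {
    neg <- which(labels == parent)
  }
  list(positive = pos, negative = neg)
}

## Vectorised Welch two-sample t-test, one test per column. Returns two-sided
## p-values. Degenerate columns (zero pooled standard error) get p = 1 when
## the means agree and p = 0 otherwise.
.welchP <- function(pos, neg) {
  n1 <- nrow(pos); n2 <- nrow(neg)
  m1 <- colMeans(pos); m2 <- colMeans(neg)
  v1 <- apply(pos, 2L, stats::var); v2 <- apply(neg, 2L, stats::var)
  se2 <- v1 / n1 + v2 / n2
  p <- rep(1, length(m1))
  ok <- se2 > 0
  tstat <- (m1[ok] - m2[ok]) / sqrt(se2[ok])
  df <- se2[ok]^2 / ((v1[ok] / n1)^2 / (n1 - 1) + (v2[ok] / n2)^2 / (n2 - 1))
  p[ok] <- 2 * stats::pt(-abs(tstat), df)
  p[!ok & abs(m1 - m2) > 0] <- 0
  p
}

#' Select informative principal components for a node
#'
#' Per component, a two-sided two-sample Welch t-test between the positive
#' and negative cells; components passing the Bonferroni-corrected level
#' (\code{alpha} divided by the number of components) are selected. When
#' none pass, the five components with the smallest p-values are used, so
#' the selection is never empty.
#'
#' @param pos,neg Score matrices (cells by components) for the positive and
#'   negative training cells; same number of columns.
#' @param alpha Family significance level; default 0.05.
#' @return List with elements \code{selected} (sorted component indices),
#'   \code{pValues}, \code{alpha}, \code{nComponents} and \code{fallback}
#'   (logical: did the five-smallest fallback fire).
#' @export
selectInformativePCs <- function(pos, neg, alpha = 0.05) {
  pos <- as.matrix(pos); neg <- as.matrix(neg)
  if (ncol(pos) != ncol(neg)) stop("component count mismatch")
  if (nrow(pos) < 2L || nrow(neg) < 2L)
    stop("need at least 2 cells in each class for the t-test")
  p <- .welchP(pos, neg)
  nc <- ncol(pos)
  sel <- which(p < alpha / nc)
  fallback <- !length(sel)
  if (fallback) sel <- sort(order(p)[seq_len(min(5L, nc))])
  list(selected = as.integer(sel), pValues = p, alpha = alpha,
       nComponents = nc, fallback = fallback)
}

#' Fit a local node classifier
#'
#' @param kind \code{"linear"} (needs positives and negatives) or
#'   \code{"one_class"} (positives only, \code{nu = 0.05}).
#' @param positives Cell-by-component matrix of positive cells.
#' @param negatives Cell-by-component matrix of negative cells
#'   (ignored by \code{one_class}).
#' @param pcIndices Component indices the matrices' columns correspond to
#'   (bookkeeping for prediction-time subsetting).
#' @param nodeName Node label, for error messages and reports.
#' @return A \code{NodeClassifier}.
#' @export
fitNodeClassifier <- function(kind = c("linear", "one_class"), positives,
                              negatives = NULL,
                              pcIndices = seq_len(ncol(positives)),
                              nodeName = "", nu = 0.05,
                              kernel = c("radial", "linear")) {
  kind <- match.arg(kind)
  kernel <- match.arg(kernel)
  positives <- as.matrix(positives)
  pcIndices <- as.integer(pcIndices)
  if (ncol(positives) != length(pcIndices))
    stop("pcIndices must match the column count of the training matrices")
  if (kind == "one_class") {
    if (nrow(positives) < 2L)
      stop("one-class classifier for node '", nodeName,
           "' needs at least 2 positive cells")
    ## radial kernel with variance-scaled gamma: a linear kernel cannot
    ## enclose a population (a halfspace through centered data leaves ~50%
    ## outside and voids the nu guarantee)
    v <- stats::var(as.vector(positives))
    fit <- e1071::svm(x = positives, y = NULL, type = "one-classification",
                      nu = nu, kernel = kernel, scale = FALSE,
                      gamma = if (v > 0) 1 / (ncol(positives) * v) else 1)
    return(new("NodeClassifier", kind = kind, pcIndices = pcIndices,
               fit = fit, flip = 1, nodeName = nodeName))
  }
  negatives <- as.matrix(negatives)
  if (!nrow(positives) || !nrow(negatives))
    stop("linear classifier for node '", nodeName,
         "' needs positive and negative cells")
  xx <- rbind(positives, negatives)
  yy <- factor(rep(c("pos", "neg"), c(nrow(positives), nrow(negatives))),
               levels = c("pos", "neg"))
  fit <- tryCatch(
    e1071::svm(x = xx, y = yy, type = "C-classification", kernel = "linear",
               cost = 1, scale = FALSE, tolerance = 1e-4),
    error = function(e) stop("linear classifier for node '", nodeName,
                             "' could not be fitted: ", conditionMessage(e)))
  ## orient decision values: positives must score > 0 on average
  dv <- attr(stats::predict(fit, xx, decision.values = TRUE),
             "decision.values")[, 1L]
  flip <- if (mean(dv[seq_len(nrow(positives))]) >=
              mean(dv[nrow(positives) + seq_len(nrow(negatives))])) 1 else -1
  new("NodeClassifier", kind = kind, pcIndices = pcIndices, fit = fit,
      flip = flip, nodeName = nodeName)
}

#' Score cells with a node classifier
#'
#' Returns a binary call and a continuous signed score per cell. The score
#' is the signed distance-like decision value of the underlying SVM,
#' oriented so that positive calls have score > 0; scores are comparable
#' across sibling nodes for the highest-score rule during prediction.
#'
#' @param model A \code{NodeClassifier}.
#' @param cells Matrix of cells expressed in the node's selected components
#'   (column count must equal \code{length(model@pcIndices)}).
#' @return List with logical \code{call} and numeric \code{score}.
#' @export
scoreAndClassify <- function(model, cells) {
  stopifnot(is(model, "NodeClassifier"))
  cells <- as.matrix(cells)
  if (ncol(cells) != length(model@pcIndices))
    stop("component-count mismatch: got ", ncol(cells), ", expected ",
         length(model@pcIndices))
  dv <- attr(stats::predict(model@fit, cells, decision.values = TRUE),
             "decision.values")[, 1L]
  score <- model@flip * as.numeric(dv)
  list(call = score > 0, score = score)
}

setMethod("show", "NodeClassifier", function(object) {
  cat("NodeClassifier(", object@kind, ") for node '", object@nodeName,
      "' on ", length(object@pcIndices), " components\n", sep = "")
})
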