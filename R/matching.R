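#' Cross-prediction confusion matrix
#'
#' Counts how many cells of each true population were predicted to be each
#' label of the other dataset's classifier. Predictions may be leaf nodes,
#' internal nodes, or \code{"rejected"}; all get their own column.
#'
#' @param trueLabels Per-cell true population labels.
#' @param predictedLabels Per-cell predictions, drawn from
#'   \code{vocabulary} or \code{"rejected"}.
#' @param vocabulary The predicting classifier's node names.
#' @return Integer matrix; rows are the true populations (in order of first
#'   appearance), columns are \code{vocabulary} plus \code{"rejected"}.
#' @export
crossPredictionConfusion <- function(trueLabels, predictedLabels,
                                     vocabulary) {
  trueLabels <- as.character(trueLabels)
  predictedLabels <- as.character(predictedLabels)
  if (length(trueLabels) != length(predictedLabels))
    stop("label vectors must have equal length")
  vocab <- unique(c(as.character(vocabulary), "rejected"))
  bad <- setdiff(unique(predictedLabels), vocab)
  if (length(bad))
    stop("predictions outside the vocabulary: ",
         paste(utils::head(bad, 10L), collapse = ", "))
  tab <- table(factor(trueLabels, levels = unique(trueLabels)),
               factor(predictedLabels, levels = vocab))
  m <- matrix(as.integer(tab), nrow(tab), ncol(tab),
              dimnames = dimnames(tab))
  names(dimnames(m)) <- NULL
  m
}

#' Row-normalize a confusion matrix
#'
#' Each row is divided by its sum, giving the fraction of each population's
#' cells assigned to each prediction. Rows summing to zero (a population
#' with no cells) are an error.
#'
#' @param C Non-negative confusion matrix.
#' @return Row-stochastic matrix of the same shape.
#' @export
normalizeConfusion <- function(C) {
  C <- as.matrix(C)
  rs <- rowSums(C)
  if (any(rs == 0))
    stop("zero row(s) in confusion matrix: ",
         paste(utils::head(rownames(C)[rs == 0], 10L), collapse = ", "))
  sweep(C, 1L, rs, "/")
}

#' Binarize matching fractions with the ranked-gap rule
#'
#' Per row, fractions are ranked in decreasing order (ties keep column
#' order). The highest fraction is set to 1; walking down the ranking, each
#' fraction whose gap to the preceding (higher) fraction is strictly less
#' than \code{threshold} is also set to 1; the first gap at or above the
#' threshold stops the walk and everything below it is 0. Multiple matches
#' per population are thereby allowed (a population split roughly in half
#' matches both parts).
#'
#' @param NC Row-stochastic matrix from \code{\link{normalizeConfusion}}.
#' @param threshold Gap threshold, default 0.25.
#' @return Binary 0/1 matrix of the same shape.
#' @export
binarizeMatches <- function(NC, threshold = 0.25) {
  NC <- as.matrix(NC)
  if (threshold <= 0) stop("threshold must be positive")
  B <- array(0L, dim(NC), dimnames = dimnames(NC))
  for (i in seq_len(nrow(NC))) {
    v <- NC[i, ]
    o <- order(v, decreasing = TRUE)
    B[i, o[[1L]]] <- 1L
    for (k in seq_along(o)[-1L]) {
      if (v[o[[k - 1L]]] - v[o[[k]]] < threshold) B[i, o[[k]]] <- 1L
      else break
    }
  }
  B
}

#' Combine directed matches into the matching matrix X
#'
#' \code{X = t(BC1) + BC2} on the population-by-population block: rows are
#' the populations of the second dataset, columns those of the first. An
#' entry of 2 is a reciprocal match, 1 a one-sided match, 0 no match.
#' Matches of a population to the other side's \code{"rejected"} column (or
#' to labels outside the population block) are kept as bookkeeping
#' attributes \code{"d1Extra"}/\code{"d2Extra"} for scenario analysis, but
#' do not enter the block itself.
#'
#' @param BC1 Binary match matrix of dataset-1 populations (rows) against
#'   dataset-2 predictions (columns).
#' @param BC2 Binary match matrix of dataset-2 populations (rows) against
#'   dataset-1 predictions (columns).
#' @param populationsD1,populationsD2 The population labels of each dataset
#'   (default: the rownames of \code{BC1}/\code{BC2}).
#' @return Integer matrix with entries in \{0,1,2\}.
#' @export
buildMatchingMatrix <- function(BC1, BC2,
                                populationsD1 = rownames(BC1),
                                populationsD2 = rownames(BC2)) {
  BC1 <- as.matrix(BC1); BC2 <- as.matrix(BC2)
  if (!all(populationsD1 %in% rownames(BC1)) ||
      !all(populationsD1 %in% colnames(BC2)))
    stop("dataset-1 populations must be rows of BC1 and columns of BC2")
  if (!all(populationsD2 %in% rownames(BC2)) ||
      !all(populationsD2 %in% colnames(BC1)))
    stop("dataset-2 populations must be rows of BC2 and columns of BC1")
  X <- t(BC1[populationsD1, populationsD2, drop = FALSE]) +
    BC2[populationsD2, populationsD1, drop = FALSE]
  storage.mode(X) <- "integer"
  attr(X, "d1Extra") <-
    BC1[populationsD1, setdiff(colnames(BC1), populationsD2), drop = FALSE]
  attr(X, "d2Extra") <-
    BC2[populationsD2, setdiff(colnames(BC2), populationsD1), drop = FALSE]
  X
}

#' Reciprocally match the populations of two datasets
#'
#' Cross-predicts (the hierarchy of each dataset predicts the cells of the
#' other), builds both confusion matrices, row-normalizes, binarizes with
#' the ranked-gap rule, and combines them into the matching matrix X.
#'
#' @param h1,h2 \code{TrainedHierarchy} objects for datasets 1 and 2.
#' @param x1,x2 Cell-by-gene matrices (or \code{SummarizedExperiment}s).
#' @param labels1,labels2 Per-cell population labels.
#' @param threshold Binarization gap threshold, default 0.25.
#' @param applyRejection Apply the reconstruction filter during
#'   cross-prediction (default \code{TRUE}).
#' @return The matching matrix X (rows: dataset-2 populations, columns:
#'   dataset-1 populations).
#' @export
matchDatasets <- function(h1, x1, labels1, h2, x2, labels2,
                          threshold = 0.25, applyRejection = TRUE) {
  labels1 <- as.character(labels1); labels2 <- as.character(labels2)
  pred1by2 <- predictLabels(h2, x1, applyRejection = applyRejection)
  pred2by1 <- predictLabels(h1, x2, applyRejection = applyRejection)
  C1 <- crossPredictionConfusion(labels1, pred1by2, nodeNames(h2@tree))
  C2 <- crossPredictionConfusion(labels2, pred2by1, nodeNames(h1@tree))
  BC1 <- binarizeMatches(normalizeConfusion(C1), threshold)
  BC2 <- binarizeMatches(normalizeConfusion(C2), threshold)
  buildMatchingMatrix(BC1, BC2)
}
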