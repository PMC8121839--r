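#' PCA projection with a calibrated reconstruction-error threshold
#'
#' A linear dimension reduction (default 100 components) fitted on training
#' data, together with a scalar reconstruction-error cutoff used to reject
#' cells from populations the training data never saw. A population absent
#' from training is not represented by the retained components, so its cells
#' lie far from the component plane and their reconstruction error is high.
#'
#' @slot center Per-gene means of the training data.
#' @slot rotation Orthonormal gene-by-component loading matrix.
#' @slot q Percentile (in (0,1)) used for calibration, default 0.99.
#' @slot threshold Non-negative scalar cutoff: the median across folds of
#'   the per-fold \code{q}-th percentile of held-out reconstruction errors.
#' @slot foldPercentiles The five per-fold percentiles behind the threshold.
#'
#' @export
setClass("RejectionModel",
         representation(center = "numeric", rotation = "matrix",
                        q = "numeric", threshold = "numeric",
                        foldPercentiles = "numeric"))

setValidity("RejectionModel", function(object) {
  if (length(object@q) != 1L || object@q <= 0 || object@q >= 1)
    return("q must be a single value in (0,1)")
  if (length(object@threshold) != 1L || object@threshold < 0)
    return("threshold must be a single non-negative value")
  if (nrow(object@rotation) != length(object@center))
    return("rotation rows must match center length")
  TRUE
})

## Exact truncated PCA. Returns list(center, rotation) with at most ncomp
## columns; rank-deficient directions (relative eigenvalue < tol) dropped.
## Uses the covariance side (p x p) when genes <= cells, the gram side
## otherwise; both are exact eigendecompositions.
.fitPCA <- function(x, ncomp = 100L, gram = NULL) {
  x <- as.matrix(x)
  n <- nrow(x); p <- ncol(x)
  if (n < 2L) stop("need at least 2 cells to fit a PCA")
  center <- colMeans(x)
  k <- min(ncomp, n - 1L, p)
  if (p <= n) {
    ## covariance-side eigendecomposition; crossprod(xc) = X'X - n mu mu'
    ## avoids materialising the centered copy and lets callers reuse X'X
    if (is.null(gram)) gram <- crossprod(x)
    e <- eigen(gram - n * tcrossprod(center), symmetric = TRUE)
    keep <- which(e$values > max(e$values[[1L]], 0) * 1e-12)
    keep <- keep[seq_len(min(k, length(keep)))]
    rot <- e$vectors[, keep, drop = FALSE]
  } else {
    xc <- sweep(x, 2L, center, check.margin = FALSE)
    e <- eigen(tcrossprod(xc), symmetric = TRUE)
    keep <- which(e$values > max(e$values[[1L]], 0) * 1e-12)
    keep <- keep[seq_len(min(k, length(keep)))]
    rot <- crossprod(xc, sweep(e$vectors[, keep, drop = FALSE], 2L,
                               sqrt(e$values[keep]), "/",
                               check.margin = FALSE))
  }
  if (!ncol(rot)) stop("training data has zero variance")
  dimnames(rot) <- NULL
  list(center = center, rotation = rot)
}

.pcaScores <- function(center, rotation, x) {
  x <- as.matrix(x)
  if (ncol(x) != length(center))
    stop("gene dimension mismatch: got ", ncol(x), ", expected ",
         length(center))
  sweep(x, 2L, center, check.margin = FALSE) %*% rotation
}

#' Per-cell PCA reconstruction error
#'
#' The Euclidean distance between a cell's expression vector and its
#' reconstruction after projecting onto the retained components and mapping
#' back (i.e., the distance of the cell to the component plane through the
#' training mean).
#'
#' @param model A \code{RejectionModel}.
#' @param cells Cell-by-gene matrix (or \code{SummarizedExperiment}).
#' @return Numeric vector of one non-negative error per cell.
#' @export
reconstructionError <- function(model, cells) {
  stopifnot(is(model, "RejectionModel"))
  x <- .asCellMatrix(cells)
  if (ncol(x) != length(model@center))
    stop("gene dimension mismatch: got ", ncol(x), ", expected ",
         length(model@center))
  xc <- sweep(x, 2L, model@center, check.margin = FALSE)
  sc <- xc %*% model@rotation
  sqrt(pmax(rowSums(xc^2) - rowSums(sc^2), 0))
}

#' Calibrate the reconstruction-error rejection threshold
#'
#' Nested five-fold cross-validation: for each fold, a PCA (default 100
#' components) is fitted on the training split and the \code{q}-th
#' percentile of the held-out cells' reconstruction errors is recorded. The
#' threshold is the median of the five percentiles, so on in-distribution
#' data roughly a fraction \code{1 - q} of fresh cells exceed it (the
#' controllable false-negative rate). Finally the projection is refitted on
#' the whole dataset.
#'
#' @param x Cell-by-gene training matrix (or \code{SummarizedExperiment}).
#' @param q Percentile in (0,1); default 0.99.
#' @param nComponents Number of components to retain; default 100.
#' @param nFolds Number of calibration folds; default 5.
#' @return A \code{RejectionModel}.
#' @export
learnRejectionThreshold <- function(x, q = 0.99, nComponents = 100L,
                                    nFolds = 5L) {
  x <- .asCellMatrix(x)
  if (length(q) != 1L || !is.finite(q) || q <= 0 || q >= 1)
    stop("q must lie in (0,1)")
  n <- nrow(x)
  if (n < nFolds) stop("need at least ", nFolds, " cells")
  folds <- .withSeed(20210514L, sample(rep_len(seq_len(nFolds), n)))
  gram <- if (ncol(x) <= (nFolds - 1L) * n / nFolds) crossprod(x) else NULL
  perc <- vapply(seq_len(nFolds), function(f) {
    te <- folds == f
    xte <- x[te, , drop = FALSE]
    fit <- .fitPCA(x[!te, , drop = FALSE], nComponents,
                   gram = if (is.null(gram)) NULL else gram - crossprod(xte))
    xc <- sweep(xte, 2L, fit$center, check.margin = FALSE)
    err <- sqrt(pmax(rowSums(xc^2) - rowSums((xc %*% fit$rotation)^2), 0))
    unname(stats::quantile(err, q))
  }, numeric(1L))
  fit <- .fitPCA(x, nComponents, gram = gram)
  new("RejectionModel", center = fit$center, rotation = fit$rotation,
      q = q, threshold = stats::median(perc), foldPercentiles = perc)
}

setMethod("show", "RejectionModel", function(object) {
  cat("RejectionModel:", ncol(object@rotation), "components, q =",
      object@q, ", threshold =", signif(object@threshold, 4L), "\n")
})
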