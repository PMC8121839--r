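#' Configuration for the hierarchical count simulator
#'
#' The defaults are the package's benchmark conditions: six well-separated
#' leaf populations of 1500 cells each under a three-level hierarchy
#' (\code{\link{benchmarkTree}}), with 2000 genes. Counts follow a negative
#' binomial with gamma-distributed baseline gene means, log-normal per-cell
#' library sizes, and sparse multiplicative differential-expression factors
#' sampled per tree branch, so sibling leaves share the DE genes of their
#' common ancestors and centroid similarity decays with tree distance.
#'
#' @param nGenes Number of genes.
#' @param cellsPerLeaf Cells per leaf population.
#' @param tree Ground-truth \code{ClassificationTree}; every branch below
#'   the root receives its own DE factor vector.
#' @param deProb Probability that a gene is differential on a branch.
#' @param deScale Standard deviation of the log2 DE factors (the separation
#'   dial; larger separates populations more).
#' @param libMeanLog,libSdLog Log-normal library-size parameters.
#' @param dispersion Negative-binomial dispersion (\code{size = 1 /
#'   dispersion}).
#' @param geneMeanShape,geneMeanRate Gamma parameters of baseline gene
#'   means.
#' @param seed Simulation seed; identical configurations reproduce
#'   bitwise-identical datasets.
#' @return A list of class \code{"SimConfig"}.
#' @export
simConfig <- function(nGenes = 2000L, cellsPerLeaf = 1500L,
                      tree = benchmarkTree(), deProb = 0.1, deScale = 0.8,
                      libMeanLog = log(15000), libSdLog = 0.25,
                      dispersion = 0.3, geneMeanShape = 0.6,
                      geneMeanRate = 0.3, seed = 1L) {
  stopifnot(nGenes > 0, cellsPerLeaf > 0, deProb >= 0, deProb <= 1,
            deScale >= 0, dispersion > 0)
  structure(list(nGenes = as.integer(nGenes),
                 cellsPerLeaf = as.integer(cellsPerLeaf), tree = tree,
                 deProb = deProb, deScale = deScale,
                 libMeanLog = libMeanLog, libSdLog = libSdLog,
                 dispersion = dispersion, geneMeanShape = geneMeanShape,
                 geneMeanRate = geneMeanRate, seed = as.integer(seed)),
            class = "SimConfig")
}

#' The default three-level benchmark hierarchy
#'
#' Six leaf populations: Group1 directly under the root, Group2/Group3
#' under Group23, and Group4 plus the Group56 pair (Group5, Group6) under
#' Group456.
#'
#' @return A \code{ClassificationTree}.
#' @export
benchmarkTree <- function() {
  parseNewick(paste0("(Group1,(Group2,Group3)Group23,",
                     "(Group4,(Group5,Group6)Group56)Group456)root;"))
}

#' Simulate a hierarchically structured scRNA-seq dataset
#'
#' Per branch of the configured tree a sparse multiplicative DE factor
#' vector is drawn; each leaf's mean expression is the gene baseline times
#' the product of the factors along its root path. Counts are negative
#' binomial with cell-specific library sizes and the returned expression is
#' \code{log2(count + 1)}.
#'
#' @param config A \code{\link{simConfig}}.
#' @return List with \code{data}, a \code{SingleCellExperiment} (assay
#'   \code{"logcounts"}, genes in rows, \code{colData$label}), and
#'   \code{tree}, the ground-truth \code{ClassificationTree} (also stored
#'   in \code{metadata(data)$tree}).
#' @export
simulateHierarchicalCounts <- function(config = simConfig()) {
  stopifnot(inherits(config, "SimConfig"))
  tree <- config$tree
  leaves <- treeLeaves(tree)
  .withSeed(config$seed, {
    base <- stats::rgamma(config$nGenes, shape = config$geneMeanShape,
                          rate = config$geneMeanRate)
    branchLFC <- lapply(stats::setNames(nm = setdiff(nodeNames(tree),
                                                     rootName(tree))),
                        function(n) {
      de <- stats::rbinom(config$nGenes, 1L, config$deProb)
      de * stats::rnorm(config$nGenes, 0, config$deScale)
    })
    mats <- vector("list", length(leaves))
    labels <- character()
    for (li in seq_along(leaves)) {
      lfc <- rep(0, config$nGenes)
      for (n in c(leaves[[li]], ancestors(tree, leaves[[li]])))
        lfc <- lfc + branchLFC[[n]]
      mu <- base * 2^lfc
      p <- mu / sum(mu)
      lib <- stats::rlnorm(config$cellsPerLeaf, config$libMeanLog,
                           config$libSdLog)
      cnt <- matrix(stats::rnbinom(config$cellsPerLeaf * config$nGenes,
                                   mu = outer(lib, p),
                                   size = 1 / config$dispersion),
                    nrow = config$cellsPerLeaf)
      mats[[li]] <- log2(cnt + 1)
      labels <- c(labels, rep(leaves[[li]], config$cellsPerLeaf))
    }
  })
  x <- do.call(rbind, mats)
  rownames(x) <- sprintf("cell%d", seq_len(nrow(x)))
  colnames(x) <- sprintf("gene%d", seq_len(ncol(x)))
  sce <- SingleCellExperiment::SingleCellExperiment(
    assays = list(logcounts = t(x)),
    colData = S4Vectors::DataFrame(label = labels,
                                   row.names = rownames(x)))
  S4Vectors::metadata(sce)$tree <- tree
  list(data = sce, tree = tree)
}

#' Derive batches at different annotation resolutions
#'
#' Partitions the cells disjointly across batches (stratified by label),
#' then rewrites each batch's annotations: labels under a merge target (an
#' internal node) are replaced by the target's name, and removed leaf
#' populations are dropped from that batch entirely.
#'
#' @param data A \code{SingleCellExperiment} (or list with \code{x},
#'   \code{labels}) as produced by
#'   \code{\link{simulateHierarchicalCounts}}.
#' @param tree The ground-truth \code{ClassificationTree}.
#' @param scheme List with one element per batch; each element is a list
#'   with optional character vectors \code{mergeTo} (internal node names)
#'   and \code{remove} (leaf names).
#' @param seed Seed for the stratified partition.
#' @return List of batches, each a list with \code{x} (cell-by-gene matrix)
#'   and \code{labels}.
#' @export
deriveBatches <- function(data, tree, scheme, seed = 1L) {
  if (is.list(data) && !is(data, "SummarizedExperiment") &&
      !is.null(data$data))  # result of simulateHierarchicalCounts
    data <- data$data
  if (is(data, "SummarizedExperiment")) {
    labels <- .getLabels(data, NULL)
    x <- .asCellMatrix(data)
  } else {
    labels <- as.character(data$labels)
    x <- .asCellMatrix(data$x)
  }
  nb <- length(scheme)
  assign <- integer(length(labels))
  .withSeed(seed, for (p in unique(labels)) {
    idx <- which(labels == p)
    assign[idx] <- sample(rep_len(seq_len(nb), length(idx)))
  })
  lapply(seq_len(nb), function(b) {
    sc <- scheme[[b]]
    keep <- which(assign == b)
    lab <- labels[keep]
    for (rm in sc$remove) {
      if (!rm %in% treeLeaves(tree))
        stop("removals must name leaves: '", rm, "'")
      drop <- lab %in% subtreeLabels(tree, rm)
      keep <- keep[!drop]; lab <- lab[!drop]
    }
    for (m in sc$mergeTo) {
      if (!m %in% c(treeInternal(tree)))
        stop("merge target must be an internal node: '", m, "'")
      lab[lab %in% setdiff(subtreeLabels(tree, m), m)] <- m
    }
    list(x = x[keep, , drop = FALSE], labels = lab)
  })
}

#' Batch schemes for the tree-learning benchmark
#'
#' Three batches at increasing annotation resolution: Batch 1 is annotated
#' at the top level only (Group1, Group23, Group456), Batch 2 merges
#' Group5 and Group6 into Group56, and Batch 3 carries the full
#' resolution. With \code{missing = TRUE}, Batch 2 instead drops Group5
#' entirely (its remaining pair member keeps the plain Group6 label),
#' emulating a population absent from one dataset.
#'
#' @param missing Use the missing-population variant of Batch 2.
#' @return A scheme list for \code{\link{deriveBatches}}.
#' @export
benchmarkBatchScheme <- function(missing = FALSE) {
  b2 <- if (missing) list(remove = "Group5") else list(mergeTo = "Group56")
  list(batch1 = list(mergeTo = c("Group23", "Group456")),
       batch2 = b2,
       batch3 = list())
}
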