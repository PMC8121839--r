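## Shared fixtures built in code.

## Two (or more) well-separated Gaussian blobs in gene space.
makeBlobs <- function(nPer = 40L, centers = list(c(0, 0), c(8, 8)),
                      nGenes = 10L, sd = 1, seed = 1L,
                      labels = LETTERS[seq_along(centers)]) {
  set.seed(seed)
  x <- do.call(rbind, lapply(centers, function(ct) {
    mu <- rep(0, nGenes)
    mu[seq_along(ct)] <- ct
    matrix(stats::rnorm(nPer * nGenes, mean = rep(mu, each = nPer), sd = sd),
           nrow = nPer)
  }))
  rownames(x) <- sprintf("cell%d", seq_len(nrow(x)))
  colnames(x) <- sprintf("gene%d", seq_len(ncol(x)))
  list(x = x, labels = rep(labels, each = nPer))
}

## A random tree with nNodes non-root nodes named n1..nk attached uniformly.
randomTree <- function(nNodes = 8L, seed = 1L) {
  set.seed(seed)
  tree <- flatTree("n1")
  for (k in seq_len(nNodes)[-1L])
    tree <- addChild(tree, sample(nodeNames(tree), 1L), paste0("n", k))
  tree
}

## A small hierarchical simulation shared by several tests.
smallSim <- function(seed = 1L, nGenes = 300L, cellsPerLeaf = 60L, ...) {
  sim <- simulateHierarchicalCounts(
    simConfig(nGenes = nGenes, cellsPerLeaf = cellsPerLeaf, seed = seed, ...))
  list(x = t(SummarizedExperiment::assay(sim$data, "logcounts")),
       labels = SummarizedExperiment::colData(sim$data)$label,
       tree = sim$tree)
}
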