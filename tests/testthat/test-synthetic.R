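test_that("the simulator is bitwise deterministic and leaves the caller's RNG alone", {
  cfg <- simConfig(nGenes = 100L, cellsPerLeaf = 20L, seed = 5L)
  a <- simulateHierarchicalCounts(cfg)
  set.seed(777)
  before <- .Random.seed
  b <- simulateHierarchicalCounts(cfg)
  expect_identical(.Random.seed, before)
  expect_identical(SummarizedExperiment::assay(a$data),
                   SummarizedExperiment::assay(b$data))
  expect_identical(SummarizedExperiment::colData(a$data)$label,
                   SummarizedExperiment::colData(b$data)$label)

  ## different seed, different draws
  c <- simulateHierarchicalCounts(simConfig(nGenes = 100L,
                                            cellsPerLeaf = 20L, seed = 6L))
  expect_false(identical(SummarizedExperiment::assay(a$data),
                         SummarizedExperiment::assay(c$data)))
})

test_that("the benchmark tree has the documented three-level shape", {
  tr <- benchmarkTree()
  expect_setequal(treeLeaves(tr), paste0("Group", 1:6))
  expect_identical(ancestors(tr, "Group5"), c("Group56", "Group456"))
  expect_identical(ancestors(tr, "Group2"), "Group23")
  expect_identical(ancestors(tr, "Group1"), character())
})

test_that("batch derivation rewrites labels, drops removals and conserves cells", {
  sim <- smallSim(seed = 8, nGenes = 120L, cellsPerLeaf = 30L)
  batches <- deriveBatches(list(x = sim$x, labels = sim$labels), sim$tree,
                           benchmarkBatchScheme(), seed = 2L)
  expect_length(batches, 3L)
  expect_setequal(unique(batches[[1L]]$labels),
                  c("Group1", "Group23", "Group456"))
  expect_setequal(unique(batches[[2L]]$labels),
                  c("Group1", "Group2", "Group3", "Group4", "Group56"))
  expect_setequal(unique(batches[[3L]]$labels), paste0("Group", 1:6))
  ## identity partition: cells conserved across batches
  expect_identical(sum(vapply(batches, function(b) nrow(b$x), integer(1L))),
                   nrow(sim$x))

  missing <- deriveBatches(list(x = sim$x, labels = sim$labels), sim$tree,
                           benchmarkBatchScheme(missing = TRUE), seed = 2L)
  expect_false("Group5" %in% missing[[2L]]$labels)
  ## exactly one third of Group5's cells land in batch 2 and are dropped;
  ## everything else is conserved
  dropped <- sum(sim$labels == "Group5") / 3L
  expect_identical(sum(vapply(missing, function(b) nrow(b$x), integer(1L))),
                   as.integer(nrow(sim$x) - dropped))

  expect_error(deriveBatches(list(x = sim$x, labels = sim$labels), sim$tree,
                             list(list(mergeTo = "Group1"))),
               "internal node")
  expect_error(deriveBatches(list(x = sim$x, labels = sim$labels), sim$tree,
                             list(list(remove = "Group56"))),
               "leaves")
})

test_that("sibling leaves are closer than cousins in centroid correlation", {
  sim <- smallSim(seed = 13, nGenes = 500L, cellsPerLeaf = 50L)
  cent <- vapply(paste0("Group", 1:6),
                 function(g) colMeans(sim$x[sim$labels == g, ]),
                 numeric(ncol(sim$x)))
  r <- stats::cor(cent)
  ## tree distance orders similarity: siblings > cousins > across the root
  expect_gt(r["Group5", "Group6"], r["Group4", "Group5"])
  expect_gt(r["Group2", "Group3"], r["Group2", "Group5"])
  expect_gt(r["Group4", "Group5"], r["Group1", "Group5"])
})

test_that("separation scales with the DE dial, from chance to near-perfect", {
  accs <- vapply(c(0, 0.5, 1, 2), function(ds) {
    sim <- smallSim(seed = 17, nGenes = 300L, cellsPerLeaf = 50L,
                    deScale = ds)
    test <- seq_len(nrow(sim$x)) %% 3L == 0L
    h <- trainHierarchy(sim$x[!test, ], sim$labels[!test],
                        flatTree(unique(sim$labels)), kind = "linear")
    mean(predictLabels(h, sim$x[test, ],
                       applyRejection = FALSE) == sim$labels[test])
  }, numeric(1L))
  ## zero DE: populations exchangeable, accuracy near chance (1/6)
  expect_lt(accs[[1L]], 0.35)
  ## monotone non-decreasing in effect scale (small slack for noise)
  expect_true(all(diff(accs) > -0.02))
  ## wide separation: essentially perfect held-out accuracy
  expect_gt(accs[[4L]], 0.98)
})
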