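mkX <- function(m, d2, d1) {
  X <- matrix(as.integer(m), length(d2), length(d1), byrow = TRUE,
              dimnames = list(d2, d1))
  X
}

test_that("scenario resolution recognises the schematic patterns", {
  ## two perfect matches
  X <- mkX(c(2, 0, 0, 2), c("p", "q"), c("u", "v"))
  sc <- resolveScenarios(X)
  expect_setequal(vapply(sc, `[[`, character(1L), "kind"),
                  "match")
  expect_length(sc, 2L)

  ## a column with two reciprocal 2s is a split of the dataset-1 population
  X <- mkX(c(2, 2), c("j1", "j2"), "i")
  expect_identical(resolveScenarios(X)[[1L]]$kind, "split")

  ## a row with two reciprocal 2s is a merge under the dataset-2 population
  X <- mkX(c(2, 2), "i", c("j1", "j2"))
  expect_identical(resolveScenarios(X)[[1L]]$kind, "merge")

  ## an all-zero row is a new-population candidate
  X <- mkX(c(2, 0, 0, 0), c("p", "q"), c("u", "v"))
  kinds <- vapply(resolveScenarios(X), `[[`, character(1L), "kind")
  expect_true("new_population" %in% kinds)

  ## entangled rows and columns defer to the strict pass
  X <- mkX(c(2, 1, 1, 2), c("p", "q"), c("u", "v"))
  expect_setequal(vapply(resolveScenarios(X), `[[`, character(1L), "kind"),
                  "deferred")
})

test_that("updateTree applies perfect, split, merge and new-population edits", {
  ## perfect match: synonym, tree unchanged
  tr <- flatTree(c("u", "v"))
  X <- mkX(c(2, 0, 0, 2), c("p", "q"), c("u", "v"))
  up <- updateTree(tr, X)
  expect_true(sameTopology(up$tree, tr))
  expect_identical(unname(up$labelMap[c("p", "q")]), c("u", "v"))
  expect_setequal(up$report$scenario, "perfect")

  ## split: children attached under the split node
  tr <- flatTree(c("1", "2"))
  X <- mkX(c(2, 0, 2, 0, 0, 2), c("A", "B", "q"), c("1", "2"))
  up <- updateTree(tr, X)
  expect_true(sameTopology(up$tree, parseNewick("((A,B)1,2)root;")))
  expect_identical(unname(up$labelMap[c("A", "B")]), c("A", "B"))

  ## merge: new parent over sibling leaves
  tr <- flatTree(c("j1", "j2", "k"))
  X <- mkX(c(2, 2, 0, 0, 0, 2), c("i", "q"), c("j1", "j2", "k"))
  up <- updateTree(tr, X)
  expect_true(sameTopology(up$tree, parseNewick("((j1,j2)i,k)root;")))

  ## new population: reciprocally rejected row attached under the root
  tr <- flatTree(c("u", "v"))
  X <- mkX(c(2, 0, 0, 2, 0, 0), c("p", "q", "new1"), c("u", "v"))
  attr(X, "d2Extra") <- matrix(c(0L, 0L, 1L), 3, 1,
                               dimnames = list(c("p", "q", "new1"),
                                               "rejected"))
  up <- updateTree(tr, X)
  expect_identical(parentOf(up$tree, "new1"), "root")

  ## a zero row without rejection evidence stays unmatched: no edit
  X2 <- mkX(c(2, 0, 0, 2, 0, 0), c("p", "q", "s"), c("u", "v"))
  up2 <- updateTree(tr, X2)
  expect_true(sameTopology(up2$tree, tr))
  expect_false("s" %in% up2$report$population)

  ## all-zero matrix: no edits, empty report
  X <- mkX(rep(0, 4), c("p", "q"), c("u", "v"))
  up <- updateTree(flatTree(c("u", "v")), X)
  expect_true(sameTopology(up$tree, flatTree(c("u", "v"))))
  expect_identical(nrow(up$report), 0L)
})

test_that("the strict pass drops entangled one-sided matches and keeps isolated ones", {
  ## a multi-row multi-column tangle defers; the strict pass zeroes the
  ## entangled 1s, recovers the perfect match, and leaves the rest unmatched
  tr <- flatTree(c("u", "v", "w"))
  X <- mkX(c(2, 0, 1, 1, 0, 0), c("p", "s"), c("u", "v", "w"))
  up <- updateTree(tr, X)
  expect_identical(up$report$scenario[up$report$population == "p"], "perfect")
  expect_false("s" %in% up$report$population)
  expect_true(sameTopology(up$tree, tr))

  ## a column mixing a 2 with a one-sided 1 on otherwise-clean rows is a
  ## split: both dataset-2 populations become children
  trs <- flatTree(c("u", "v"))
  Xs <- mkX(c(2, 0, 1, 0, 0, 2), c("p", "s", "q"), c("u", "v"))
  ups <- updateTree(trs, Xs)
  expect_identical(parentOf(ups$tree, "p"), "u")
  expect_identical(parentOf(ups$tree, "s"), "u")

  ## an isolated 1 (sole nonzero in row and column) survives as a match
  X <- mkX(c(2, 0, 0, 1), c("p", "q"), c("u", "v"))
  up <- updateTree(flatTree(c("u", "v")), X)
  expect_identical(unname(up$labelMap[["q"]]), "v")

  ## a {1,2} single-row component resolves as a merge in the first pass
  tr <- flatTree(c("G5", "G6"))
  X <- mkX(c(1, 2), "G6b", c("G5", "G6"))
  up <- updateTree(tr, X)
  expect_true(sameTopology(up$tree, parseNewick("((G5,G6)G6b)root;")))
})

test_that("a lone reciprocal match to an internal node attaches a child", {
  tr <- parseNewick("((A,B)1,2)root;")
  X <- mkX(c(2), "p", "1")
  up <- updateTree(tr, X)
  expect_identical(parentOf(up$tree, "p"), "1")
  expect_identical(up$report$scenario, "refinement")
})

test_that("merges close over complete sibships and degrade to complex otherwise", {
  ## matched leaves {G4,G5,G6} with G5,G6 already grouped: parent over
  ## {G4, G56}
  tr <- parseNewick("(G4,(G5,G6)G56)root;")
  X <- mkX(c(2, 2, 2, 0), "G456", c("G4", "G5", "G6", "G56")) # plus G56 col
  up <- updateTree(tr, X)
  expect_true(sameTopology(up$tree,
                           parseNewick("((G4,(G5,G6)G56)G456)root;")))

  ## non-siblings that do not close over a sibship: complex, omitted
  tr2 <- parseNewick("((A,B)1,(C,D)2)root;")
  X2 <- mkX(c(2, 2), "m", c("A", "C"))
  expect_warning(up2 <- updateTree(tr2, X2), "complex")
  expect_true(sameTopology(up2$tree, tr2))
  expect_true(is.na(up2$labelMap[["m"]]))

  ## matched leaves exactly forming an existing grouping: synonym
  tr3 <- parseNewick("(G4,(G5,G6)G56)root;")
  X3 <- mkX(c(2, 2), "pair", c("G5", "G6"))
  up3 <- updateTree(tr3, X3)
  expect_true(sameTopology(up3$tree, tr3))
  expect_identical(unname(up3$labelMap[["pair"]]), "G56")
})

test_that("every dataset-2 population is accounted for exactly once", {
  tr <- flatTree(c("u", "v", "w"))
  set.seed(8)
  for (rep in 1:20) {
    d2 <- paste0("p", 1:4)
    X <- matrix(sample(0:2, 12L, replace = TRUE, prob = c(0.6, 0.2, 0.2)),
                4L, 3L, dimnames = list(d2, c("u", "v", "w")))
    up <- suppressWarnings(updateTree(tr, X))
    ## each population is resolved at most once; rows with matches are
    ## either edited, recorded as synonyms, or explicitly complex
    expect_identical(anyDuplicated(up$report$population), 0L)
    expect_true(all(up$report$population %in% d2))
    matched <- d2[rowSums(X != 0) > 0]
    resolved <- up$report$population[up$report$scenario != "complex"]
    expect_true(all(resolved %in% matched))
    expect_true(validObject(up$tree))
  }
})

test_that("two identical separable datasets learn a flat tree of perfect matches", {
  d <- makeBlobs(nPer = 60L, seed = 15L, nGenes = 12L,
                 centers = list(c(0, 0), c(10, 0), c(0, 10)),
                 labels = c("a", "b", "c"))
  half <- rep(c(TRUE, FALSE), length.out = nrow(d$x))
  res <- learnTreeProgressive(
    list(list(x = d$x[half, ], labels = d$labels[half]),
         list(x = d$x[!half, ], labels = d$labels[!half])),
    kind = "linear", nComponents = 10L)
  expect_true(sameTopology(res$tree, flatTree(c("a", "b", "c"))))
  expect_setequal(res$reports[[1L]]$scenario, "perfect")
})
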