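## Matching-matrix scenario resolution and the progressive learning loop.

## Connected components of the bipartite graph on nonzero entries of X.
## Returns a list of components, each with integer row/col index vectors.
.xComponents <- function(X) {
  nz <- which(X != 0, arr.ind = TRUE)
  if (!nrow(nz)) return(list())
  comps <- list()
  seenRow <- logical(nrow(X)); seenCol <- logical(ncol(X))
  for (s in seq_len(nrow(nz))) {
    if (seenRow[nz[s, 1L]]) next
    rows <- nz[s, 1L]; cols <- integer()
    repeat {
      newCols <- setdiff(unique(nz[nz[, 1L] %in% rows, 2L]), cols)
      newRows <- setdiff(unique(nz[nz[, 2L] %in% cols, 1L]), rows)
      if (!length(newCols) && !length(newRows)) break
      cols <- c(cols, newCols); rows <- c(rows, newRows)
    }
    seenRow[rows] <- TRUE; seenCol[cols] <- TRUE
    comps[[length(comps) + 1L]] <- list(rows = sort(rows), cols = sort(cols))
  }
  comps
}

#' Classify the matching matrix into tree-update scenarios
#'
#' Nonzero entries of X are grouped into connected components (shared rows
#' or columns). Each component is classified: a lone entry is a
#' \code{match} (perfect when reciprocal); a single-column component with
#' several rows is a \code{split} of that dataset-1 population; a
#' single-row component with several columns is a \code{merge} under that
#' dataset-2 population; anything larger is \code{deferred} -- it is left
#' for the strict second pass, which keeps only reciprocal 2s (and 1s that
#' are the sole nonzero in both their row and column) and re-classifies.
#' In the first pass, \code{match}/\code{split}/\code{merge} require at
#' least one reciprocal 2 in the component; in the strict pass a lone
#' surviving 1 also counts as a match. Rows with no nonzero entry at all
#' are \code{new_population} candidates.
#'
#' @param X Matching matrix from \code{\link{buildMatchingMatrix}}.
#' @param strict Strict-pass rules (lone 1 counts as a match).
#' @return List of scenarios: \code{kind}, \code{d2} (row labels),
#'   \code{d1} (column labels).
#' @export
resolveScenarios <- function(X, strict = FALSE) {
  X <- as.matrix(X)
  out <- list()
  for (cp in .xComponents(X)) {
    vals <- X[cp$rows, cp$cols, drop = FALSE]
    hasTwo <- any(vals == 2L)
    d2 <- rownames(X)[cp$rows]; d1 <- colnames(X)[cp$cols]
    kind <-
      if (length(cp$rows) == 1L && length(cp$cols) == 1L) {
        if (hasTwo || strict) "match" else "deferred"
      } else if (length(cp$cols) == 1L && hasTwo) {
        "split"
      } else if (length(cp$rows) == 1L && hasTwo) {
        "merge"
      } else {
        "deferred"
      }
    out[[length(out) + 1L]] <- list(kind = kind, d2 = d2, d1 = d1)
  }
  empty <- rownames(X)[rowSums(X != 0) == 0L]
  for (p in empty)
    out[[length(out) + 1L]] <- list(kind = "new_population", d2 = p,
                                    d1 = character())
  out
}

## Keep reciprocal 2s; keep a 1 only when it is the sole nonzero in both its
## row and its column (an isolated one-sided match); zero every other 1.
.strictX <- function(X) {
  ones <- which(X == 1L, arr.ind = TRUE)
  for (s in seq_len(nrow(ones))) {
    i <- ones[s, 1L]; j <- ones[s, 2L]
    if (sum(X[i, ] != 0) > 1L || sum(X[, j] != 0) > 1L) X[i, j] <- 0L
  }
  X
}

## Replace a set of tree node names by the minimal ancestor-closed form:
## if a node is in the set together with all of its children, the children
## are dropped; if all children of a node are in the set (node absent), they
## are replaced by the node. Makes merges tolerant of matches expressed at
## leaf level when the grouping node already exists.
.canonicalizeSet <- function(tree, set) {
  repeat {
    changed <- FALSE
    for (nm in setdiff(nodeNames(tree), treeLeaves(tree))) {
      ch <- childrenOf(tree, nm)
      if (!length(ch) || !all(ch %in% set)) next
      if (nm %in% set) {
        set <- setdiff(set, ch); changed <- TRUE
      } else if (nm != rootName(tree)) {
        set <- c(setdiff(set, ch), nm); changed <- TRUE
      }
    }
    if (!changed) break
  }
  set
}

.freshName <- function(tree, name) {
  if (!name %in% nodeNames(tree)) return(name)
  k <- 2L
  while (paste0(name, " (", k, ")") %in% nodeNames(tree)) k <- k + 1L
  paste0(name, " (", k, ")")
}

#' Update a classification tree from a matching matrix
#'
#' Applies the scenarios of \code{\link{resolveScenarios}} in priority
#' order (matches, then splits, then merges, then new populations): a
#' perfect match to a leaf records a synonym (the tree keeps the incumbent
#' name); a lone reciprocal match to an internal node attaches the
#' dataset-2 population as a new child; a split attaches the matched
#' dataset-2 populations as children of the dataset-1 node; a merge inserts
#' the dataset-2 population as a new parent over its matched dataset-1
#' nodes (which must be siblings after closing the set over complete
#' sibships -- otherwise the scenario degrades to complex); a dataset-2
#' population matching nothing becomes a child of the root when its cells
#' were reciprocally rejected (the bookkeeping carried by
#' \code{\link{buildMatchingMatrix}}), and is otherwise left out as
#' unmatched without an edit. Entries consumed by an
#' applied scenario are zeroed; if nonzeros remain a strict second sweep
#' keeps only reciprocal matches (plus isolated one-sided matches) and
#' tries once more. Populations still unresolved are omitted with a
#' warning.
#'
#' @param tree The dataset-1 \code{ClassificationTree}.
#' @param X Matching matrix (rows: dataset-2 populations, columns:
#'   dataset-1 populations; columns must be tree nodes).
#' @return List with the updated \code{tree}, a \code{report} data frame
#'   (population, scenario, mappedTo), and \code{labelMap}: named character
#'   vector taking each dataset-2 label to its tree node (\code{NA} for
#'   omitted populations).
#' @export
updateTree <- function(tree, X) {
  X <- as.matrix(X)
  storage.mode(X) <- "integer"
  if (!all(colnames(X) %in% nodeNames(tree)))
    stop("matching-matrix columns must be nodes of the tree")
  report <- data.frame(population = character(), scenario = character(),
                       mappedTo = character(), stringsAsFactors = FALSE)
  labelMap <- stats::setNames(rep(NA_character_, nrow(X)), rownames(X))
  note <- function(pop, scen, to) {
    report[nrow(report) + 1L, ] <<- list(pop, scen, to)
    if (pop %in% names(labelMap) && !is.na(to)) labelMap[[pop]] <<- to
  }
  apply1 <- function(sc, strict) {
    ## returns TRUE when the scenario was applied (entries to be zeroed)
    switch(sc$kind,
      match = {
        j <- sc$d1
        if (length(childrenOf(tree, j))) {
          nm <- .freshName(tree, sc$d2)
          tree <<- addChild(tree, j, nm)
          note(sc$d2, "refinement", nm)
        } else {
          note(sc$d2, "perfect", j)
        }
        TRUE
      },
      split = {
        for (p in sc$d2) {
          nm <- .freshName(tree, p)
          tree <<- addChild(tree, sc$d1, nm)
          note(p, "split", nm)
        }
        TRUE
      },
      merge = {
        set <- .canonicalizeSet(tree, sc$d1)
        if (length(set) == 1L) {
          ## the matched leaves are exactly an existing grouping: synonym
          note(sc$d2, "perfect", set)
          return(TRUE)
        }
        pars <- unique(vapply(set, function(s) parentOf(tree, s),
                              character(1L)))
        if (length(pars) == 1L && !is.na(pars)) {
          nm <- .freshName(tree, sc$d2)
          tree <<- insertParent(tree, set, nm)
          note(sc$d2, "merge", nm)
          TRUE
        } else if (strict) {
          note(sc$d2, "complex", NA_character_)
          TRUE  # consume: give up on this component
        } else FALSE
      },
      new_population = {
        ## only a reciprocally rejected population is genuinely new (a row
        ## of zeros without rejection evidence stays unmatched: no edit)
        d2x <- attr(X, "d2Extra")
        if (!is.null(d2x) && "rejected" %in% colnames(d2x) &&
            d2x[sc$d2, "rejected"] == 1) {
          nm <- .freshName(tree, sc$d2)
          tree <<- addChild(tree, rootName(tree), nm)
          note(sc$d2, "new_population", nm)
        }
        TRUE
      },
      deferred = {
        if (strict) {
          for (p in sc$d2) note(p, "complex", NA_character_)
          TRUE
        } else FALSE
      })
  }
  priority <- c("match", "split", "merge", "new_population", "deferred")
  sweep1 <- function(strict) {
    scen <- resolveScenarios(X, strict = strict)
    scen <- scen[order(match(vapply(scen, `[[`, character(1L), "kind"),
                             priority))]
    for (sc in scen) {
      ## new-population candidates are only valid if the population was not
      ## already handled in an earlier sweep
      if (sc$kind == "new_population" && sc$d2 %in% report$population) next
      if (apply1(sc, strict))
        X[sc$d2, sc$d1] <<- 0L
    }
  }
  sweep1(strict = FALSE)
  if (any(X != 0)) {
    X <- .strictX(X)
    sweep1(strict = TRUE)
  }
  unresolved <- report$population[report$scenario == "complex"]
  if (length(unresolved))
    warning(length(unresolved), " population(s) could not be added to the ",
            "tree due to complex scenarios: ",
            paste(unique(unresolved), collapse = ", "))
  list(tree = tree, report = report, labelMap = labelMap)
}

#' Progressively learn a classification tree from multiple datasets
#'
#' Iteration 1 starts from a flat tree over the first dataset's labels.
#' Each further iteration trains a flat classifier on the incoming dataset
#' and retrains the current tree on all pre-existing datasets pooled,
#' cross-predicts, matches reciprocally, and updates the tree. Incoming
#' cells whose population was folded into the tree join the pool (with
#' their labels mapped to tree nodes); populations omitted as complex drop
#' out.
#'
#' @param datasets List of datasets; each element is either a
#'   \code{SummarizedExperiment}/\code{SingleCellExperiment} with
#'   \code{colData$label}, or a list with elements \code{x} (cell-by-gene
#'   matrix) and \code{labels}. Expression spaces must be pre-aligned.
#' @param kind Classifier kind for every iteration.
#' @param threshold Matching gap threshold, default 0.25.
#' @param q,nComponents,alpha Passed to \code{\link{trainHierarchy}}.
#' @param applyRejection Use the reconstruction filter during
#'   cross-prediction.
#' @param verbose Print one line per applied scenario.
#' @return List with the final \code{tree}, the pooled training data
#'   (\code{x}, \code{labels}), and the per-iteration update \code{reports}.
#' @export
learnTreeProgressive <- function(datasets, kind = c("linear", "one_class"),
                                 threshold = 0.25, q = 0.99,
                                 nComponents = 100L, alpha = 0.05,
                                 applyRejection = TRUE, verbose = FALSE) {
  kind <- match.arg(kind)
  if (length(datasets) < 2L) stop("need at least 2 datasets")
  getXY <- function(d) {
    if (is(d, "SummarizedExperiment"))
      list(x = .asCellMatrix(d), labels = .getLabels(d, NULL))
    else if (is.list(d) && !is.null(d$x))
      list(x = .asCellMatrix(d$x), labels = as.character(d$labels))
    else stop("each dataset must be a SummarizedExperiment or list(x, labels)")
  }
  d1 <- getXY(datasets[[1L]])
  poolX <- d1$x; poolLabels <- d1$labels
  tree <- flatTree(unique(poolLabels))
  reports <- list()
  for (k in seq_along(datasets)[-1L]) {
    d2 <- getXY(datasets[[k]])
    h1 <- trainHierarchy(poolX, poolLabels, tree, kind = kind, q = q,
                         nComponents = nComponents, alpha = alpha)
    tree2 <- flatTree(unique(d2$labels))
    h2 <- trainHierarchy(d2$x, d2$labels, tree2, kind = kind, q = q,
                         nComponents = nComponents, alpha = alpha)
    X <- matchDatasets(h1, poolX, poolLabels, h2, d2$x, d2$labels,
                       threshold = threshold,
                       applyRejection = applyRejection)
    upd <- updateTree(tree, X)
    if (verbose)
      for (r in seq_len(nrow(upd$report)))
        message(sprintf("[iter %d] %-14s %s -> %s", k,
                        upd$report$scenario[r], upd$report$population[r],
                        upd$report$mappedTo[r]))
    tree <- upd$tree
    mapped <- upd$labelMap[d2$labels]
    keep <- !is.na(mapped)
    poolX <- rbind(poolX, d2$x[keep, , drop = FALSE])
    poolLabels <- c(poolLabels, mapped[keep])
    reports[[k - 1L]] <- upd$report
  }
  list(tree = tree, x = poolX, labels = poolLabels, reports = reports)
}
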