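#' @import methods
NULL

#' Rooted classification tree of named cell populations
#'
#' A rooted tree whose nodes are named cell populations. The root is a
#' synthetic node (conventionally named \code{"root"}) that never carries a
#' classifier; every other node corresponds to a population that can appear
#' as a cell label. A flat classifier is represented as a depth-1 tree: the
#' root with only leaf children.
#'
#' The tree is stored as a parent table: one row per node, in insertion
#' order. Child order among siblings is row order, so serialization is
#' deterministic.
#'
#' @slot nodes A \code{data.frame} with character columns \code{name} and
#'   \code{parent} (\code{NA} for the root only).
#'
#' @export
setClass("ClassificationTree", representation(nodes = "data.frame"))

setValidity("ClassificationTree", function(object) {
  nd <- object@nodes
  if (!all(c("name", "parent") %in% colnames(nd)))
    return("nodes must have columns 'name' and 'parent'")
  if (!is.character(nd$name) || !is.character(nd$parent))
    return("'name' and 'parent' must be character")
  if (any(!nzchar(nd$name)) || anyNA(nd$name))
    return("node names must be non-empty")
  dup <- nd$name[duplicated(nd$name)]
  if (length(dup))
    return(paste0("duplicate node name: '", dup[[1L]], "'"))
  rootIdx <- which(is.na(nd$parent))
  if (length(rootIdx) != 1L)
    return("exactly one node (the root) must have no parent")
  if (!all(nd$parent[-rootIdx] %in% nd$name))
    return("every non-root node must name an existing parent")
  ## reachability from the root implies acyclicity
  seen <- nd$name[rootIdx]
  frontier <- seen
  while (length(frontier)) {
    frontier <- nd$name[nd$parent %in% frontier]
    seen <- c(seen, frontier)
  }
  if (length(seen) != nrow(nd))
    return("tree contains nodes unreachable from the root (cycle?)")
  TRUE
})

.newTree <- function(name, parent) {
  obj <- new("ClassificationTree",
             nodes = data.frame(name = as.character(name),
                                parent = as.character(parent),
                                stringsAsFactors = FALSE))
  validObject(obj)
  obj
}

#' Build a flat (depth-1) classification tree
#'
#' @param labels Character vector of population names (the leaf children of
#'   the root).
#' @param rootName Name of the synthetic root node.
#' @return A \code{ClassificationTree}.
#' @examples
#' flatTree(c("A", "B", "C"))
#' @export
flatTree <- function(labels, rootName = "root") {
  labels <- as.character(unique(labels))
  if (!length(labels)) stop("need at least one population label")
  .newTree(c(rootName, labels), c(NA_character_, rep(rootName, length(labels))))
}

## ---- Newick parsing ------------------------------------------------------

#' Parse a Newick string with named internal nodes
#'
#' Every node (including internal nodes and the root) must be named and the
#' names must be unique. Branch lengths are accepted and ignored. Labels may
#' be single-quoted to include spaces, parentheses or commas.
#'
#' @param text A single Newick string, terminated by \code{";"}.
#' @return A \code{ClassificationTree} with identical topology and names;
#'   child order is preserved.
#' @examples
#' parseNewick("((A,B)1,2)root;")
#' @export
parseNewick <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  s <- trimws(text)
  if (!nzchar(s) || substr(s, nchar(s), nchar(s)) != ";")
    stop("Newick text must end with ';'")
  s <- substr(s, 1L, nchar(s) - 1L)
  chars <- strsplit(s, "", fixed = TRUE)[[1L]]
  n <- length(chars)
  pos <- 1L
  peek <- function() if (pos > n) "" else chars[[pos]]
  readLabel <- function() {
    if (peek() == "'") {
      pos <<- pos + 1L
      from <- pos
      while (pos <= n && chars[[pos]] != "'") pos <<- pos + 1L
      if (pos > n) stop("unterminated quoted label at position ", from)
      lab <- if (pos > from) paste0(chars[from:(pos - 1L)], collapse = "") else ""
      pos <<- pos + 1L
    } else {
      from <- pos
      while (pos <= n && !chars[[pos]] %in% c(",", "(", ")", ":", ";"))
        pos <<- pos + 1L
      lab <- if (pos > from) paste0(chars[from:(pos - 1L)], collapse = "") else ""
    }
    if (peek() == ":") {  # branch length: ignored
      pos <<- pos + 1L
      while (pos <= n && grepl("[0-9eE.+-]", chars[[pos]])) pos <<- pos + 1L
    }
    trimws(lab)
  }
  parseClade <- function() {
    children <- list()
    if (peek() == "(") {
      pos <<- pos + 1L
      repeat {
        children[[length(children) + 1L]] <- parseClade()
        if (peek() == ",") pos <<- pos + 1L else break
      }
      if (peek() != ")") stop("expected ')' at position ", pos)
      pos <<- pos + 1L
    }
    at <- pos
    lab <- readLabel()
    if (!nzchar(lab)) stop("unnamed node at position ", at, " of Newick text")
    list(name = lab, children = children)
  }
  clade <- parseClade()
  if (pos <= n) stop("trailing characters at position ", pos)
  name <- character()
  parent <- character()
  emit <- function(cl, par) {
    name <<- c(name, cl$name)
    parent <<- c(parent, par)
    for (ch in cl$children) emit(ch, cl$name)
  }
  emit(clade, NA_character_)
  dup <- name[duplicated(name)]
  if (length(dup)) stop("duplicate node name: '", dup[[1L]], "'")
  .newTree(name, parent)
}

.quoteLabel <- function(x) {
  needs <- grepl("[(),:;'[:space:]]", x)
  if (any(grepl("'", x)))
    stop("node names may not contain single quotes")
  ifelse(needs, paste0("'", x, "'"), x)
}

#' Serialize a classification tree to Newick text
#'
#' Deterministic given child order; no branch lengths are written.
#'
#' @param tree A \code{ClassificationTree}.
#' @return A single Newick string ending in \code{";"}.
#' @examples
#' writeNewick(flatTree(c("A", "B")))
#' @export
writeNewick <- function(tree) {
  stopifnot(is(tree, "ClassificationTree"))
  rec <- function(nm) {
    ch <- childrenOf(tree, nm)
    lab <- .quoteLabel(nm)
    if (!length(ch)) return(lab)
    paste0("(", paste(vapply(ch, rec, character(1L)), collapse = ","), ")", lab)
  }
  paste0(rec(rootName(tree)), ";")
}

## ---- accessors -----------------------------------------------------------

#' Node accessors for classification trees
#'
#' @param tree A \code{ClassificationTree}.
#' @param name A node name present in the tree.
#' @return \code{nodeNames}: all node names (root included);
#'   \code{rootName}: the root's name; \code{childrenOf}: the node's
#'   children in child order; \code{parentOf}: the parent name (\code{NA}
#'   for the root); \code{treeLeaves}: names of leaf nodes;
#'   \code{treeInternal}: names of non-root internal nodes.
#' @name tree-accessors
NULL

#' @rdname tree-accessors
#' @export
nodeNames <- function(tree) tree@nodes$name

#' @rdname tree-accessors
#' @export
rootName <- function(tree) tree@nodes$name[is.na(tree@nodes$parent)]

#' @rdname tree-accessors
#' @export
childrenOf <- function(tree, name) {
  .checkNode(tree, name)
  tree@nodes$name[!is.na(tree@nodes$parent) & tree@nodes$parent == name]
}

#' @rdname tree-accessors
#' @export
parentOf <- function(tree, name) {
  .checkNode(tree, name)
  tree@nodes$parent[tree@nodes$name == name]
}

#' @rdname tree-accessors
#' @export
treeLeaves <- function(tree) {
  nd <- tree@nodes
  nd$name[!nd$name %in% nd$parent]
}

#' @rdname tree-accessors
#' @export
treeInternal <- function(tree) {
  nd <- tree@nodes
  setdiff(nd$name[nd$name %in% nd$parent], rootName(tree))
}

.checkNode <- function(tree, name) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!name %in% tree@nodes$name)
    stop("unknown node: '", name, "'")
  invisible(name)
}

#' Ancestors of a node, excluding the root
#'
#' Returns the chain of ancestors from the immediate parent up to (but
#' excluding) the root. A node directly under the root has no ancestors.
#' The root itself has no ancestor set by contract: ancestor overlap with
#' the root would be awarded to every prediction and is uninformative for
#' the hierarchical F1 score.
#'
#' @param tree A \code{ClassificationTree}.
#' @param name A non-root node name.
#' @return Character vector, immediate parent first.
#' @examples
#' ancestors(parseNewick("((A,B)1,2)root;"), "A")  # "1"
#' @export
ancestors <- function(tree, name) {
  .checkNode(tree, name)
  if (name == rootName(tree))
    stop("the root has no ancestor set")
  out <- character()
  p <- parentOf(tree, name)
  while (!is.na(p) && p != rootName(tree)) {
    out <- c(out, p)
    p <- parentOf(tree, p)
  }
  out
}

#' Labels of a node's subtree
#'
#' The node's own name plus all descendant names. Used to pool positive
#' training cells: cells from the node itself and all its child nodes count
#' as positives for the node's local classifier.
#'
#' @param tree A \code{ClassificationTree}.
#' @param name A node name.
#' @return Character vector of node names (the node first, then a
#'   breadth-first sweep of descendants).
#' @export
subtreeLabels <- function(tree, name) {
  .checkNode(tree, name)
  out <- name
  frontier <- name
  nd <- tree@nodes
  while (length(frontier)) {
    frontier <- nd$name[!is.na(nd$parent) & nd$parent %in% frontier]
    out <- c(out, frontier)
  }
  out
}

## ---- edits ---------------------------------------------------------------

#' Tree edit operations
#'
#' All edits return a new, validated tree; the unique-name and single-root
#' invariants are re-checked after every edit. \code{addChild} appends a new
#' leaf under \code{parent}. \code{insertParent} creates a new node under the
#' common parent of \code{children} and reparents them beneath it.
#' \code{removeNode} splices a non-root node out, reattaching its children to
#' its parent.
#'
#' @param tree A \code{ClassificationTree}.
#' @param parent,name,children Node names.
#' @return The edited \code{ClassificationTree}.
#' @name tree-edits
NULL

#' @rdname tree-edits
#' @export
addChild <- function(tree, parent, name) {
  .checkNode(tree, parent)
  if (name %in% tree@nodes$name)
    stop("node '", name, "' already exists")
  tree@nodes <- rbind(tree@nodes,
                      data.frame(name = name, parent = parent,
                                 stringsAsFactors = FALSE))
  validObject(tree)
  tree
}

#' @rdname tree-edits
#' @export
insertParent <- function(tree, children, name) {
  for (ch in children) .checkNode(tree, ch)
  if (name %in% tree@nodes$name)
    stop("node '", name, "' already exists")
  pars <- unique(vapply(children, function(ch) parentOf(tree, ch), character(1L)))
  if (length(pars) != 1L || is.na(pars))
    stop("children must be siblings (shared non-missing parent)")
  tree@nodes <- rbind(tree@nodes,
                      data.frame(name = name, parent = pars,
                                 stringsAsFactors = FALSE))
  tree@nodes$parent[tree@nodes$name %in% children] <- name
  validObject(tree)
  tree
}

#' @rdname tree-edits
#' @export
removeNode <- function(tree, name) {
  .checkNode(tree, name)
  if (name == rootName(tree)) stop("cannot remove the root")
  p <- parentOf(tree, name)
  tree@nodes$parent[!is.na(tree@nodes$parent) & tree@nodes$parent == name] <- p
  tree@nodes <- tree@nodes[tree@nodes$name != name, , drop = FALSE]
  rownames(tree@nodes) <- NULL
  validObject(tree)
  tree
}

#' Compare two trees by topology and node names
#'
#' Child order is ignored: each tree is serialized in a canonical form with
#' children sorted recursively, and the strings compared.
#'
#' @param tree1,tree2 \code{ClassificationTree} objects.
#' @return \code{TRUE} if the trees are isomorphic with matching names.
#' @export
sameTopology <- function(tree1, tree2) {
  canon <- function(tree, nm) {
    ch <- childrenOf(tree, nm)
    if (!length(ch)) return(nm)
    sub <- sort(vapply(ch, function(x) canon(tree, x), character(1L)))
    paste0("(", paste(sub, collapse = ","), ")", nm)
  }
  identical(canon(tree1, rootName(tree1)), canon(tree2, rootName(tree2)))
}

setMethod("show", "ClassificationTree", function(object) {
  cat("ClassificationTree with", nrow(object@nodes), "nodes (",
      length(treeLeaves(object)), "leaves )\n")
  cat(writeNewick(object), "\n")
})
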