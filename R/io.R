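#' Read an expression matrix (dense TSV/CSV or MatrixMarket triplet)
#'
#' Dense files must carry a header row of gene names and a first column of
#' cell ids. MatrixMarket (\code{.mtx}) files are read with
#' \code{Matrix::readMM} and need two sidecar files with one name per line:
#' \code{<prefix>_genes.tsv} and \code{<prefix>_cells.tsv} (overridable).
#' The returned orientation is always cells by genes; an MTX file stored
#' genes-by-cells is transposed automatically based on the sidecar lengths.
#'
#' @param path File path.
#' @param genesFile,cellsFile Sidecar paths for MTX input.
#' @return Numeric matrix, cells in rows, genes in columns, fully named.
#' @export
readExpression <- function(path,
                           genesFile = sub("\\.mtx$", "_genes.tsv", path),
                           cellsFile = sub("\\.mtx$", "_cells.tsv", path)) {
  if (grepl("\\.mtx$", path)) {
    m <- as.matrix(Matrix::readMM(path))
    genes <- readLines(genesFile)
    cells <- readLines(cellsFile)
    if (nrow(m) == length(cells) && ncol(m) == length(genes)) {
      ## cells x genes already
    } else if (nrow(m) == length(genes) && ncol(m) == length(cells)) {
      m <- t(m)
    } else {
      stop("sidecar mismatch: matrix is ", nrow(m), "x", ncol(m),
           " but sidecars have ", length(genes), " genes and ",
           length(cells), " cells")
    }
    dimnames(m) <- list(cells, genes)
  } else {
    sep <- if (grepl("\\.csv$", path)) "," else "\t"
    df <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1L,
                            check.names = FALSE)
    m <- as.matrix(df)
  }
  dup <- colnames(m)[duplicated(colnames(m))]
  if (length(dup))
    stop("duplicate gene name: '", dup[[1L]], "'")
  storage.mode(m) <- "double"
  m
}

#' Write an expression matrix as dense TSV
#'
#' @param x Cell-by-gene matrix with dimnames.
#' @param path Output path.
#' @export
writeExpression <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     col.names = NA)
  invisible(path)
}

#' Read per-cell labels and align them to a matrix's cells
#'
#' Two-column TSV (cell id, label); a header line is detected and skipped
#' when its first field matches none of \code{cellIds}. Rows are reordered
#' to match \code{cellIds}.
#'
#' @param path File path.
#' @param cellIds Cell ids of the expression matrix, in matrix order.
#' @return Character label vector aligned to \code{cellIds}.
#' @export
readLabels <- function(path, cellIds) {
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          colClasses = "character", quote = "")
  if (ncol(df) < 2L) stop("label file needs two columns (cell id, label)")
  headerish <- c("cell", "cell_id", "cellid", "id", "barcode", "cell.id")
  if (nrow(df) && !df[[1L]][[1L]] %in% cellIds &&
      tolower(df[[1L]][[1L]]) %in% headerish)
    df <- df[-1L, , drop = FALSE]
  ids <- df[[1L]]; lab <- df[[2L]]
  missing <- setdiff(cellIds, ids)
  if (length(missing))
    stop("cell id(s) missing from label file: ",
         paste(utils::head(missing, 10L), collapse = ", "))
  extra <- setdiff(ids, cellIds)
  if (length(extra))
    stop("label file has unknown cell id(s): ",
         paste(utils::head(extra, 10L), collapse = ", "))
  lab <- lab[match(cellIds, ids)]
  if (any(!nzchar(lab))) stop("empty label(s) in label file")
  lab
}

#' Read / write a classification tree as a Newick file
#'
#' @param path File path.
#' @param tree A \code{ClassificationTree}.
#' @return \code{readTree}: a \code{ClassificationTree}.
#' @export
readTree <- function(path) parseNewick(paste(readLines(path), collapse = ""))

#' @rdname readTree
#' @export
writeTree <- function(tree, path) {
  writeLines(writeNewick(tree), path)
  invisible(path)
}
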