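## internal helpers shared across modules

## Evaluate expr with a temporary RNG state so that fitting is deterministic
## regardless of the caller's seed, and the caller's RNG stream is untouched.
.withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

## Canonical internal orientation is cells-by-genes. Accepts a plain matrix
## (cells in rows), or a SummarizedExperiment/SingleCellExperiment with a
## "logcounts" (preferred) or first assay, genes in rows as usual.
.asCellMatrix <- function(x) {
  if (is(x, "SummarizedExperiment")) {
    nm <- SummarizedExperiment::assayNames(x)
    a <- if ("logcounts" %in% nm) {
      SummarizedExperiment::assay(x, "logcounts")
    } else {
      SummarizedExperiment::assay(x, 1L)
    }
    return(t(as.matrix(a)))
  }
  if (is(x, "Matrix")) return(as.matrix(x))
  if (!is.matrix(x)) stop("expected a matrix or SummarizedExperiment")
  x
}

## Pull per-cell labels: explicit vector wins, else colData(x)$label.
.getLabels <- function(x, labels) {
  if (!is.null(labels)) return(as.character(labels))
  if (is(x, "SummarizedExperiment")) {
    cd <- SummarizedExperiment::colData(x)
    if ("label" %in% colnames(cd)) return(as.character(cd$label))
  }
  stop("labels are required (pass 'labels' or provide colData(x)$label)")
}
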