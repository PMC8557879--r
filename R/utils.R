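## Internal helpers shared across the package.

## Accept either a SummarizedExperiment or a plain genes x samples matrix
## with dimnames; always hand back a numeric matrix.
.asExprs <- function(x) {
  if (methods::is(x, "SummarizedExperiment")) {
    m <- SummarizedExperiment::assay(x, 1L)
  } else if (is.matrix(x) && is.numeric(x)) {
    m <- x
  } else {
    stop("expected a SummarizedExperiment or a numeric genes x samples matrix")
  }
  if (is.null(rownames(m)) || is.null(colnames(m)))
    stop("expression matrix must carry gene ids (rownames) and sample ids (colnames)")
  if (anyDuplicated(rownames(m))) stop("duplicate gene ids in expression matrix")
  if (anyDuplicated(colnames(m))) stop("duplicate sample ids in expression matrix")
  if (any(!is.finite(m))) stop("expression matrix must not contain missing or non-finite values")
  m
}

## Wrap a matrix as the package's canonical expression container.
.asSE <- function(m) {
  SummarizedExperiment::SummarizedExperiment(assays = list(exprs = m))
}

## Run `expr` under a private RNG stream seeded with `seed`, restoring any
## pre-existing global RNG state afterwards.
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

## Jaccard index of two character sets.
.jaccard <- function(a, b) {
  u <- length(union(a, b))
  if (u == 0L) return(1)
  length(intersect(a, b)) / u
}

.fmtNum <- function(x) formatC(x, digits = 6, format = "f")
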