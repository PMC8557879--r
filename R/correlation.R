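#' Drop genes with zero expression variance
#'
#' Correlation is undefined for constant profiles; callers must remove them
#' before [correlateAllPairs()].  Dropped gene ids are reported in a warning.
#'
#' @param x a \code{SummarizedExperiment} or genes x samples matrix.
#' @return Object of the same kind without the zero-variance genes.
#' @export
dropZeroVarianceGenes <- function(x) {
  m <- .asExprs(x)
  v <- apply(m, 1L, stats::var)
  bad <- v < .Machine$double.eps
  if (any(bad)) {
    warning(sprintf("dropping %d zero-variance gene(s): %s", sum(bad),
                    paste(rownames(m)[bad], collapse = ", ")))
    if (methods::is(x, "SummarizedExperiment")) return(x[!bad, ])
    return(m[!bad, , drop = FALSE])
  }
  x
}

#' All-pairs gene-gene correlation
#'
#' @param x a \code{SummarizedExperiment} or genes x samples matrix with at
#'   least 3 samples and no zero-variance genes (see
#'   [dropZeroVarianceGenes()]).
#' @param method \code{"pearson"} or \code{"spearman"} (Spearman uses average
#'   ranks for ties).
#' @return A \linkS4class{CorrelationMatrix}.
#' @examples
#' m <- matrix(rnorm(40), 4, 10,
#'             dimnames = list(paste0("g", 1:4), paste0("s", 1:10)))
#' correlateAllPairs(m, "spearman")
#' @export
correlateAllPairs <- function(x, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  m <- .asExprs(x)
  if (ncol(m) < 3L) stop("correlation needs at least 3 samples")
  v <- apply(m, 1L, stats::var)
  if (any(v < .Machine$double.eps))
    stop(sprintf("zero-variance gene(s) present: %s (drop them with dropZeroVarianceGenes())",
                 paste(rownames(m)[v < .Machine$double.eps], collapse = ", ")))
  cc <- stats::cor(t(m), method = method)
  ## guard against tiny float asymmetries / |r| marginally above 1
  cc <- (cc + t(cc)) / 2
  cc[cc > 1] <- 1
  cc[cc < -1] <- -1
  diag(cc) <- 1
  methods::new("CorrelationMatrix", values = cc, method = method)
}

#' Per-gene correlation rank lists
#'
#' For every gene A, ranks every other gene B from most to least correlated
#' with A (rank 1 = best).  Self-correlations are excluded; ties are broken
#' by ascending gene id, so the table is deterministic.
#'
#' @param corr a \linkS4class{CorrelationMatrix}.
#' @return An integer matrix R with \code{R[A, B] = Rank_A(B)} and \code{NA}
#'   on the diagonal.
#' @export
rankLists <- function(corr) {
  stopifnot(methods::is(corr, "CorrelationMatrix"))
  v <- corValues(corr)
  n <- nrow(v)
  ids <- rownames(v)
  out <- matrix(NA_integer_, n, n, dimnames = dimnames(v))
  idOrder <- seq_len(n)  # column index order == ascending id after sort below
  for (a in seq_len(n)) {
    others <- setdiff(seq_len(n), a)
    ## order by descending correlation, ties by ascending gene id
    o <- others[order(-v[a, others], ids[others], method = "radix")]
    out[a, o] <- seq_along(o)
  }
  out
}

#' Mutual rank transform
#'
#' \eqn{MR(A,B) = \sqrt{Rank_A(B) \cdot Rank_B(A)}}: the geometric mean of
#' the two genes' reciprocal positions in each other's correlation-ordered
#' gene lists.  Mutual best partners attain the minimum MR of 1; small MR
#' means strong mutual coexpression and is robust for rarely expressed genes
#' whose raw correlations are inflated by shared sparsity.
#'
#' @param corr a \linkS4class{CorrelationMatrix} (typically Pearson).
#' @return A \linkS4class{MutualRankMatrix}.
#' @export
mutualRank <- function(corr) {
  r <- rankLists(corr)
  mr <- sqrt(r * t(r))
  diag(mr) <- NA_real_
  methods::new("MutualRankMatrix", values = mr)
}

#' Exponential decay edge weight
#'
#' Maps a mutual rank to an edge weight \eqn{w = e^{-(MR - 1)/x}} in (0, 1]:
#' mutual best partners (MR = 1) get weight 1 for every \code{x}, and the
#' weight decays with MR at a speed set by \code{x} (larger \code{x} =
#' slower decay = more permissive network).
#'
#' @param mr mutual rank value(s), all >= 1.
#' @param x positive decay parameter.
#' @return Weight(s) in (0, 1]; \code{NA} entries pass through.
#' @examples
#' decayWeight(1, 5)                      # 1
#' decayWeight(1 + 25 * log(10), 25)      # 0.1 crossing
#' @export
decayWeight <- function(mr, x) {
  if (!is.numeric(x) || length(x) != 1L || x <= 0)
    stop("decayWeight: x must be a positive number")
  if (any(mr < 1 - 1e-12, na.rm = TRUE))
    stop("decayWeight: mutual ranks must be >= 1")
  exp(-(mr - 1) / x)
}
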