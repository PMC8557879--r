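#' Trimmed mean
#'
#' Mean after removing \code{floor(trim * n)} largest and the same number of
#' smallest values (no interpolation), so results are bit-reproducible.
#'
#' @param values non-empty numeric vector of finite values.
#' @param trim per-tail trim fraction in [0, 0.5).
#' @return The trimmed mean (numeric scalar).
#' @examples
#' trimmedMean(1:20, 0.05)        # drops 1 and 20 -> 10.5
#' trimmedMean(c(1, 2, 3, 100), 0.05)  # floor(0.2) = 0, nothing trimmed
#' @export
trimmedMean <- function(values, trim = 0.05) {
  if (length(values) == 0L) stop("trimmedMean: empty input")
  if (!is.numeric(values) || any(!is.finite(values)))
    stop("trimmedMean: values must be finite numbers")
  if (!is.numeric(trim) || length(trim) != 1L || trim < 0 || trim >= 0.5)
    stop("trimmedMean: trim must satisfy 0 <= trim < 0.5")
  k <- floor(trim * length(values))
  if (k > 0L) {
    s <- sort(values)
    values <- s[(k + 1L):(length(s) - k)]
  }
  mean(values)
}

#' Scale a compendium to the cross-experiment trimmed mean
#'
#' Makes arrays (samples) comparable across experiments: each sample column
#' is multiplied by \code{T / t_j}, where \code{t_j} is that column's trimmed
#' mean and the cross-experiment target \code{T} is the mean of the
#' per-column trimmed means.  After scaling, every column's trimmed mean
#' equals \code{T}, and the operation is an exact fixed point (scaling a
#' scaled matrix changes nothing).
#'
#' @param x a \code{SummarizedExperiment} or genes x samples matrix.
#' @param trim per-tail trim fraction (default 0.05, i.e. the top and bottom
#'   5\% of each column's values are excluded).
#' @return An object of the same kind as \code{x} with scaled values.
#' @examples
#' m <- matrix(c(1, 2, 3, 4, 2, 4, 6, 8), ncol = 2,
#'             dimnames = list(paste0("g", 1:4), c("s1", "s2")))
#' scaleToTrimmedMean(m, trim = 0)
#' @export
scaleToTrimmedMean <- function(x, trim = 0.05) {
  m <- .asExprs(x)
  tj <- apply(m, 2L, trimmedMean, trim = trim)
  zero <- abs(tj) < .Machine$double.eps
  if (any(zero))
    stop(sprintf("sample(s) with zero trimmed mean: %s",
                 paste(colnames(m)[zero], collapse = ", ")))
  target <- mean(tj)
  scaled <- sweep(m, 2L, target / tj, `*`)
  if (methods::is(x, "SummarizedExperiment")) {
    SummarizedExperiment::assay(x, 1L) <- scaled
    x
  } else scaled
}
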