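## Assemble a CoexpressionNetwork from a logical keep-mask over gene pairs.
.edgesFromMask <- function(ids, keep, weight, extra = NULL) {
  ut <- upper.tri(keep)
  sel <- which(keep & ut, arr.ind = TRUE)
  e <- data.frame(from = ids[sel[, 1L]], to = ids[sel[, 2L]],
                  weight = weight[sel], stringsAsFactors = FALSE)
  if (!is.null(extra)) for (nm in names(extra)) e[[nm]] <- extra[[nm]][sel]
  swap <- e$from > e$to
  if (any(swap)) {
    tmp <- e$from[swap]; e$from[swap] <- e$to[swap]; e$to[swap] <- tmp
  }
  e <- e[order(e$from, e$to, method = "radix"), , drop = FALSE]
  rownames(e) <- NULL
  e
}

#' Build a mutual-rank Pearson (MR-PCC) coexpression network
#'
#' Pearson correlations are computed between every pair of genes, rank lists
#' and mutual ranks derived, and MR values mapped to edge weights with
#' [decayWeight()].  An edge (A, B) is kept iff the signed Pearson
#' correlation is at least \code{pccMin} \emph{and} the decay weight is at
#' least \code{weightMin}.  With the conventional decay parameters x = 5, 10
#' and 25 the resulting networks are named NET05, NET10 and NET25
#' (stringent to relaxed; edge sets are nested: NET05 within NET10 within
#' NET25).
#'
#' @param exprs a \code{SummarizedExperiment} or genes x samples matrix
#'   (zero-variance genes must be dropped beforehand).
#' @param x positive decay parameter.
#' @param pccMin minimum signed Pearson correlation (default 0.3).
#' @param weightMin minimum decay weight (default 0.1).
#' @return A \linkS4class{CoexpressionNetwork} whose edge weights are the
#'   decay-transformed mutual ranks.
#' @seealso [buildMRNetworks()] to build several networks from one MR
#'   computation, [buildSCCNetwork()].
#' @export
buildMRNetwork <- function(exprs, x = 10, pccMin = 0.3, weightMin = 0.1) {
  buildMRNetworks(exprs, xs = x, pccMin = pccMin,
                  weightMin = weightMin)[[1L]]
}

#' @rdname buildMRNetwork
#' @param xs numeric vector of decay parameters; the expensive correlation
#'   and mutual-rank computations are shared across all of them.
#' @return For \code{buildMRNetworks}: a named list of networks (names
#'   \code{NET05}-style).
#' @export
buildMRNetworks <- function(exprs, xs = c(5, 10, 25), pccMin = 0.3,
                            weightMin = 0.1) {
  m <- .asExprs(exprs)
  if (nrow(m) < 2L) stop("network construction needs at least 2 genes")
  pcc <- correlateAllPairs(m, "pearson")
  mr <- mutualRank(pcc)
  ids <- rownames(corValues(pcc))
  out <- lapply(xs, function(x) {
    w <- decayWeight(mrValues(mr), x)
    keep <- !is.na(w) & corValues(pcc) >= pccMin & w >= weightMin
    net <- methods::new("CoexpressionNetwork",
      nodes = ids,
      edges = .edgesFromMask(ids, keep, w),
      params = list(method = "mr-pcc", x = x, pccMin = pccMin,
                    weightMin = weightMin, name = sprintf("NET%02d", x)))
    methods::validObject(net)
    net
  })
  stats::setNames(out, vapply(out, function(n) n@params$name, character(1)))
}

#' Build a Spearman (SCC) coexpression network
#'
#' An edge is present iff the absolute Spearman rank correlation is at least
#' \code{rhoMin}; the edge records the signed coefficient in column
#' \code{rho} and carries \code{abs(rho)} as its weight.
#'
#' @inheritParams buildMRNetwork
#' @param rhoMin minimum absolute Spearman correlation (default 0.5).
#' @return A \linkS4class{CoexpressionNetwork}.
#' @export
buildSCCNetwork <- function(exprs, rhoMin = 0.5) {
  m <- .asExprs(exprs)
  if (nrow(m) < 2L) stop("network construction needs at least 2 genes")
  scc <- correlateAllPairs(m, "spearman")
  v <- corValues(scc)
  keep <- abs(v) >= rhoMin
  diag(keep) <- FALSE
  ids <- rownames(v)
  net <- methods::new("CoexpressionNetwork",
    nodes = ids,
    edges = .edgesFromMask(ids, keep, abs(v), extra = list(rho = v)),
    params = list(method = "scc", rhoMin = rhoMin, name = "SCC"))
  methods::validObject(net)
  net
}

## igraph view of a network (keeps isolated nodes).
.asIgraph <- function(net) {
  igraph::graph_from_data_frame(networkEdges(net), directed = FALSE,
                                vertices = data.frame(name = networkNodes(net)))
}

.subNetwork <- function(net, keepNodes) {
  keepNodes <- sort(keepNodes)
  e <- networkEdges(net)
  e <- e[e$from %in% keepNodes & e$to %in% keepNodes, , drop = FALSE]
  rownames(e) <- NULL
  methods::new("CoexpressionNetwork", nodes = keepNodes, edges = e,
               params = networkParams(net))
}

#' Extract the subnetwork of components containing query genes
#'
#' Returns the union of the connected components that contain at least one
#' query gene (query genes absent from the network are ignored; an isolated
#' query gene contributes a single-node component).
#'
#' @param net a \linkS4class{CoexpressionNetwork}.
#' @param genes character vector of query gene ids.
#' @return A \linkS4class{CoexpressionNetwork} restricted to the selected
#'   components.
#' @seealso [largestComponent()]
#' @export
subnetworkContaining <- function(net, genes) {
  g <- .asIgraph(net)
  comp <- igraph::components(g)
  hit <- genes[genes %in% networkNodes(net)]
  if (!length(hit)) return(.subNetwork(net, character()))
  keepComp <- unique(comp$membership[hit])
  keep <- names(comp$membership)[comp$membership %in% keepComp]
  .subNetwork(net, keep)
}

#' @rdname subnetworkContaining
#' @return For \code{largestComponent}: the component with the most nodes
#'   (ties broken by the lexicographically smallest member id).
#' @export
largestComponent <- function(net) {
  g <- .asIgraph(net)
  comp <- igraph::components(g)
  best <- which(comp$csize == max(comp$csize))
  if (length(best) > 1L) {
    firsts <- vapply(best, function(b)
      min(names(comp$membership)[comp$membership == b]), character(1))
    best <- best[order(firsts)][1L]
  }
  keep <- names(comp$membership)[comp$membership == best]
  .subNetwork(net, keep)
}
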