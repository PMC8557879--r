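## Independent brute-force oracles used to check the package's correlation,
## rank, mutual-rank and module-detection code.  These deliberately use
## explicit textbook formulas and exhaustive loops rather than anything from
## the package internals.

## Pearson correlation from explicit sums.
brutePearson <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  num <- n * sum(x * y) - sx * sy
  den <- sqrt(n * sum(x^2) - sx^2) * sqrt(n * sum(y^2) - sy^2)
  num / den
}

## Spearman = Pearson on average ranks.
bruteSpearman <- function(x, y) brutePearson(rank(x), rank(y))

bruteCorrelationMatrix <- function(m, method = "pearson") {
  n <- nrow(m)
  out <- matrix(1, n, n, dimnames = list(rownames(m), rownames(m)))
  f <- if (method == "pearson") brutePearson else bruteSpearman
  for (i in seq_len(n)) for (j in seq_len(n))
    if (i != j) out[i, j] <- f(m[i, ], m[j, ])
  out
}

## Rank of every gene B in gene A's descending-correlation list, ties broken
## by ascending gene id; computed by explicit sorting per row.
bruteRankTable <- function(cc) {
  n <- nrow(cc)
  ids <- rownames(cc)
  out <- matrix(NA_integer_, n, n, dimnames = dimnames(cc))
  for (a in seq_len(n)) {
    others <- setdiff(seq_len(n), a)
    ord <- others[order(-cc[a, others], ids[others])]
    for (r in seq_along(ord)) out[a, ord[r]] <- r
  }
  out
}

bruteMutualRank <- function(cc) {
  rk <- bruteRankTable(cc)
  n <- nrow(cc)
  out <- matrix(NA_real_, n, n, dimnames = dimnames(cc))
  for (a in seq_len(n)) for (b in seq_len(n))
    if (a != b) out[a, b] <- sqrt(rk[a, b] * rk[b, a])
  out
}

## ---- module-detection oracles ------------------------------------------

## Build a small unit-weight (or custom-weight) test network from an edge
## list given as a data.frame(from, to, weight).
toyNetwork <- function(edges, nodes = NULL, name = "toy") {
  if (is.null(nodes)) nodes <- sort(unique(c(edges$from, edges$to)))
  swap <- edges$from > edges$to
  tmp <- edges$from[swap]; edges$from[swap] <- edges$to[swap]
  edges$to[swap] <- tmp
  edges <- edges[order(edges$from, edges$to), , drop = FALSE]
  rownames(edges) <- NULL
  methods::new("CoexpressionNetwork", nodes = nodes, edges = edges,
               params = list(method = "toy", name = name))
}

cliqueEdges <- function(nodes, weight = 1) {
  p <- t(combn(nodes, 2))
  data.frame(from = p[, 1], to = p[, 2], weight = weight,
             stringsAsFactors = FALSE)
}

## Cohesiveness computed directly from the edge list (independent of the
## package's adjacency bookkeeping).
bruteCohesiveness <- function(net, genes, penalty = 2) {
  e <- networkEdges(net)
  inA <- e$from %in% genes
  inB <- e$to %in% genes
  wIn <- sum(e$weight[inA & inB])
  wBound <- sum(e$weight[xor(inA, inB)])
  den <- wIn + wBound + penalty * length(genes)
  if (den <= 0) 0 else wIn / den
}

bruteDensity <- function(net, genes) {
  e <- networkEdges(net)
  wIn <- sum(e$weight[e$from %in% genes & e$to %in% genes])
  k <- length(genes)
  if (k < 2) 0 else 2 * wIn / (k * (k - 1))
}

## Exhaustive single-move local-optimality check: no addition of an incident
## external node and no removal of an internal node strictly improves
## cohesiveness.
bruteLocallyOptimal <- function(net, genes, penalty = 2, eps = 1e-12) {
  nodes <- networkNodes(net)
  e <- networkEdges(net)
  f0 <- bruteCohesiveness(net, genes, penalty)
  incident <- unique(c(e$to[e$from %in% genes], e$from[e$to %in% genes]))
  for (v in setdiff(incident, genes))
    if (bruteCohesiveness(net, c(genes, v), penalty) > f0 + eps) return(FALSE)
  if (length(genes) > 1)
    for (u in genes)
      if (bruteCohesiveness(net, setdiff(genes, u), penalty) > f0 + eps)
        return(FALSE)
  TRUE
}

## Enumerate every connected, locally optimal, filter-passing gene set of a
## small (<= ~12 node) network by exhaustive subset search.
bruteEnumerateModules <- function(net, minSize = 3, minDensity = 0.3,
                                  penalty = 2) {
  nodes <- networkNodes(net)
  e <- networkEdges(net)
  stopifnot(length(nodes) <= 14)
  isConnected <- function(genes) {
    if (length(genes) == 1) return(TRUE)
    seen <- genes[1]
    repeat {
      nb <- unique(c(e$to[e$from %in% seen], e$from[e$to %in% seen]))
      grow <- intersect(nb, setdiff(genes, seen))
      if (!length(grow)) break
      seen <- c(seen, grow)
    }
    length(seen) == length(genes)
  }
  out <- list()
  for (k in seq_len(2^length(nodes) - 1)) {
    genes <- nodes[bitwAnd(k, 2^(seq_along(nodes) - 1)) > 0]
    if (length(genes) < minSize) next
    if (bruteDensity(net, genes) < minDensity) next
    if (!isConnected(genes)) next
    if (bruteLocallyOptimal(net, genes, penalty))
      out[[length(out) + 1]] <- sort(genes)
  }
  out
}

moduleKey <- function(genes) paste(sort(genes), collapse = "|")

## ---- shared heavy fixtures (computed once per test run) -----------------

.fixtures <- new.env(parent = emptyenv())

## Rare-cluster scenario at the reference seed, with derived networks.
scenarioFixture <- function() {
  if (is.null(.fixtures$scenario)) {
    sim <- rareClusterScenario(1)
    m <- SummarizedExperiment::assay(sim$exprs, 1L)
    pcc <- correlateAllPairs(m, "pearson")
    nets <- buildMRNetworks(m)
    .fixtures$scenario <- list(
      exprs = m, truth = sim$truth, pcc = pcc,
      mr = mutualRank(pcc), nets = nets,
      modules10 = detectModules(nets$NET10))
  }
  .fixtures$scenario
}

## Full planted compendium at the reference seed, with the whole pipeline's
## in-memory results.
compendiumFixture <- function() {
  if (is.null(.fixtures$compendium)) {
    pc <- plantedCompendium(42)
    scaled <- scaleToTrimmedMean(pc$exprs)
    m <- SummarizedExperiment::assay(scaled, 1L)
    nets <- buildMRNetworks(m)
    mods <- lapply(nets, detectModules)
    scc <- buildSCCNetwork(m)
    .fixtures$compendium <- list(
      pc = pc, exprs = m, truth = pc$truth, catalog = pc$catalog,
      nets = nets, modules = mods, scc = scc)
  }
  .fixtures$compendium
}

bestJaccard <- function(moduleSet, genes) {
  js <- vapply(moduleGenes(moduleSet), function(mm)
    length(intersect(mm, genes)) / length(union(mm, genes)), numeric(1))
  if (!length(js)) return(0)
  max(js)
}

## Small fixed 4-gene x 5-sample matrix for oracle-equivalence checks.
fixtureMatrix4 <- function() {
  matrix(c(1.0, 2.0, 3.0, 4.0, 5.0,
           2.1, 3.9, 6.2, 7.8, 10.1,
           9.0, 7.0, 5.2, 3.1, 1.0,
           4.0, 4.5, 4.2, 6.0, 5.1),
         nrow = 4, byrow = TRUE,
         dimnames = list(c("gA", "gB", "gC", "gD"),
                         paste0("s", 1:5)))
}
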