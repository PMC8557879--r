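## Internal adjacency representation: for node index i, adj[[i]] is an
## integer vector of neighbour indices and adjW[[i]] the matching weights.
.adjacency <- function(net) {
  nodes <- networkNodes(net)
  n <- length(nodes)
  idx <- stats::setNames(seq_len(n), nodes)
  e <- networkEdges(net)
  adj <- vector("list", n)
  adjW <- vector("list", n)
  for (i in seq_len(n)) {
    adj[[i]] <- integer()
    adjW[[i]] <- numeric()
  }
  if (nrow(e)) {
    f <- idx[e$from]; t <- idx[e$to]; w <- e$weight
    ends <- c(f, t); other <- c(t, f); ws <- c(w, w)
    o <- order(ends)
    ends <- ends[o]; other <- other[o]; ws <- ws[o]
    runs <- rle(ends)
    stops <- cumsum(runs$lengths)
    starts <- stops - runs$lengths + 1L
    for (k in seq_along(runs$values)) {
      i <- runs$values[k]
      adj[[i]] <- other[starts[k]:stops[k]]
      adjW[[i]] <- ws[starts[k]:stops[k]]
    }
  }
  list(nodes = nodes, idx = idx, adj = adj, adjW = adjW,
       degW = vapply(adjW, sum, numeric(1)))
}

.setStats <- function(g, inSet) {
  wIn <- 0; wBound <- 0
  for (i in which(inSet)) {
    wi <- sum(g$adjW[[i]][inSet[g$adj[[i]]]])
    wIn <- wIn + wi / 2
    wBound <- wBound + (g$degW[i] - wi)
  }
  list(wIn = wIn, wBound = wBound)
}

.cohScore <- function(wIn, wBound, penalty, size) {
  denom <- wIn + wBound + penalty * size
  if (denom <= 0) 0 else wIn / denom
}

#' Cohesiveness of a gene set on a weighted network
#'
#' \eqn{f(V) = w_{in} / (w_{in} + w_{bound} + p |V|)} where \eqn{w_{in}} is
#' the total weight of edges with both ends in \eqn{V}, \eqn{w_{bound}} the
#' total weight of edges with exactly one end in \eqn{V}, and \eqn{p} a
#' per-node penalty modelling unobserved connections.
#'
#' @param net a \linkS4class{CoexpressionNetwork}.
#' @param genes non-empty character vector of gene ids (must be nodes).
#' @param penalty per-node penalty, >= 0 (default 2).
#' @return Cohesiveness in [0, 1].
#' @export
cohesiveness <- function(net, genes, penalty = 2) {
  if (!length(genes)) stop("cohesiveness: empty gene set")
  if (penalty < 0) stop("cohesiveness: penalty must be >= 0")
  nodes <- networkNodes(net)
  if (!all(genes %in% nodes))
    stop(sprintf("cohesiveness: unknown gene(s): %s",
                 paste(setdiff(genes, nodes), collapse = ", ")))
  g <- .adjacency(net)
  inSet <- rep(FALSE, length(nodes))
  inSet[g$idx[unique(genes)]] <- TRUE
  st <- .setStats(g, inSet)
  .cohScore(st$wIn, st$wBound, penalty, sum(inSet))
}

## Weighted edge density of a set: 2 * wIn / (|V| (|V| - 1)).
.densityScore <- function(wIn, size) {
  if (size < 2L) return(0)
  2 * wIn / (size * (size - 1))
}

## Greedy growth from a seed set of node indices.  Returns indices, wIn,
## wBound.  At each step the single best strictly-improving move is applied:
## add an external node incident to the set, or remove an internal node.
## Ties in the new score are broken by ascending gene id.
.growFrom <- function(g, seedIdx, penalty) {
  n <- length(g$nodes)
  inSet <- rep(FALSE, n)
  inSet[seedIdx] <- TRUE
  size <- length(seedIdx)
  st <- .setStats(g, inSet)
  wIn <- st$wIn; wBound <- st$wBound
  f <- .cohScore(wIn, wBound, penalty, size)
  eps <- 1e-12
  repeat {
    members <- which(inSet)
    ## candidate additions: external nodes incident to the set
    cand <- unique(unlist(g$adj[members], use.names = FALSE))
    cand <- cand[!inSet[cand]]
    mvNode <- integer()
    mvType <- character()
    mvF <- numeric()
    mvWIn <- numeric()
    mvWB <- numeric()
    for (v in cand) {
      wTo <- sum(g$adjW[[v]][inSet[g$adj[[v]]]])
      nwIn <- wIn + wTo
      nwB <- wBound - wTo + (g$degW[v] - wTo)
      mvNode <- c(mvNode, v); mvType <- c(mvType, "add")
      mvF <- c(mvF, .cohScore(nwIn, nwB, penalty, size + 1L))
      mvWIn <- c(mvWIn, nwIn); mvWB <- c(mvWB, nwB)
    }
    if (size > 1L) {
      for (u in members) {
        wToSet <- sum(g$adjW[[u]][inSet[g$adj[[u]]]])
        nwIn <- wIn - wToSet
        nwB <- wBound - (g$degW[u] - wToSet) + wToSet
        mvNode <- c(mvNode, u); mvType <- c(mvType, "remove")
        mvF <- c(mvF, .cohScore(nwIn, nwB, penalty, size - 1L))
        mvWIn <- c(mvWIn, nwIn); mvWB <- c(mvWB, nwB)
      }
    }
    improving <- which(mvF > f + eps)
    if (!length(improving)) break
    top <- improving[mvF[improving] >= max(mvF[improving]) - eps]
    pick <- top[order(g$nodes[mvNode[top]], method = "radix")][1L]
    if (mvType[pick] == "add") {
      inSet[mvNode[pick]] <- TRUE
      size <- size + 1L
    } else {
      inSet[mvNode[pick]] <- FALSE
      size <- size - 1L
    }
    wIn <- mvWIn[pick]
    wBound <- mvWB[pick]
    f <- .cohScore(wIn, wBound, penalty, size)
  }
  list(members = which(inSet), wIn = wIn, wBound = wBound, f = f)
}

#' Grow a single cohesive module from a seed gene
#'
#' Starting from the singleton seed set, repeatedly applies the single best
#' cohesiveness-improving move - adding an external node incident to the set
#' or removing an internal node - until no move strictly improves the score.
#' The result is locally optimal under single add/remove moves; ties between
#' candidate moves are broken by ascending gene id, so growth is
#' deterministic.
#'
#' @param net a \linkS4class{CoexpressionNetwork}.
#' @param seedGene gene id to grow from (must be a node).
#' @param penalty per-node cohesiveness penalty (default 2).
#' @return A single-module \linkS4class{ModuleSet}.
#' @export
growModule <- function(net, seedGene, penalty = 2) {
  g <- .adjacency(net)
  if (!seedGene %in% g$nodes)
    stop(sprintf("growModule: unknown seed gene '%s'", seedGene))
  res <- .growFrom(g, g$idx[[seedGene]], penalty)
  methods::new("ModuleSet",
    genes = list(sort(g$nodes[res$members])),
    cohesiveness = res$f,
    density = .densityScore(res$wIn, length(res$members)),
    sourceNetwork = networkParams(net)$name %||% "network",
    params = list(penalty = penalty))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Detect overlapping coexpression modules
#'
#' Greedy cohesiveness clustering over the whole network: seeds are taken in
#' decreasing weighted-degree order (ties by ascending gene id), skipping
#' nodes already covered by a previously grown module; each seed is expanded
#' with [growModule()]'s greedy procedure.  Grown modules smaller than
#' \code{minSize} or with weighted density below \code{minDensity} are
#' discarded; remaining modules whose overlap score
#' \eqn{\omega(A,B) = |A \cap B|^2 / (|A| |B|)} reaches \code{mergeOverlap}
#' are merged transitively into their union.  Modules may overlap - a gene
#' can belong to several modules.
#'
#' @param net a \linkS4class{CoexpressionNetwork}.
#' @param minSize minimum module size (default 3).
#' @param minDensity minimum weighted density (default 0.3).
#' @param penalty per-node cohesiveness penalty (default 2).
#' @param mergeOverlap overlap score at or above which modules are merged
#'   (default 0.8).
#' @param seedMode \code{"unused"} (default) seeds only nodes not yet covered
#'   by a grown module; \code{"all"} seeds every node.
#' @return A \linkS4class{ModuleSet}, sorted by descending cohesiveness
#'   (ties by first gene id).
#' @export
detectModules <- function(net, minSize = 3L, minDensity = 0.3, penalty = 2,
                          mergeOverlap = 0.8,
                          seedMode = c("unused", "all")) {
  seedMode <- match.arg(seedMode)
  g <- .adjacency(net)
  n <- length(g$nodes)
  if (n == 0L) stop("detectModules: empty network")
  seedOrder <- order(-g$degW, g$nodes, method = "radix")
  covered <- rep(FALSE, n)
  grown <- list()
  for (s in seedOrder) {
    if (seedMode == "unused" && covered[s]) next
    res <- .growFrom(g, s, penalty)
    covered[res$members] <- TRUE
    if (length(res$members) >= minSize &&
        .densityScore(res$wIn, length(res$members)) >= minDensity)
      grown[[length(grown) + 1L]] <- res$members
  }
  ## drop exact duplicates (possible under seedMode = "all")
  if (length(grown)) {
    keys <- vapply(grown, function(m) paste(m, collapse = ","), character(1))
    grown <- grown[!duplicated(keys)]
  }
  ## transitive merge of highly overlapping modules
  if (length(grown) > 1L) {
    k <- length(grown)
    parent <- seq_len(k)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    sizes <- vapply(grown, length, integer(1))
    for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
      ov <- length(intersect(grown[[i]], grown[[j]]))
      if (ov^2 / (sizes[i] * sizes[j]) >= mergeOverlap) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
      }
    }
    roots <- vapply(seq_len(k), find, integer(1))
    grown <- lapply(split(seq_len(k), roots), function(ix)
      sort(unique(unlist(grown[ix], use.names = FALSE))))
    names(grown) <- NULL
  }
  ## score final modules
  coh <- numeric(length(grown))
  dens <- numeric(length(grown))
  for (i in seq_along(grown)) {
    inSet <- rep(FALSE, n)
    inSet[grown[[i]]] <- TRUE
    st <- .setStats(g, inSet)
    coh[i] <- .cohScore(st$wIn, st$wBound, penalty, length(grown[[i]]))
    dens[i] <- .densityScore(st$wIn, length(grown[[i]]))
  }
  geneSets <- lapply(grown, function(m) sort(g$nodes[m]))
  firstGene <- vapply(geneSets, function(gs)
    if (length(gs)) gs[1L] else "", character(1))
  o <- order(-coh, firstGene, method = "radix")
  methods::new("ModuleSet",
    genes = geneSets[o], cohesiveness = coh[o], density = dens[o],
    sourceNetwork = networkParams(net)$name %||% "network",
    params = list(minSize = as.integer(minSize), minDensity = minDensity,
                  penalty = penalty, mergeOverlap = mergeOverlap,
                  seedMode = seedMode))
}

#' Collapse modules around anchor genes into a metamodule
#'
#' Pools modules from any number of module sets (typically one per network),
#' keeps every module containing at least one anchor gene, and returns the
#' non-overlapping union of their genes.  If no module contains an anchor,
#' an empty metamodule is returned with a warning.
#'
#' @param modules a \linkS4class{ModuleSet} or a list of them.
#' @param anchors non-empty character vector of anchor gene ids (the genes of
#'   interest, e.g. a TF pair).
#' @return A \linkS4class{Metamodule}.
#' @export
collapseMetamodule <- function(modules, anchors) {
  if (!length(anchors)) stop("collapseMetamodule: anchors must be non-empty")
  if (methods::is(modules, "ModuleSet")) modules <- list(modules)
  stopifnot(all(vapply(modules, methods::is, logical(1), "ModuleSet")))
  contrib <- list()
  genes <- character()
  for (ms in modules) {
    src <- sourceNetwork(ms)
    for (i in seq_len(moduleCount(ms))) {
      gs <- moduleGenes(ms, i)
      if (any(anchors %in% gs)) {
        genes <- union(genes, gs)
        contrib[[length(contrib) + 1L]] <- data.frame(
          source_network = src, module_index = i, size = length(gs),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(contrib)) {
    warning("no module contains any anchor gene; metamodule is empty")
    contrib <- data.frame(source_network = character(),
                          module_index = integer(), size = integer(),
                          stringsAsFactors = FALSE)
  } else {
    contrib <- do.call(rbind, contrib)
  }
  methods::new("Metamodule", genes = sort(genes),
               anchorGenes = sort(unique(anchors)), contributing = contrib)
}
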