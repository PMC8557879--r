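## Provenance header written at the top of TSV artifacts: '# key: value'
## comment lines (no timestamps, so reruns are byte-identical).
.provenanceLines <- function(params) {
  if (!length(params)) return(character())
  vals <- vapply(params, function(p) paste(format(p), collapse = ","),
                 character(1))
  sprintf("# %s: %s", names(params), vals)
}

#' Read and write expression matrices as TSV
#'
#' Dialect: tab-separated; a header row of sample ids; first column holds
#' gene ids (header cell \code{gene_id}); every other cell is a finite
#' number.  Lines starting with \code{#} are comments (used for provenance
#' headers); Windows line endings are tolerated.  Values are written with 6
#' decimals, so \code{read(write(M))} equals \code{M} up to that formatting.
#'
#' @param path file path.
#' @return \code{readExpressionTSV}: a \code{SummarizedExperiment} with
#'   assay \code{"exprs"}.
#' @export
readExpressionTSV <- function(path) {
  if (!file.exists(path)) stop(sprintf("expression file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  keep <- !startsWith(lines, "#") & nzchar(lines)
  lineNo <- which(keep)
  lines <- lines[keep]
  if (length(lines) < 2L) stop("expression TSV needs a header and data rows")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1L]]
  sampleIds <- header[-1L]
  if (anyDuplicated(sampleIds))
    stop("duplicate sample ids in expression TSV header")
  ncolExp <- length(header)
  nf <- lengths(fields)
  bad <- which(nf[-1L] != ncolExp)
  if (length(bad))
    stop(sprintf("ragged row(s) at line(s): %s",
                 paste(lineNo[bad + 1L], collapse = ", ")))
  body <- fields[-1L]
  geneIds <- vapply(body, `[[`, character(1), 1L)
  if (anyDuplicated(geneIds))
    stop(sprintf("duplicate gene id(s): %s",
                 paste(unique(geneIds[duplicated(geneIds)]), collapse = ", ")))
  cells <- vapply(body, function(r) r[-1L], character(ncolExp - 1L))
  vals <- suppressWarnings(as.numeric(cells))
  if (any(is.na(vals))) {
    badRow <- unique(ceiling(which(is.na(vals)) / (ncolExp - 1L)))
    stop(sprintf("non-numeric cell(s) at line(s): %s",
                 paste(lineNo[badRow + 1L], collapse = ", ")))
  }
  m <- matrix(vals, nrow = length(geneIds), byrow = TRUE,
              dimnames = list(geneIds, sampleIds))
  .asSE(m)
}

#' @rdname readExpressionTSV
#' @param x a \code{SummarizedExperiment} or genes x samples matrix.
#' @param provenance named list echoed into \code{#} comment lines.
#' @export
writeExpressionTSV <- function(x, path, provenance = list()) {
  m <- .asExprs(x)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.provenanceLines(provenance), con)
  writeLines(paste(c("gene_id", colnames(m)), collapse = "\t"), con)
  body <- apply(m, 1L, function(r) paste(.fmtNum(r), collapse = "\t"))
  writeLines(paste(rownames(m), body, sep = "\t"), con)
  invisible(path)
}

#' Read and write networks as edge TSV and GraphML
#'
#' The edge TSV has columns \code{from}, \code{to}, \code{weight} (and
#' \code{rho} for SCC networks), weights rounded to 6 decimals; construction
#' parameters and the node list (including isolated nodes) are carried in
#' \code{#} provenance comments, so the file round-trips to an identical
#' network.  GraphML export goes through \pkg{igraph}, the lingua franca for
#' Cytoscape-style visualization.
#'
#' @param net a \linkS4class{CoexpressionNetwork}.
#' @param path file path.
#' @export
writeNetworkTSV <- function(net, path) {
  e <- networkEdges(net)
  p <- networkParams(net)
  p$nodes <- paste(networkNodes(net), collapse = ",")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.provenanceLines(p), con)
  numCols <- vapply(e, is.numeric, logical(1))
  e[numCols] <- lapply(e[numCols], .fmtNum)
  writeLines(paste(colnames(e), collapse = "\t"), con)
  if (nrow(e))
    writeLines(do.call(paste, c(unname(as.list(e)), sep = "\t")), con)
  invisible(path)
}

#' @rdname writeNetworkTSV
#' @export
readNetworkTSV <- function(path) {
  if (!file.exists(path)) stop(sprintf("network file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  prov <- lines[startsWith(lines, "#")]
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  params <- list()
  for (pl in prov) {
    kv <- sub("^# ", "", pl)
    key <- sub(":.*$", "", kv)
    val <- sub("^[^:]*: ?", "", kv)
    params[[key]] <- val
  }
  nodes <- if (!is.null(params$nodes))
    strsplit(params$nodes, ",", fixed = TRUE)[[1L]] else NULL
  for (k in c("x", "pccMin", "weightMin", "rhoMin"))
    if (!is.null(params[[k]])) params[[k]] <- as.numeric(params[[k]])
  params$nodes <- NULL
  header <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]]
  if (length(lines) > 1L) {
    body <- strsplit(lines[-1L], "\t", fixed = TRUE)
    e <- as.data.frame(do.call(rbind, body), stringsAsFactors = FALSE)
    colnames(e) <- header
    for (col in setdiff(header, c("from", "to")))
      e[[col]] <- as.numeric(e[[col]])
  } else {
    e <- data.frame(from = character(), to = character(),
                    weight = numeric(), stringsAsFactors = FALSE)
  }
  if (is.null(nodes)) nodes <- sort(unique(c(e$from, e$to)))
  net <- methods::new("CoexpressionNetwork", nodes = nodes, edges = e,
                      params = params)
  methods::validObject(net)
  net
}

#' @rdname writeNetworkTSV
#' @param catalog optional \linkS4class{BGCCatalog}; when supplied, BGC and
#'   role annotations are attached as node attributes.
#' @export
writeGraphML <- function(net, path, catalog = NULL) {
  g <- .asIgraph(net)
  p <- networkParams(net)
  for (k in names(p)) g <- igraph::set_graph_attr(g, k, as.character(p[[k]]))
  if (!is.null(catalog)) {
    tab <- catalogTable(catalog)
    ix <- match(igraph::V(g)$name, tab$gene_id)
    g <- igraph::set_vertex_attr(g, "bgc_id",
      value = ifelse(is.na(ix), "", ifelse(is.na(tab$bgc_id[ix]), "",
                                           tab$bgc_id[ix])))
    g <- igraph::set_vertex_attr(g, "role",
      value = ifelse(is.na(ix), "", tab$role[ix]))
  }
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' @rdname writeNetworkTSV
#' @export
readGraphML <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  e <- igraph::as_data_frame(g, what = "edges")
  params <- igraph::graph_attr(g)
  for (k in c("x", "pccMin", "weightMin", "rhoMin"))
    if (!is.null(params[[k]])) params[[k]] <- as.numeric(params[[k]])
  keepCols <- intersect(c("from", "to", "weight", "rho"), colnames(e))
  e <- e[keepCols]
  swap <- e$from > e$to
  if (any(swap)) {
    tmp <- e$from[swap]; e$from[swap] <- e$to[swap]; e$to[swap] <- tmp
  }
  e <- e[order(e$from, e$to, method = "radix"), , drop = FALSE]
  rownames(e) <- NULL
  net <- methods::new("CoexpressionNetwork",
                      nodes = sort(igraph::V(g)$name), edges = e,
                      params = params)
  methods::validObject(net)
  net
}

#' Read and write module sets as JSON and flat TSV
#'
#' JSON layout: an object with \code{source_network}, \code{params} and a
#' \code{modules} array (id, genes, cohesiveness, density).  The flat TSV
#' has one row per gene-module membership (overlapping genes repeat).
#'
#' @param modules a \linkS4class{ModuleSet}.
#' @param path file path.
#' @export
writeModulesJSON <- function(modules, path) {
  stopifnot(methods::is(modules, "ModuleSet"))
  obj <- list(
    source_network = sourceNetwork(modules),
    params = modules@params,
    modules = lapply(seq_len(moduleCount(modules)), function(i) list(
      id = sprintf("%s_%03d", sourceNetwork(modules), i),
      genes = moduleGenes(modules, i),
      cohesiveness = cohesivenessScores(modules)[i],
      density = densityScores(modules)[i])))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname writeModulesJSON
#' @export
readModulesJSON <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  mods <- obj$modules
  methods::new("ModuleSet",
    genes = lapply(mods, function(m) unlist(m$genes)),
    cohesiveness = vapply(mods, function(m) m$cohesiveness, numeric(1)),
    density = vapply(mods, function(m) m$density, numeric(1)),
    sourceNetwork = obj$source_network,
    params = lapply(obj$params, function(p) p))
}

#' @rdname writeModulesJSON
#' @export
writeModulesTSV <- function(modules, path) {
  stopifnot(methods::is(modules, "ModuleSet"))
  rows <- lapply(seq_len(moduleCount(modules)), function(i)
    data.frame(gene_id = moduleGenes(modules, i),
               module_id = sprintf("%s_%03d", sourceNetwork(modules), i),
               stringsAsFactors = FALSE))
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene_id = character(), module_id = character())
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a metamodule or coexpression report as JSON
#'
#' @param x a \linkS4class{Metamodule} or \linkS4class{CoexpressionReport}.
#' @param path file path.
#' @export
writeMetamoduleJSON <- function(x, path) {
  stopifnot(methods::is(x, "Metamodule"))
  obj <- list(genes = metamoduleGenes(x), anchor_genes = anchorGenes(x),
              contributing_modules = contributingModules(x))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname writeMetamoduleJSON
#' @export
writeReportJSON <- function(x, path) {
  stopifnot(methods::is(x, "CoexpressionReport"))
  obj <- list(bgc = bgcTable(x), tf = tfTable(x), details = reportDetails(x),
              params = x@params)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Write planted-truth ground truth as JSON
#'
#' @param truth a \linkS4class{PlantedTruth}.
#' @param path file path.
#' @export
writeTruthJSON <- function(truth, path) {
  stopifnot(methods::is(truth, "PlantedTruth"))
  obj <- list(group_members = groupMembers(truth),
              group_active_samples = groupActiveSamples(truth),
              regulator_targets = regulatorTargets(truth),
              confounders = confounderIds(truth))
  jsonlite::write_json(obj, path, auto_unbox = FALSE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname writeTruthJSON
#' @export
readTruthJSON <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  methods::new("PlantedTruth",
    groupMembers = lapply(obj$group_members, as.character),
    groupActiveSamples = lapply(obj$group_active_samples, as.character),
    regulatorTargets = lapply(obj$regulator_targets, as.character),
    confounders = as.character(obj$confounders))
}

#' Write a node attribute table for network visualization
#'
#' One row per network node with its BGC membership and role from the
#' catalog (empty for genes outside the catalog) - the companion file to an
#' edge TSV for Cytoscape-style tools.
#'
#' @param net a \linkS4class{CoexpressionNetwork}.
#' @param catalog a \linkS4class{BGCCatalog}.
#' @param path file path.
#' @export
writeNodeAttributesTSV <- function(net, catalog, path) {
  tab <- catalogTable(catalog)
  ix <- match(networkNodes(net), tab$gene_id)
  out <- data.frame(
    gene_id = networkNodes(net),
    bgc_id = ifelse(is.na(ix) | is.na(tab$bgc_id[ix]), "", tab$bgc_id[ix]),
    role = ifelse(is.na(ix), "", tab$role[ix]),
    core_type = ifelse(is.na(ix), "", tab$core_type[ix]),
    stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
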