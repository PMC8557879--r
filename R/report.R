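#' Construct or load a BGC catalog
#'
#' The catalog TSV has columns \code{gene_id}, \code{bgc_id}, \code{role},
#' \code{core_type}, \code{chromosome}, \code{start}, \code{end}; the last
#' three are optional (absent coordinates are stored as \code{NA}).
#' Coordinates are 1-based inclusive.  Unclustered genes (e.g. global
#' regulators) carry an empty \code{bgc_id}.
#'
#' @param table data.frame in catalog shape (missing optional columns are
#'   added as \code{NA}).
#' @return A validated \linkS4class{BGCCatalog}.
#' @export
bgcCatalog <- function(table) {
  for (col in c("chromosome"))
    if (!col %in% colnames(table)) table[[col]] <- NA_character_
  for (col in c("start", "end"))
    if (!col %in% colnames(table)) table[[col]] <- NA_integer_
  if (!"core_type" %in% colnames(table)) table$core_type <- "none"
  table$bgc_id[!is.na(table$bgc_id) & table$bgc_id == ""] <- NA_character_
  rownames(table) <- NULL
  obj <- methods::new("BGCCatalog", table = table)
  methods::validObject(obj)
  obj
}

#' @rdname bgcCatalog
#' @param path path to a catalog TSV (lines starting with \code{#} are
#'   treated as comments).
#' @export
loadCatalog <- function(path) {
  if (!file.exists(path)) stop(sprintf("catalog file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  keep <- !startsWith(lines, "#") & nzchar(lines)
  lineNo <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) stop("catalog file is empty")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1L]]
  need <- c("gene_id", "bgc_id", "role", "core_type")
  if (!all(need %in% header))
    stop(sprintf("catalog header must contain columns: %s",
                 paste(need, collapse = ", ")))
  nf <- lengths(fields)
  bad <- which(nf[-1L] != length(header)) + 1L
  if (length(bad))
    stop(sprintf("malformed catalog row(s) at line(s): %s",
                 paste(lineNo[bad], collapse = ", ")))
  body <- fields[-1L]
  tab <- as.data.frame(do.call(rbind, body), stringsAsFactors = FALSE)
  colnames(tab) <- header
  for (col in c("start", "end")) if (col %in% colnames(tab)) {
    v <- suppressWarnings(as.integer(tab[[col]]))
    v[tab[[col]] == ""] <- NA_integer_
    bad <- which(is.na(v) & tab[[col]] != "")
    if (length(bad))
      stop(sprintf("non-numeric %s at line(s): %s", col,
                   paste(lineNo[bad + 1L], collapse = ", ")))
    tab[[col]] <- v
  }
  bgcCatalog(tab)
}

#' @rdname bgcCatalog
#' @param catalog a \linkS4class{BGCCatalog} to write.
#' @export
writeCatalog <- function(catalog, path) {
  stopifnot(methods::is(catalog, "BGCCatalog"))
  tab <- catalogTable(catalog)
  tab$bgc_id[is.na(tab$bgc_id)] <- ""
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "")
  invisible(path)
}

.catalogBGCGenes <- function(catalog) {
  tab <- catalogTable(catalog)
  split(tab$gene_id, tab$bgc_id)
}

.emptyBgcTable <- function() {
  data.frame(bgc_id = character(), n_genes = integer(),
             n_recovered = integer(), coexpressed = logical(),
             stringsAsFactors = FALSE)
}

.emptyTfTable <- function() {
  data.frame(tf_id = character(), scc_count = integer(),
             mr_count = integer(), clustered = logical(),
             bgc_id = character(), stringsAsFactors = FALSE)
}

.poolModules <- function(modules) {
  if (methods::is(modules, "ModuleSet")) modules <- list(modules)
  stopifnot(all(vapply(modules, methods::is, logical(1), "ModuleSet")))
  out <- list()
  for (ms in modules) {
    src <- sourceNetwork(ms)
    for (i in seq_len(moduleCount(ms)))
      out[[sprintf("%s_%03d", src, i)]] <- moduleGenes(ms, i)
  }
  out
}

#' Per-BGC module recovery and coexpression accounting
#'
#' For every BGC in the catalog, counts how many member genes appear in any
#' module, and flags the BGC as coexpressed iff at least two member genes
#' share at least one module.  Both quantities are reported, together with
#' the ids of the modules involved, so either the gene-recovery or the
#' shared-module reading can be recovered from the report.
#'
#' @param modules a \linkS4class{ModuleSet} or list of them (e.g. one per
#'   network).
#' @param catalog a \linkS4class{BGCCatalog}.
#' @return A \linkS4class{CoexpressionReport} with the BGC part filled.
#' @export
bgcModuleOverlap <- function(modules, catalog) {
  stopifnot(methods::is(catalog, "BGCCatalog"))
  pool <- .poolModules(modules)
  byBGC <- .catalogBGCGenes(catalog)
  rows <- list()
  moduleIds <- list()
  for (bgc in names(byBGC)) {
    gs <- byBGC[[bgc]]
    inAny <- vapply(gs, function(gene)
      any(vapply(pool, function(m) gene %in% m, logical(1))), logical(1))
    shared <- names(pool)[vapply(pool, function(m)
      sum(gs %in% m) >= 2L, logical(1))]
    rows[[bgc]] <- data.frame(
      bgc_id = bgc, n_genes = length(gs), n_recovered = sum(inAny),
      coexpressed = length(shared) > 0L, stringsAsFactors = FALSE)
    moduleIds[[bgc]] <- shared
  }
  tab <- if (length(rows)) do.call(rbind, rows) else .emptyBgcTable()
  rownames(tab) <- NULL
  methods::new("CoexpressionReport",
    bgcTable = tab, tfTable = .emptyTfTable(),
    details = list(bgcModuleIds = moduleIds),
    params = list(moduleSources = names(pool)))
}

#' Per-TF counts of coexpressed BGC core genes
#'
#' Two complementary operational readings of "coexpressed with a core gene"
#' are computed for every query TF: the SCC rule counts catalog core genes
#' directly connected to the TF by an edge of the Spearman network (1-hop
#' neighbourhood; component membership would not discriminate at these
#' thresholds), and the MR rule counts core genes sharing at least one
#' MR-PCC module with the TF.
#'
#' @param sccNet the SCC \linkS4class{CoexpressionNetwork}.
#' @param modules a \linkS4class{ModuleSet} or list of them (MR-PCC
#'   networks).
#' @param catalog a \linkS4class{BGCCatalog}.
#' @param tfIds character vector of TF gene ids (must be in the catalog).
#' @return A \linkS4class{CoexpressionReport} with the TF part filled; the
#'   per-TF core gene id sets live in \code{reportDetails()}.
#' @export
tfCoreCoexpressionCounts <- function(sccNet, modules, catalog, tfIds) {
  stopifnot(methods::is(sccNet, "CoexpressionNetwork"),
            methods::is(catalog, "BGCCatalog"))
  tab <- catalogTable(catalog)
  unknown <- setdiff(tfIds, tab$gene_id)
  if (length(unknown))
    stop(sprintf("unknown TF id(s): %s", paste(unknown, collapse = ", ")))
  coreIds <- tab$gene_id[tab$role == "core"]
  pool <- .poolModules(modules)
  e <- networkEdges(sccNet)
  rows <- list()
  sccCores <- list()
  mrCores <- list()
  for (tf in tfIds) {
    nbrs <- c(e$to[e$from == tf], e$from[e$to == tf])
    scc <- sort(intersect(nbrs, coreIds))
    withTf <- pool[vapply(pool, function(m) tf %in% m, logical(1))]
    mr <- sort(intersect(unique(unlist(withTf, use.names = FALSE)), coreIds))
    mr <- setdiff(mr, tf)
    bgc <- tab$bgc_id[tab$gene_id == tf]
    rows[[tf]] <- data.frame(
      tf_id = tf, scc_count = length(scc), mr_count = length(mr),
      clustered = !is.na(bgc),
      bgc_id = ifelse(is.na(bgc), NA_character_, bgc),
      stringsAsFactors = FALSE)
    sccCores[[tf]] <- scc
    mrCores[[tf]] <- mr
  }
  tfTab <- if (length(rows)) do.call(rbind, rows) else .emptyTfTable()
  rownames(tfTab) <- NULL
  methods::new("CoexpressionReport",
    bgcTable = .emptyBgcTable(), tfTable = tfTab,
    details = list(tfSccCores = sccCores, tfMrCores = mrCores),
    params = list(sccNetwork = networkParams(sccNet)$name,
                  moduleSources = names(pool)))
}

#' Shortlist candidate secondary-metabolism regulators
#'
#' Applies the two selection rules to a TF report: a TF qualifies as a
#' putative \emph{global} regulator when its SCC count (core genes directly
#' coexpressed in the Spearman network) reaches \code{minCore}; it qualifies
#' as a putative \emph{pathway-specific} regulator when, under the MR rule,
#' it shares a module with core genes from at least two distinct BGCs (the
#' cross-cluster signature).  Each shortlisted TF is labelled with its
#' category and whether it resides in a cataloged BGC.
#'
#' @param report a \linkS4class{CoexpressionReport} from
#'   [tfCoreCoexpressionCounts()].
#' @param catalog the \linkS4class{BGCCatalog} (maps core genes to BGCs).
#' @param minCore minimum SCC core-gene count for the global rule
#'   (default 10).
#' @return data.frame with columns \code{tf_id}, \code{category},
#'   \code{clustered}, \code{bgc_id}, \code{scc_count}, \code{mr_count},
#'   \code{mr_bgcs}; zero rows if nothing qualifies.
#' @export
shortlistTFs <- function(report, catalog, minCore = 10L) {
  stopifnot(methods::is(report, "CoexpressionReport"),
            methods::is(catalog, "BGCCatalog"))
  tfTab <- tfTable(report)
  det <- reportDetails(report)
  tab <- catalogTable(catalog)
  coreBGC <- stats::setNames(tab$bgc_id, tab$gene_id)
  rows <- list()
  for (i in seq_len(nrow(tfTab))) {
    tf <- tfTab$tf_id[i]
    mrBgcs <- sort(unique(stats::na.omit(coreBGC[det$tfMrCores[[tf]]])))
    isGlobal <- tfTab$scc_count[i] >= minCore
    isPathway <- length(mrBgcs) >= 2L
    if (!isGlobal && !isPathway) next
    category <- paste(c(if (isGlobal) "global (SCC)",
                        if (isPathway) "pathway-specific (MR-PCC)"),
                      collapse = " + ")
    rows[[tf]] <- data.frame(
      tf_id = tf, category = category,
      clustered = ifelse(tfTab$clustered[i], "clustered", "unclustered"),
      bgc_id = tfTab$bgc_id[i], scc_count = tfTab$scc_count[i],
      mr_count = tfTab$mr_count[i],
      mr_bgcs = paste(mrBgcs, collapse = ","),
      stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(tf_id = character(), category = character(),
               clustered = character(), bgc_id = character(),
               scc_count = integer(), mr_count = integer(),
               mr_bgcs = character(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Export the correlation submatrix of one BGC
#'
#' Convenience for heatmap-style inspection of a cluster's internal
#' coexpression: the correlation submatrix restricted to the BGC's member
#' genes (plus optional flanking genes supplied by the caller).
#'
#' @param corr a \linkS4class{CorrelationMatrix}.
#' @param catalog a \linkS4class{BGCCatalog}.
#' @param bgcId BGC id to extract.
#' @param extraGenes additional gene ids to include.
#' @return The correlation submatrix (base matrix).
#' @export
bgcCorrelationSubmatrix <- function(corr, catalog, bgcId,
                                    extraGenes = character()) {
  tab <- catalogTable(catalog)
  gs <- tab$gene_id[!is.na(tab$bgc_id) & tab$bgc_id == bgcId]
  if (!length(gs)) stop(sprintf("unknown BGC id: %s", bgcId))
  gs <- intersect(c(gs, extraGenes), rownames(corValues(corr)))
  corValues(corr)[gs, gs, drop = FALSE]
}
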