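#' @import methods
#' @importFrom stats cor median quantile rnorm
#' @importFrom utils head read.delim write.table
NULL

#' Simulation configuration for a synthetic expression compendium
#'
#' Describes a synthetic genes x samples compendium with planted BGC-like
#' co-regulated gene groups, regulator genes whose profile tracks one or more
#' groups, and sparse-expression confounder genes.  All intensities are on a
#' log-like (RMA-style) scale and all randomness flows from the single
#' \code{seed}.
#'
#' @slot nGenes total number of genes.
#' @slot nSamples total number of samples (conditions).
#' @slot groups list of planted groups; each element is a list with fields
#'   \code{size} (number of member genes), \code{activeSamples} (either a
#'   count, in which case active samples are drawn at random, or an explicit
#'   integer vector of sample indices), \code{signalMean} and \code{signalSd}.
#' @slot globalRegulators list of integer vectors; each vector gives the
#'   planted-group indices tracked by one unclustered (global) regulator gene.
#' @slot residentRegulators list of lists with fields \code{home} (the group
#'   whose genomic cluster hosts the regulator) and \code{targets} (integer
#'   vector of tracked groups).
#' @slot nConfounders number of sparse-expression confounder genes.  Each
#'   planted group eligible to host confounders draws a small set of
#'   "aberrant conditions" (of size \code{confounderSpikes}, capped at the
#'   window size) inside its active window; a confounder is assigned to one
#'   eligible group at random and spikes to that group's signal level in
#'   exactly those conditions, staying at baseline elsewhere.  Confounders
#'   of one group therefore correlate spuriously both with the group's
#'   members and with each other - the hazard that plain correlation
#'   networks suffer from for rarely expressed genes.
#' @slot confounderSpikes in-window spike conditions per hosting group
#'   (capped at the window size).
#' @slot confounderPrivateSpikes additional aberrant conditions per hosting
#'   group drawn outside every group's active window; the group's
#'   confounders also spike there (making fellow confounders each other's
#'   strongest mutual-rank partners, as sparse genes are in real compendia).
#' @slot confounderGroups integer vector of group indices eligible to host
#'   confounders (default: all planted groups).
#' @slot baselineMean,baselineSd baseline intensity distribution.
#' @slot seed integer seed; identical configurations give bit-identical
#'   output.
#' @seealso [simulationConfig()], [simulateCompendium()]
#' @export
setClass("SimulationConfig",
  representation(
    nGenes = "integer",
    nSamples = "integer",
    groups = "list",
    globalRegulators = "list",
    residentRegulators = "list",
    nConfounders = "integer",
    confounderSpikes = "integer",
    confounderPrivateSpikes = "integer",
    confounderGroups = "integer",
    baselineMean = "numeric",
    baselineSd = "numeric",
    seed = "integer"
  )
)

.groupSize <- function(g) as.integer(g$size)

.validSimulationConfig <- function(object) {
  msg <- character()
  if (object@nGenes < 1L) msg <- c(msg, "nGenes must be >= 1")
  if (object@nSamples < 3L)
    msg <- c(msg, "nSamples must be >= 3 (correlation needs >= 3 points)")
  for (i in seq_along(object@groups)) {
    g <- object@groups[[i]]
    if (!all(c("size", "activeSamples", "signalMean", "signalSd") %in%
             names(g)))
      msg <- c(msg, sprintf(
        "group %d must have fields size, activeSamples, signalMean, signalSd",
        i))
    else {
      if (g$size < 1) msg <- c(msg, sprintf("group %d: size must be >= 1", i))
      act <- g$activeSamples
      if (length(act) == 1L && act >= 1) {
        if (act > object@nSamples)
          msg <- c(msg, sprintf(
            "group %d: activeSamples (%d) exceeds nSamples (%d)",
            i, as.integer(act), object@nSamples))
      } else if (length(act) > 1L) {
        if (any(act < 1) || any(act > object@nSamples) || anyDuplicated(act))
          msg <- c(msg, sprintf(
            "group %d: explicit activeSamples must be unique indices in 1..nSamples", i))
      } else {
        msg <- c(msg, sprintf("group %d: invalid activeSamples", i))
      }
      if (g$signalSd < 0)
        msg <- c(msg, sprintf("group %d: signalSd must be >= 0", i))
    }
  }
  ngrp <- length(object@groups)
  for (tg in object@globalRegulators)
    if (any(tg < 1) || any(tg > ngrp))
      msg <- c(msg, "globalRegulators reference a group index out of range")
  for (rr in object@residentRegulators) {
    if (!all(c("home", "targets") %in% names(rr)))
      msg <- c(msg, "residentRegulators entries need fields home and targets")
    else if (rr$home < 1 || rr$home > ngrp ||
             any(rr$targets < 1) || any(rr$targets > ngrp))
      msg <- c(msg, "residentRegulators reference a group index out of range")
  }
  if (object@nConfounders < 0L) msg <- c(msg, "nConfounders must be >= 0")
  if (object@nConfounders > 0L && ngrp == 0L)
    msg <- c(msg, "confounders require at least one planted group")
  if (length(object@confounderGroups) &&
      (any(object@confounderGroups < 1L) || any(object@confounderGroups > ngrp)))
    msg <- c(msg, "confounderGroups reference a group index out of range")
  if (object@baselineSd < 0) msg <- c(msg, "baselineSd must be >= 0")
  planted <- sum(vapply(object@groups, .groupSize, integer(1))) +
    length(object@globalRegulators) + length(object@residentRegulators) +
    object@nConfounders
  if (planted > object@nGenes)
    msg <- c(msg, sprintf(
      "planted genes (%d groups + regulators + confounders = %d) exceed nGenes (%d)",
      ngrp, planted, object@nGenes))
  if (length(msg)) msg else TRUE
}
setValidity("SimulationConfig", .validSimulationConfig)

#' Ground truth of a simulated compendium
#'
#' Records which genes were planted where, so that recovery of the planted
#' structure by the network/module pipeline can be measured.
#'
#' @slot groupMembers named list, group id -> character vector of member gene
#'   ids (pairwise disjoint).
#' @slot groupActiveSamples named list, group id -> character vector of sample
#'   ids in which the group is transcriptionally active.
#' @slot regulatorTargets named list, regulator gene id -> character vector of
#'   target group ids.
#' @slot confounders character vector of sparse-confounder gene ids.
#' @export
setClass("PlantedTruth",
  representation(
    groupMembers = "list",
    groupActiveSamples = "list",
    regulatorTargets = "list",
    confounders = "character"
  )
)

setValidity("PlantedTruth", function(object) {
  msg <- character()
  members <- unlist(object@groupMembers, use.names = FALSE)
  if (anyDuplicated(members))
    msg <- c(msg, "planted group member sets must be pairwise disjoint")
  if (length(intersect(members, object@confounders)))
    msg <- c(msg, "confounders must be disjoint from planted group members")
  if (!setequal(names(object@groupMembers), names(object@groupActiveSamples)))
    msg <- c(msg, "groupMembers and groupActiveSamples must share group ids")
  for (tg in object@regulatorTargets)
    if (!all(tg %in% names(object@groupMembers)))
      msg <- c(msg, "regulatorTargets reference an unknown group id")
  if (length(msg)) msg else TRUE
})

#' All-pairs gene correlation matrix
#'
#' @slot values symmetric numeric matrix with unit diagonal; dimnames carry
#'   the gene ids.
#' @slot method \code{"pearson"} or \code{"spearman"}.
#' @export
setClass("CorrelationMatrix",
  representation(values = "matrix", method = "character")
)

setValidity("CorrelationMatrix", function(object) {
  v <- object@values
  msg <- character()
  if (!is.numeric(v) || nrow(v) != ncol(v))
    msg <- c(msg, "values must be a square numeric matrix")
  if (is.null(rownames(v)) || anyDuplicated(rownames(v)))
    msg <- c(msg, "values must carry unique gene ids as dimnames")
  if (!all(is.finite(v)))
    msg <- c(msg, "correlations must all be finite")
  else {
    if (max(abs(v - t(v))) > 1e-8) msg <- c(msg, "values must be symmetric")
    if (max(abs(diag(v) - 1)) > 1e-8) msg <- c(msg, "diagonal must be 1")
    if (max(abs(v)) > 1 + 1e-8) msg <- c(msg, "correlations must lie in [-1, 1]")
  }
  if (!object@method %in% c("pearson", "spearman"))
    msg <- c(msg, "method must be 'pearson' or 'spearman'")
  if (length(msg)) msg else TRUE
})

#' Mutual rank matrix
#'
#' Off-diagonal entries hold the mutual rank
#' \eqn{MR(A,B) = \sqrt{Rank_A(B) \cdot Rank_B(A)}}; the diagonal is
#' undefined and stored as \code{NA}.
#'
#' @slot values symmetric numeric matrix, off-diagonal >= 1, diagonal NA.
#' @export
setClass("MutualRankMatrix", representation(values = "matrix"))

setValidity("MutualRankMatrix", function(object) {
  v <- object@values
  msg <- character()
  if (nrow(v) != ncol(v)) msg <- c(msg, "values must be square")
  if (is.null(rownames(v)) || anyDuplicated(rownames(v)))
    msg <- c(msg, "values must carry unique gene ids as dimnames")
  off <- v[row(v) != col(v)]
  if (length(off) && (any(!is.finite(off)) || any(off < 1 - 1e-12)))
    msg <- c(msg, "off-diagonal mutual ranks must be finite and >= 1")
  if (length(off) && max(abs(v - t(v)), na.rm = TRUE) > 1e-8)
    msg <- c(msg, "values must be symmetric")
  if (length(msg)) msg else TRUE
})

#' Weighted undirected coexpression network
#'
#' @slot nodes character vector of gene ids (isolated genes are kept as
#'   nodes).
#' @slot edges data.frame with columns \code{from}, \code{to}, \code{weight}
#'   and, for SCC networks, \code{rho} (the signed Spearman coefficient; the
#'   weight is then \code{abs(rho)}).  Edges are stored once with
#'   \code{from < to} and sorted, so equal networks are byte-identical on
#'   export.
#' @slot params construction record: method, decay parameter \code{x} or
#'   \code{rhoMin}, \code{pccMin}, \code{weightMin}, and a display name such
#'   as \code{"NET10"}.
#' @export
setClass("CoexpressionNetwork",
  representation(nodes = "character", edges = "data.frame", params = "list")
)

setValidity("CoexpressionNetwork", function(object) {
  msg <- character()
  e <- object@edges
  if (!all(c("from", "to", "weight") %in% colnames(e)))
    msg <- c(msg, "edges must have columns from, to, weight")
  else if (nrow(e)) {
    if (any(e$from == e$to)) msg <- c(msg, "self-loops are not allowed")
    if (any(e$from > e$to)) msg <- c(msg, "edges must be stored with from < to")
    if (anyDuplicated(paste(e$from, e$to))) msg <- c(msg, "duplicate edges")
    if (!all(e$from %in% object@nodes) || !all(e$to %in% object@nodes))
      msg <- c(msg, "edge endpoints must be nodes")
    if (any(!is.finite(e$weight)) || any(e$weight < 0))
      msg <- c(msg, "edge weights must be finite and >= 0")
  }
  if (anyDuplicated(object@nodes)) msg <- c(msg, "node ids must be unique")
  if (length(msg)) msg else TRUE
})

#' A set of (possibly overlapping) coexpression modules
#'
#' Modules are locally optimal cohesive gene sets found by the greedy
#' cohesiveness clusterer; a gene may belong to several modules.
#'
#' @slot genes list of character vectors (each sorted); one entry per module.
#' @slot cohesiveness numeric vector, the cohesiveness score of each module on
#'   its source network.
#' @slot density numeric vector, weighted edge density of each module.
#' @slot sourceNetwork character scalar naming the network the modules were
#'   detected on (e.g. \code{"NET10"}).
#' @slot params detection parameters (minSize, minDensity, penalty,
#'   mergeOverlap, seedMode).
#' @export
setClass("ModuleSet",
  representation(genes = "list", cohesiveness = "numeric",
                 density = "numeric", sourceNetwork = "character",
                 params = "list")
)

setValidity("ModuleSet", function(object) {
  msg <- character()
  n <- length(object@genes)
  if (length(object@cohesiveness) != n || length(object@density) != n)
    msg <- c(msg, "cohesiveness and density must have one value per module")
  if (length(object@cohesiveness) &&
      (any(object@cohesiveness < -1e-12) || any(object@cohesiveness > 1 + 1e-12)))
    msg <- c(msg, "cohesiveness must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Metamodule: non-overlapping union of modules around anchor genes
#'
#' @slot genes character vector; the union of the genes of every contributing
#'   module (set semantics, sorted).
#' @slot anchorGenes the genes of interest the modules were collapsed around.
#' @slot contributing data.frame recording, for each contributing module, its
#'   source network, its index within that network's module set, and its size.
#' @export
setClass("Metamodule",
  representation(genes = "character", anchorGenes = "character",
                 contributing = "data.frame")
)

#' Catalog of predicted biosynthetic gene clusters
#'
#' Wraps a table with one row per cataloged gene: its BGC membership (possibly
#' none, for unclustered regulators), its role within the cluster, the core
#' enzyme type for core genes, and optional 1-based inclusive genomic
#' coordinates.
#'
#' @slot table data.frame with columns \code{gene_id}, \code{bgc_id},
#'   \code{role} (core/tailoring/transporter/TF/other), \code{core_type}
#'   (PKS/NRPS/FAS/terpene/hybrid/other/none), \code{chromosome},
#'   \code{start}, \code{end}.
#' @export
setClass("BGCCatalog", representation(table = "data.frame"))

.catalogRoles <- c("core", "tailoring", "transporter", "TF", "other")
.catalogCoreTypes <- c("PKS", "NRPS", "FAS", "terpene", "hybrid", "other",
                       "none")

setValidity("BGCCatalog", function(object) {
  tab <- object@table
  msg <- character()
  need <- c("gene_id", "bgc_id", "role", "core_type", "chromosome", "start",
            "end")
  if (!all(need %in% colnames(tab)))
    return(sprintf("catalog table must have columns: %s",
                   paste(need, collapse = ", ")))
  if (anyDuplicated(tab$gene_id))
    msg <- c(msg, sprintf("duplicate gene ids: %s",
                          paste(unique(tab$gene_id[duplicated(tab$gene_id)]),
                                collapse = ", ")))
  if (!all(tab$role %in% .catalogRoles))
    msg <- c(msg, sprintf("role must be one of %s",
                          paste(.catalogRoles, collapse = "/")))
  if (!all(tab$core_type %in% .catalogCoreTypes))
    msg <- c(msg, sprintf("core_type must be one of %s",
                          paste(.catalogCoreTypes, collapse = "/")))
  if (any(tab$role == "core" & tab$core_type == "none"))
    msg <- c(msg, "every core gene needs a core_type other than 'none'")
  bad <- !is.na(tab$start) & !is.na(tab$end) & tab$start > tab$end
  if (any(bad))
    msg <- c(msg, sprintf("start > end for gene(s): %s",
                          paste(tab$gene_id[bad], collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' Coexpression report over BGCs and transcription factors
#'
#' @slot bgcTable per-BGC accounting: number of member genes recovered in any
#'   module and a coexpression flag (>= 2 member genes sharing a module).
#' @slot tfTable per-TF accounting: number of BGC core genes directly linked
#'   to the TF in the SCC network (\code{scc_count}) and number of core genes
#'   sharing at least one MR-PCC module with the TF (\code{mr_count}).
#' @slot details named list with per-BGC module ids and per-TF core gene ids,
#'   so every count can be recomputed from its underlying set.
#' @slot params inputs record (network label, module sources).
#' @export
setClass("CoexpressionReport",
  representation(bgcTable = "data.frame", tfTable = "data.frame",
                 details = "list", params = "list")
)
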