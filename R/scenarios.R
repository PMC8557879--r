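#' Canned scenario: rarely expressed clusters plus sparse confounders
#'
#' A fixed study design exercising the failure mode of plain correlation
#' networks on rarely expressed genes: three planted BGC-like groups, each
#' transcriptionally active in at most five of 155 conditions, share the
#' compendium with 75 sparse-expression confounders.  Each hosting group has
#' a set of aberrant conditions (three inside its active window, two outside
#' every window) in which its confounders spike, so under plain Pearson
#' correlation every confounder acquires a strong spurious correlation
#' (|r| >= 0.5) with members of its group; but because genuine members rank
#' their fellow members first, and the confounders crowd each other's rank
#' lists, the mutual-rank transform demotes the confounder-member pairs and
#' keeps the confounders out of the planted modules.
#'
#' Rarely expressed secondary-metabolism genes are strongly induced when they
#' do fire, so the scenario uses a signal intensity of 13 against a baseline
#' of 4 on the log-like scale.
#'
#' @param seed integer seed.
#' @return As [simulateCompendium()]: list with \code{exprs} and
#'   \code{truth}.
#' @examples
#' sc <- rareClusterScenario(1)
#' length(confounderIds(sc$truth))
#' @export
rareClusterScenario <- function(seed = 1L) {
  cfg <- simulationConfig(
    nGenes = 400L, nSamples = 155L,
    groups = list(
      plantedGroup(10, 5, signalMean = 13),
      plantedGroup(8, 5, signalMean = 13),
      plantedGroup(8, 4, signalMean = 13)
    ),
    nConfounders = 75L, confounderSpikes = 3L,
    confounderPrivateSpikes = 2L,
    baselineMean = 4, baselineSd = 0.5,
    seed = seed)
  simulateCompendium(cfg)
}

#' Canned scenario: full planted compendium with BGC catalog
#'
#' The package's reference study design for end-to-end testing: 1,000 genes
#' over 155 conditions with seven planted co-regulated groups (four
#' frequently expressed, three rarely expressed), two cluster-resident
#' transcription factors that jointly track two partially co-active clusters
#' (the cross-cluster anchor pair, mirroring the pathway-specific-TF
#' pattern), one unclustered regulator whose 20-gene regulon spans two
#' core-gene-rich genomic BGCs (the global-TF pattern), 60 sparse
#' confounders riding the rare groups' aberrant conditions, and three
#' transcriptionally silent BGCs whose genes stay at baseline.
#'
#' The returned catalog maps transcriptional groups onto genomic BGCs (the
#' global-TF regulon is split across BGC03 and BGC04) and assigns roles: the
#' first gene(s) of each BGC are core enzymes, the remainder tailoring
#' enzymes; the anchor pair is cataloged as TFs resident in their home
#' cluster, the global regulator as an unclustered TF.
#'
#' @param seed integer seed.
#' @return A list with \code{exprs}, \code{truth}, \code{catalog}
#'   (\linkS4class{BGCCatalog}), \code{anchors} (the two resident TF gene
#'   ids), \code{globalRegulator} (gene id), \code{tfIds} (all cataloged
#'   TFs), and \code{config}.
#' @examples
#' pc <- plantedCompendium(42)
#' pc$catalog
#' @export
plantedCompendium <- function(seed = 42L) {
  groups <- list(
    plantedGroup(12, 1:30),    # grp01: anchor target A (hosts the TF pair)
    plantedGroup(12, 19:48),   # grp02: anchor target B, co-active with A
    plantedGroup(20, 49:98),   # grp03: global-TF regulon spanning two BGCs
    plantedGroup(8, 109:133),  # grp04
    plantedGroup(12, 134:138), # grp05: rarely expressed
    plantedGroup(12, 139:142), # grp06: rarely expressed
    plantedGroup(11, 143:146)  # grp07: rarely expressed
  )
  cfg <- simulationConfig(
    nGenes = 1000L, nSamples = 155L, groups = groups,
    globalRegulators = list(3L),
    residentRegulators = list(
      list(home = 1L, targets = c(1L, 2L)),
      list(home = 1L, targets = c(1L, 2L))
    ),
    nConfounders = 60L, confounderSpikes = 3L,
    confounderPrivateSpikes = 2L,
    confounderGroups = c(5L, 6L, 7L),  # sparse genes ride the rare windows
    baselineMean = 4, baselineSd = 0.5, seed = seed)
  sim <- simulateCompendium(cfg)
  truth <- sim$truth

  members <- groupMembers(truth)
  regs <- names(regulatorTargets(truth))
  anchors <- regs[1:2]           # resident pair (layout: resident first)
  globalReg <- regs[3]

  ## Genomic annotation: transcriptional group -> one or two contiguous
  ## BGCs.  The global-TF regulon (grp03) is split across BGC03 and BGC04,
  ## each with 6 core genes - a single co-regulated transcriptional unit
  ## spanning two predicted clusters, the pattern a global regulator shows.
  bgcOf <- list(
    list(bgc = "BGC01", group = 1L, genes = 1:12, cores = 1L,
         types = "FAS"),
    list(bgc = "BGC02", group = 2L, genes = 1:12, cores = 2L,
         types = c("PKS", "NRPS")),
    list(bgc = "BGC03", group = 3L, genes = 1:10, cores = 6L,
         types = rep("PKS", 6)),
    list(bgc = "BGC04", group = 3L, genes = 11:20, cores = 6L,
         types = rep("NRPS", 6)),
    list(bgc = "BGC05", group = 4L, genes = 1:8, cores = 1L,
         types = "PKS"),
    list(bgc = "BGC06", group = 5L, genes = 1:12, cores = 1L,
         types = "PKS"),
    list(bgc = "BGC07", group = 6L, genes = 1:12, cores = 1L,
         types = "terpene"),
    list(bgc = "BGC08", group = 7L, genes = 1:11, cores = 1L,
         types = "NRPS")
  )
  rows <- list()
  pos <- 1L
  addRow <- function(gene, bgc, role, coreType, chrom) {
    start <- pos * 3000L + 1L
    rows[[length(rows) + 1L]] <<- data.frame(
      gene_id = gene, bgc_id = bgc, role = role, core_type = coreType,
      chromosome = chrom, start = start, end = start + 1499L,
      stringsAsFactors = FALSE)
    pos <<- pos + 1L
  }
  for (i in seq_along(bgcOf)) {
    b <- bgcOf[[i]]
    gs <- members[[b$group]][b$genes]
    for (k in seq_along(gs)) {
      role <- if (k <= b$cores) "core" else "tailoring"
      ct <- if (k <= b$cores) b$types[k] else "none"
      addRow(gs[k], b$bgc, role, ct, sprintf("chr%d", ((i - 1L) %% 4L) + 1L))
    }
    if (b$bgc == "BGC01")  # the anchor TF pair is resident in BGC01
      for (a in anchors) addRow(a, b$bgc, "TF", "none", "chr1")
  }
  addRow(globalReg, NA_character_, "TF", "none", "chr5")

  ## three silent BGCs drawn from baseline genes (never transcribed above
  ## baseline; must never be flagged coexpressed)
  allGenes <- rownames(SummarizedExperiment::assay(sim$exprs, 1L))
  planted <- c(unlist(members, use.names = FALSE), regs,
               confounderIds(truth))
  baselineGenes <- setdiff(allGenes, planted)
  silentSizes <- c(6L, 5L, 4L)
  off <- 0L
  for (s in seq_along(silentSizes)) {
    bgc <- sprintf("BGC%02d", length(bgcOf) + s)
    gs <- baselineGenes[off + seq_len(silentSizes[s])]
    off <- off + silentSizes[s]
    for (k in seq_along(gs))
      addRow(gs[k], bgc, if (k == 1L) "core" else "tailoring",
             if (k == 1L) "PKS" else "none", "chr6")
  }

  catalog <- methods::new("BGCCatalog", table = do.call(rbind, rows))
  methods::validObject(catalog)

  list(exprs = sim$exprs, truth = truth, catalog = catalog,
       anchors = anchors, globalRegulator = globalReg,
       tfIds = c(anchors, globalReg), config = cfg)
}
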