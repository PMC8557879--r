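#' Run the full coexpression-mining pipeline
#'
#' Orchestrates simulate (optional) -> trimmed-mean scaling -> MR-PCC
#' networks (NET05/NET10/NET25) + SCC network -> module detection per MR
#' network -> metamodule collapse (optional) -> BGC/TF report (optional).
#' Every artifact is written with a provenance header or params block, no
#' timestamps, so a rerun with the same configuration and seed produces
#' byte-identical files.
#'
#' @param config a named list, or the path to a YAML file holding one.
#'   Recognised fields (all optional unless noted): \describe{
#'   \item{outDir}{output directory (required).}
#'   \item{seed}{integer seed for the simulate stage (default 1).}
#'   \item{simulate}{\code{"plantedCompendium"}, \code{"rareClusterScenario"},
#'     or a list of [simulationConfig()] arguments; omit to read an existing
#'     matrix.}
#'   \item{matrix}{path to an expression TSV (when not simulating;
#'     required then).}
#'   \item{catalog}{path to a BGC catalog TSV (unneeded when simulating the
#'     planted compendium, which supplies its own).}
#'   \item{trim}{per-tail trim fraction (default 0.05).}
#'   \item{xs}{decay parameters (default 5, 10, 25).}
#'   \item{pccMin, weightMin, rhoMin}{network thresholds (defaults 0.3, 0.1,
#'     0.5).}
#'   \item{minSize, minDensity, penalty, mergeOverlap}{module-detection
#'     parameters (defaults 3, 0.3, 2, 0.8).}
#'   \item{anchors}{gene ids for metamodule collapse.}
#'   \item{tfs}{TF gene ids for the report stage.}
#'   \item{minCore}{shortlist threshold (default 10).}}
#' @return Invisibly, a list with the in-memory stage results and the paths
#'   of all written artifacts.
#' @export
runPipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config))
      stop(sprintf("pipeline config not found: %s", config))
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  cfg <- config
  if (is.null(cfg$outDir)) stop("pipeline config needs an outDir")
  dir.create(cfg$outDir, recursive = TRUE, showWarnings = FALSE)
  pathOf <- function(f) file.path(cfg$outDir, f)
  paths <- list()
  seed <- as.integer(cfg$seed %||% 1L)
  trim <- cfg$trim %||% 0.05
  xs <- cfg$xs %||% c(5, 10, 25)
  pccMin <- cfg$pccMin %||% 0.3
  weightMin <- cfg$weightMin %||% 0.1
  rhoMin <- cfg$rhoMin %||% 0.5
  stage <- function(name, expr) {
    message(sprintf("[%s] running", name))
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }

  truth <- NULL
  catalog <- NULL
  anchors <- cfg$anchors
  tfs <- cfg$tfs
  exprs <- stage("simulate/load", {
    if (!is.null(cfg$simulate)) {
      sim <- if (identical(cfg$simulate, "plantedCompendium")) {
        pc <- plantedCompendium(seed)
        catalog <- pc$catalog
        if (is.null(anchors)) anchors <- pc$anchors
        if (is.null(tfs)) tfs <- pc$tfIds
        pc
      } else if (identical(cfg$simulate, "rareClusterScenario")) {
        rareClusterScenario(seed)
      } else {
        simulateCompendium(do.call(simulationConfig,
                                   c(cfg$simulate, list(seed = seed))))
      }
      truth <- sim$truth
      paths$matrix <- writeExpressionTSV(sim$exprs, pathOf("matrix.tsv"),
        provenance = list(stage = "simulate", seed = seed))
      paths$truth <- writeTruthJSON(sim$truth, pathOf("truth.json"))
      sim$exprs
    } else {
      if (is.null(cfg$matrix))
        stop("config must supply either 'simulate' or 'matrix'")
      readExpressionTSV(cfg$matrix)
    }
  })
  if (is.null(catalog) && !is.null(cfg$catalog))
    catalog <- stage("catalog", loadCatalog(cfg$catalog))
  if (!is.null(catalog))
    paths$catalog <- writeCatalog(catalog, pathOf("catalog.tsv"))

  scaled <- stage("normalize", {
    s <- scaleToTrimmedMean(exprs, trim = trim)
    paths$scaled <- writeExpressionTSV(s, pathOf("matrix.scaled.tsv"),
      provenance = list(stage = "normalize", trim = trim))
    s
  })

  scaled <- stage("variance-filter", dropZeroVarianceGenes(scaled))

  mrNets <- stage("mr-networks", {
    nets <- buildMRNetworks(scaled, xs = xs, pccMin = pccMin,
                            weightMin = weightMin)
    for (nm in names(nets)) {
      paths[[paste0("net_", nm)]] <-
        writeNetworkTSV(nets[[nm]], pathOf(sprintf("net_%s.tsv", nm)))
      paths[[paste0("graphml_", nm)]] <-
        writeGraphML(nets[[nm]], pathOf(sprintf("net_%s.graphml", nm)),
                     catalog = catalog)
    }
    nets
  })
  sccNet <- stage("scc-network", {
    net <- buildSCCNetwork(scaled, rhoMin = rhoMin)
    paths$net_SCC <- writeNetworkTSV(net, pathOf("net_SCC.tsv"))
    paths$graphml_SCC <- writeGraphML(net, pathOf("net_SCC.graphml"),
                                       catalog = catalog)
    if (!is.null(catalog))
      paths$node_attributes <- writeNodeAttributesTSV(
        net, catalog, pathOf("node_attributes.tsv"))
    net
  })

  moduleSets <- stage("modules", {
    ms <- lapply(mrNets, detectModules,
                 minSize = cfg$minSize %||% 3L,
                 minDensity = cfg$minDensity %||% 0.3,
                 penalty = cfg$penalty %||% 2,
                 mergeOverlap = cfg$mergeOverlap %||% 0.8)
    for (nm in names(ms)) {
      paths[[paste0("modules_", nm)]] <-
        writeModulesJSON(ms[[nm]], pathOf(sprintf("modules_%s.json", nm)))
      paths[[paste0("modules_tsv_", nm)]] <-
        writeModulesTSV(ms[[nm]], pathOf(sprintf("modules_%s.tsv", nm)))
    }
    ms
  })

  metamodule <- NULL
  if (!is.null(anchors) && length(anchors))
    metamodule <- stage("metamodule", {
      mm <- collapseMetamodule(unname(moduleSets), anchors)
      paths$metamodule <- writeMetamoduleJSON(mm, pathOf("metamodule.json"))
      mm
    })

  report <- NULL
  shortlist <- NULL
  if (!is.null(catalog))
    report <- stage("report", {
      bgcRep <- bgcModuleOverlap(unname(moduleSets), catalog)
      rep <- bgcRep
      if (!is.null(tfs) && length(tfs)) {
        tfRep <- tfCoreCoexpressionCounts(sccNet, unname(moduleSets),
                                          catalog, tfs)
        rep <- methods::new("CoexpressionReport",
          bgcTable = bgcTable(bgcRep), tfTable = tfTable(tfRep),
          details = c(reportDetails(bgcRep), reportDetails(tfRep)),
          params = c(bgcRep@params["moduleSources"], tfRep@params))
        shortlist <- shortlistTFs(tfRep, catalog,
                                   minCore = cfg$minCore %||% 10L)
        utils::write.table(tfTable(tfRep), pathOf("report_tf.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        paths$report_tf <- pathOf("report_tf.tsv")
      }
      paths$report <- writeReportJSON(rep, pathOf("report.json"))
      rep
    })

  invisible(list(exprs = exprs, scaled = scaled, truth = truth,
                 catalog = catalog, mrNetworks = mrNets, sccNetwork = sccNet,
                 moduleSets = moduleSets, metamodule = metamodule,
                 report = report, shortlist = shortlist, paths = paths))
}
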