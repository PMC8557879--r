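#' @rdname mrcoex-accessors
setMethod("corValues", "CorrelationMatrix", function(x, ...) x@values)

#' @rdname mrcoex-accessors
setMethod("corMethod", "CorrelationMatrix", function(x, ...) x@method)

#' @rdname mrcoex-accessors
setMethod("mrValues", "MutualRankMatrix", function(x, ...) x@values)

#' @rdname mrcoex-accessors
setMethod("networkNodes", "CoexpressionNetwork", function(x, ...) x@nodes)

#' @rdname mrcoex-accessors
setMethod("networkEdges", "CoexpressionNetwork", function(x, ...) x@edges)

#' @rdname mrcoex-accessors
setMethod("networkParams", "CoexpressionNetwork", function(x, ...) x@params)

#' @rdname mrcoex-accessors
#' @param i optional module index; if missing, the full list is returned.
setMethod("moduleGenes", "ModuleSet", function(x, i, ...) {
  if (missing(i)) x@genes else x@genes[[i]]
})

#' @rdname mrcoex-accessors
setMethod("moduleCount", "ModuleSet", function(x, ...) length(x@genes))

#' @rdname mrcoex-accessors
setMethod("cohesivenessScores", "ModuleSet", function(x, ...) x@cohesiveness)

#' @rdname mrcoex-accessors
setMethod("densityScores", "ModuleSet", function(x, ...) x@density)

#' @rdname mrcoex-accessors
setMethod("sourceNetwork", "ModuleSet", function(x, ...) x@sourceNetwork)

#' @rdname mrcoex-accessors
setMethod("metamoduleGenes", "Metamodule", function(x, ...) x@genes)

#' @rdname mrcoex-accessors
setMethod("anchorGenes", "Metamodule", function(x, ...) x@anchorGenes)

#' @rdname mrcoex-accessors
setMethod("contributingModules", "Metamodule", function(x, ...) x@contributing)

#' @rdname mrcoex-accessors
setMethod("catalogTable", "BGCCatalog", function(x, ...) x@table)

#' @rdname mrcoex-accessors
setMethod("groupMembers", "PlantedTruth", function(x, ...) x@groupMembers)

#' @rdname mrcoex-accessors
setMethod("groupActiveSamples", "PlantedTruth",
          function(x, ...) x@groupActiveSamples)

#' @rdname mrcoex-accessors
setMethod("regulatorTargets", "PlantedTruth",
          function(x, ...) x@regulatorTargets)

#' @rdname mrcoex-accessors
setMethod("confounderIds", "PlantedTruth", function(x, ...) x@confounders)

#' @rdname mrcoex-accessors
setMethod("bgcTable", "CoexpressionReport", function(x, ...) x@bgcTable)

#' @rdname mrcoex-accessors
setMethod("tfTable", "CoexpressionReport", function(x, ...) x@tfTable)

#' @rdname mrcoex-accessors
setMethod("reportDetails", "CoexpressionReport", function(x, ...) x@details)

setMethod("show", "SimulationConfig", function(object) {
  cat(sprintf("SimulationConfig: %d genes x %d samples, seed %d\n",
              object@nGenes, object@nSamples, object@seed))
  cat(sprintf("  %d planted group(s), %d global / %d resident regulator(s), %d confounder(s)\n",
              length(object@groups), length(object@globalRegulators),
              length(object@residentRegulators), object@nConfounders))
  cat(sprintf("  baseline %.2f +/- %.2f\n", object@baselineMean,
              object@baselineSd))
})

setMethod("show", "PlantedTruth", function(object) {
  sizes <- vapply(object@groupMembers, length, integer(1))
  cat(sprintf("PlantedTruth: %d group(s) (sizes: %s), %d regulator(s), %d confounder(s)\n",
              length(sizes), paste(sizes, collapse = ", "),
              length(object@regulatorTargets), length(object@confounders)))
})

setMethod("show", "CorrelationMatrix", function(object) {
  cat(sprintf("CorrelationMatrix (%s): %d genes\n", object@method,
              nrow(object@values)))
})

setMethod("show", "MutualRankMatrix", function(object) {
  cat(sprintf("MutualRankMatrix: %d genes\n", nrow(object@values)))
})

setMethod("show", "CoexpressionNetwork", function(object) {
  p <- object@params
  nm <- if (!is.null(p$name)) p$name else "network"
  cat(sprintf("CoexpressionNetwork %s: %d nodes, %d edges\n", nm,
              length(object@nodes), nrow(object@edges)))
  if (!is.null(p$method))
    cat(sprintf("  method: %s%s\n", p$method,
                if (!is.null(p$x)) sprintf(" (x = %g, pccMin = %g, weightMin = %g)",
                                           p$x, p$pccMin, p$weightMin)
                else if (!is.null(p$rhoMin)) sprintf(" (|rho| >= %g)", p$rhoMin)
                else ""))
})

setMethod("show", "ModuleSet", function(object) {
  n <- length(object@genes)
  cat(sprintf("ModuleSet (%s): %d module(s)\n", object@sourceNetwork, n))
  if (n) {
    sizes <- vapply(object@genes, length, integer(1))
    cat(sprintf("  sizes: median %g, range %d-%d\n", median(sizes),
                min(sizes), max(sizes)))
    cat(sprintf("  cohesiveness: %.3f-%.3f\n", min(object@cohesiveness),
                max(object@cohesiveness)))
  }
})

setMethod("show", "Metamodule", function(object) {
  cat(sprintf("Metamodule: %d genes from %d contributing module(s); anchors: %s\n",
              length(object@genes), nrow(object@contributing),
              paste(object@anchorGenes, collapse = ", ")))
})

setMethod("show", "BGCCatalog", function(object) {
  tab <- object@table
  cat(sprintf("BGCCatalog: %d genes, %d BGC(s), %d core gene(s), %d TF(s)\n",
              nrow(tab), length(unique(tab$bgc_id[!is.na(tab$bgc_id)])),
              sum(tab$role == "core"), sum(tab$role == "TF")))
})

setMethod("show", "CoexpressionReport", function(object) {
  cat("CoexpressionReport\n")
  if (nrow(object@bgcTable))
    cat(sprintf("  BGCs: %d assessed, %d flagged coexpressed\n",
                nrow(object@bgcTable), sum(object@bgcTable$coexpressed)))
  if (nrow(object@tfTable))
    cat(sprintf("  TFs: %d assessed (SCC counts %s)\n",
                nrow(object@tfTable),
                paste(object@tfTable$scc_count, collapse = ", ")))
})
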