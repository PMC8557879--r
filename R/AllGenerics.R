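#' @name mrcoex-accessors
#' @title Accessors for mrcoex classes
#' @description Small accessor generics so downstream code never reaches into
#'   slots directly.
#' @param x an mrcoex object.
#' @param ... ignored.
#' @return The slot contents documented per method.
NULL

#' @rdname mrcoex-accessors
#' @export
setGeneric("corValues", function(x, ...) standardGeneric("corValues"))

#' @rdname mrcoex-accessors
#' @export
setGeneric("corMethod", function(x, ...) standardGeneric("corMethod"))

#' @rdname mrcoex-accessors
#' @export
setGeneric("mrValues", function(x, ...) standardGeneric("mrValues"))

#' @rdname mrcoex-accessors
#' @export
setGeneric("networkNodes", function(x, ...) standardGeneric("networkNodes"))

#' @rdname mrcoex-accessors
#' @export
setGeneric("networkEdges", function(x, ...) standardGeneric("networkEdges"))

#' @rdname mrcoex-accessors
#' @export
setGeneric("networkParams", function(x, ...) standardGeneric("networkParams"))

#' @rdname mrcoex-accessors
#' @export
setGeneric("moduleGenes", function(x, ...) standardGeneric("moduleGenes"))

#' @rdname mrcoex-accessors
#' @export
setGeneric("moduleCount", function(x, ...) standardGeneric("moduleCount"))

#' @rdname mrcoex-accessors
#' @export
setGeneric("cohesivenessScores",
           function(x, ...) standardGeneric("cohesivenessScores"))

#' @rdname mrcoex-accessors
#' @export
setGeneric("densityScores", function(x, ...) standardGeneric("densityScores"))

#' @rdname mrcoex-accessors
#' @export
setGeneric("sourceNetwork", function(x, ...) standardGeneric("sourceNetwork"))

#' @rdname mrcoex-accessors
#' @export
setGeneric("metamoduleGenes",
           function(x, ...) standardGeneric("metamoduleGenes"))

#' @rdname mrcoex-accessors
#' @export
setGeneric("anchorGenes", function(x, ...) standardGeneric("anchorGenes"))

#' @rdname mrcoex-accessors
#' @export
setGeneric("contributingModules",
           function(x, ...) standardGeneric("contributingModules"))

#' @rdname mrcoex-accessors
#' @export
setGeneric("catalogTable", function(x, ...) standardGeneric("catalogTable"))

#' @rdname mrcoex-accessors
#' @export
setGeneric("groupMembers", function(x, ...) standardGeneric("groupMembers"))

#' @rdname mrcoex-accessors
#' @export
setGeneric("groupActiveSamples",
           function(x, ...) standardGeneric("groupActiveSamples"))

#' @rdname mrcoex-accessors
#' @export
setGeneric("regulatorTargets",
           function(x, ...) standardGeneric("regulatorTargets"))

#' @rdname mrcoex-accessors
#' @export
setGeneric("confounderIds", function(x, ...) standardGeneric("confounderIds"))

#' @rdname mrcoex-accessors
#' @export
setGeneric("bgcTable", function(x, ...) standardGeneric("bgcTable"))

#' @rdname mrcoex-accessors
#' @export
setGeneric("tfTable", function(x, ...) standardGeneric("tfTable"))

#' @rdname mrcoex-accessors
#' @export
setGeneric("reportDetails", function(x, ...) standardGeneric("reportDetails"))
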