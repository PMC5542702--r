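#' @import methods
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays colData
#'   rowData
#' @importFrom S4Vectors DataFrame metadata
NULL

#' @export
setGeneric("log2Ratios", function(x, contrast) standardGeneric("log2Ratios"))

#' @export
setGeneric("detectionFlags",
           function(x, contrast) standardGeneric("detectionFlags"))

#' @export
setGeneric("contrastNames", function(x) standardGeneric("contrastNames"))

#' @export
setGeneric("truthLabels", function(x) standardGeneric("truthLabels"))

#' @export
setGeneric("detectableProbes", function(x) standardGeneric("detectableProbes"))

#' @export
setGeneric("callDifferentialExpression",
           function(x, config = deConfig(), ...)
             standardGeneric("callDifferentialExpression"))
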