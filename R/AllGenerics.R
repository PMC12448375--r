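#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames colData
#' @importFrom S4Vectors DataFrame metadata
#' @importFrom e1071 svm
#' @importFrom stats predict rnorm runif sd setNames quantile
#' @importFrom utils read.delim write.table head
NULL

#' @export
setGeneric("rawIntensity", function(x) standardGeneric("rawIntensity"))

#' @export
setGeneric("normIntensity", function(x) standardGeneric("normIntensity"))

#' @export
setGeneric("matchedMask", function(x) standardGeneric("matchedMask"))

#' @export
setGeneric("nMatched", function(x) standardGeneric("nMatched"))

#' @export
setGeneric("scanIds", function(x) standardGeneric("scanIds"))

#' @export
setGeneric("cfLabels", function(x) standardGeneric("cfLabels"))

#' @export
setGeneric("cfLabels<-", function(x, value) standardGeneric("cfLabels<-"))

#' @export
setGeneric("reconstructionError",
           function(model, X) standardGeneric("reconstructionError"))
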