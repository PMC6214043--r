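#' @include AllClasses.R
NULL

#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))

#' @export
setGeneric("exprValues", function(x) standardGeneric("exprValues"))

#' @export
setGeneric("nGenes", function(x) standardGeneric("nGenes"))

#' @export
setGeneric("nTimePoints", function(x) standardGeneric("nTimePoints"))

#' @export
setGeneric("timeLabels", function(x) standardGeneric("timeLabels"))

#' @export
setGeneric("edges", function(x) standardGeneric("edges"))

#' @export
setGeneric("candidates", function(x) standardGeneric("candidates"))
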