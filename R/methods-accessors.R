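#' @include AllClasses.R AllGenerics.R
NULL

#' @describeIn ExpressionSeries-class gene identifiers.
#' @param x an object.
#' @export
setMethod("geneIds", "ExpressionSeries", function(x) rownames(x@values))

#' @describeIn ExpressionSeries-class the genes-by-time matrix.
#' @export
setMethod("exprValues", "ExpressionSeries", function(x) x@values)

#' @describeIn ExpressionSeries-class number of genes.
#' @export
setMethod("nGenes", "ExpressionSeries", function(x) nrow(x@values))

#' @describeIn ExpressionSeries-class number of time points.
#' @export
setMethod("nTimePoints", "ExpressionSeries", function(x) ncol(x@values))

#' @describeIn ExpressionSeries-class time labels (may be NULL).
#' @export
setMethod("timeLabels", "ExpressionSeries", function(x) colnames(x@values))

setMethod("show", "ExpressionSeries", function(object) {
    cat("ExpressionSeries:", nGenes(object), "genes x",
        nTimePoints(object), "time points\n")
    cat("genes:", paste(utils::head(geneIds(object), 6), collapse = ", "),
        if (nGenes(object) > 6) "..." else "", "\n")
})

#' @describeIn GoldNetwork-class the directed edge table.
#' @param x an object.
#' @export
setMethod("edges", "GoldNetwork", function(x) x@edges)

setMethod("show", "GoldNetwork", function(object) {
    e <- object@edges
    cat("GoldNetwork:", nrow(e), "directed edge(s),",
        sum(e$self_loop), "self-loop(s)\n")
})

#' @describeIn InferredNetwork-class the inferred edge table.
#' @export
setMethod("edges", "InferredNetwork", function(x) x@edges)

setMethod("show", "InferredNetwork", function(object) {
    e <- object@edges
    cat("InferredNetwork:", nrow(e), "directed lag-annotated edge(s)\n")
    if (nrow(e)) print(utils::head(e, 10), row.names = FALSE)
})

#' @describeIn CandidateSet-class the ranked shortlist table.
#' @export
setMethod("candidates", "CandidateSet", function(x) x@candidates)

setMethod("show", "CandidateSet", function(object) {
    cat("CandidateSet for target", object@targetIndex, ":",
        nrow(object@candidates), "candidate(s)\n")
    print(object@candidates, row.names = FALSE)
})

setMethod("show", "RunConfig", function(object) {
    cat("RunConfig: tauMax =", object@tauMax, ", L =", object@L,
        ", minLag =", object@minLag, "\n")
    cat("  normalization =", object@normalization,
        ", encoding =", object@encoding,
        ", seed =", object@seed, ", nRuns =", object@nRuns, "\n")
})

setMethod("show", "DelayedDesign", function(object) {
    cat("DelayedDesign: target", object@targetIndex, ",",
        length(object@regulatorIndices), "regulator(s), window length",
        length(object@target), "\n")
    cat("  lags:", paste(object@lags, collapse = ", "), "\n")
})

setMethod("show", "CVFNTree", function(object) {
    cat("CVFNTree:", treeSize(object), "node(s), depth", treeDepth(object),
        "/", object@maxDepth, ",", object@nInputs, "input(s)\n")
    cat(" ", formatTree(object@root), "\n")
})

setMethod("show", "SyntheticSpec", function(object) {
    cat("SyntheticSpec:", object@nGenes, "genes,", nrow(object@edges),
        "edges, m =", object@m, ", noiseSd =", object@noiseSd,
        ", link =", object@link, "\n")
})
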