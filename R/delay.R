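#' Build the lag-aligned design matrix for one target gene
#'
#' Each candidate regulator is shifted forward by its own lag so that the
#' regulator value driving the target at output time \code{t} sits in the
#' same column as the target value at \code{t}. Because the regulators carry
#' different lags, all series are truncated to the common output window
#' \code{t = max(lags) .. m-1} (0-based), of length
#' \code{m_eff = m - max(lags)}; one target vector then serves all inputs of
#' the multi-input tree model.
#'
#' @param es an \code{\link{ExpressionSeries}}.
#' @param candidateSet a \code{\link{CandidateSet}} whose lags were chosen by
#'   \code{\link{bestLag}} during scoring (they are not re-estimated here).
#' @return a \code{\link{DelayedDesign}}.
#' @export
buildDelayedDesign <- function(es, candidateSet) {
    values <- exprValues(es)
    m <- ncol(values)
    cd <- candidates(candidateSet)
    lags <- as.integer(cd$lag)
    regs <- as.integer(cd$regulator)
    maxLag <- max(lags)
    mEff <- m - maxLag
    if (mEff < 5L)
        stop("output window shorter than 5 points; reduce tauMax ",
             "(m = ", m, ", max lag = ", maxLag, ")")
    outWin <- seq.int(maxLag + 1L, m)           # 1-based output window
    inputs <- matrix(0, nrow = length(regs), ncol = mEff)
    for (i in seq_along(regs))
        inputs[i, ] <- values[regs[i], outWin - lags[i]]
    rownames(inputs) <- rownames(values)[regs]
    new("DelayedDesign",
        targetIndex = candidateSet@targetIndex,
        regulatorIndices = regs, lags = lags,
        inputs = inputs, target = values[candidateSet@targetIndex, outWin])
}

#' Dump a delayed design matrix as tab-separated text
#'
#' Debug view: one row per regulator (lag-aligned) plus the target row.
#'
#' @param design a \code{\link{DelayedDesign}}.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writeDelayedDesign <- function(design, path) {
    mat <- rbind(design@inputs, target = design@target)
    df <- data.frame(series = c(paste0("regulator_", design@regulatorIndices,
                                       "_lag", design@lags), "target"),
                     mat, check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
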