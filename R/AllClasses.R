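#' Gene-expression time series container
#'
#' An \code{ExpressionSeries} holds a genes-by-time-points matrix of
#' expression values from a single time-course experiment. Row names are the
#' gene identifiers (unique, non-empty); column order is the temporal order,
#' with optional column names as time labels. Values must be finite: the
#' downstream association measures and the neural-tree model make no provision
#' for missing data.
#'
#' @slot values numeric matrix, genes in rows, ordered time points in columns.
#'
#' @examples
#' es <- ExpressionSeries(matrix(runif(40), 4, 10,
#'   dimnames = list(paste0("g", 1:4), NULL)))
#' nGenes(es)
#' @export
setClass("ExpressionSeries", representation(values = "matrix"))

setValidity("ExpressionSeries", function(object) {
    v <- object@values
    if (!is.numeric(v))
        return("'values' must be a numeric matrix")
    if (anyNA(v) || any(!is.finite(v)))
        return("expression values must be finite with no missing entries")
    if (nrow(v) < 2L)
        return("at least 2 genes are required")
    ids <- rownames(v)
    if (is.null(ids) || any(!nzchar(ids)))
        return("row names (gene identifiers) are required and must be non-empty")
    if (anyDuplicated(ids))
        return(sprintf("duplicated gene identifier(s): %s",
                       paste(unique(ids[duplicated(ids)]), collapse = ", ")))
    TRUE
})

#' @rdname ExpressionSeries-class
#' @param values numeric matrix with unique row names (gene ids).
#' @param timeLabels optional character vector of column labels.
#' @export
ExpressionSeries <- function(values, timeLabels = colnames(values)) {
    values <- as.matrix(values)
    storage.mode(values) <- "double"
    if (!is.null(timeLabels))
        colnames(values) <- as.character(timeLabels)
    new("ExpressionSeries", values = values)
}

#' Gold-standard directed regulatory network
#'
#' Directed (regulator, target) edge pairs used as ground truth for
#' evaluation. Self-loops are retained on input but flagged, because the
#' inference procedure never proposes them; whether they enter the confusion
#' universe is decided at evaluation time (\code{\link{confusionCounts}}).
#'
#' @slot edges data.frame with character columns \code{regulator},
#'   \code{target} and logical \code{self_loop}.
#' @export
setClass("GoldNetwork", representation(edges = "data.frame"))

setValidity("GoldNetwork", function(object) {
    e <- object@edges
    need <- c("regulator", "target", "self_loop")
    if (!all(need %in% names(e)))
        return("edges must have columns regulator, target, self_loop")
    if (nrow(e) && anyDuplicated(e[, c("regulator", "target")]))
        return("duplicate directed edges in gold network")
    TRUE
})

#' @rdname GoldNetwork-class
#' @param regulator,target character vectors of equal length.
#' @export
GoldNetwork <- function(regulator = character(), target = character()) {
    regulator <- as.character(regulator)
    target <- as.character(target)
    stopifnot(length(regulator) == length(target))
    e <- unique(data.frame(regulator = regulator, target = target,
                           stringsAsFactors = FALSE))
    e$self_loop <- e$regulator == e$target
    new("GoldNetwork", edges = e)
}

#' Run configuration
#'
#' Global parameters of one inference run: the lag search window
#' \code{[minLag, tauMax]} (in sampling intervals), the candidate-shortlist
#' size \code{L}, the per-gene normalisation applied before scoring and
#' modelling, the complex input encoding for the neural tree, the root random
#' seed and the optimizer settings (see \code{\link{optimizerConfig}}).
#'
#' @slot tauMax,minLag non-negative integers, \code{minLag <= tauMax}.
#' @slot L positive integer, number of candidate regulators per target.
#' @slot normalization one of \code{"minmax"}, \code{"zscore"}, \code{"none"}.
#' @slot encoding complex input encoding, \code{"real"} or \code{"phase"}.
#' @slot seed integer root seed; \code{nRuns} number of repeated runs.
#' @slot optimizer list from \code{\link{optimizerConfig}}.
#' @export
setClass("RunConfig", representation(
    tauMax = "integer", L = "integer", minLag = "integer",
    normalization = "character", encoding = "character",
    seed = "integer", nRuns = "integer", optimizer = "list"))

setValidity("RunConfig", function(object) {
    if (object@tauMax < 0L || object@minLag < 0L)
        return("tauMax and minLag must be non-negative")
    if (object@minLag > object@tauMax)
        return("minLag must not exceed tauMax")
    if (object@L < 1L)
        return("L must be a positive integer")
    if (!object@normalization %in% c("minmax", "zscore", "none"))
        return("normalization must be one of minmax, zscore, none")
    if (!object@encoding %in% c("real", "phase"))
        return("encoding must be 'real' or 'phase'")
    if (object@nRuns < 1L)
        return("nRuns must be positive")
    TRUE
})

#' @rdname RunConfig-class
#' @param tauMax maximum time lag searched, in sampling intervals.
#' @param L candidate regulators kept per target gene.
#' @param minLag smallest lag searched (0 allows instantaneous regulation).
#' @param normalization per-gene normalisation mode.
#' @param encoding real-to-complex input encoding for the tree terminals.
#' @param seed root random seed.
#' @param nRuns number of repeated runs for \code{\link{multiRunSummary}}.
#' @param optimizer optimizer settings, see \code{\link{optimizerConfig}}.
#' @export
RunConfig <- function(tauMax = 6L, L = 2L, minLag = 0L,
                      normalization = "minmax", encoding = "real",
                      seed = 1L, nRuns = 1L,
                      optimizer = optimizerConfig()) {
    new("RunConfig", tauMax = as.integer(tauMax), L = as.integer(L),
        minLag = as.integer(minLag), normalization = normalization,
        encoding = encoding, seed = as.integer(seed),
        nRuns = as.integer(nRuns), optimizer = optimizer)
}

#' Ranked candidate-regulator shortlist for one target gene
#'
#' Result of the hybrid rank aggregation: the \code{L} genes whose summed
#' per-measure ranks (time-delayed mutual information, maximal information
#' coefficient and absolute correlation) are smallest, each annotated with the
#' correlation-optimal lag used downstream to align the design matrix.
#'
#' @slot targetIndex index of the target gene in its dataset.
#' @slot candidates data.frame with columns \code{regulator} (index),
#'   \code{agg_rank}, \code{lag}, and the three per-measure scores.
#' @export
setClass("CandidateSet", representation(
    targetIndex = "integer", candidates = "data.frame"))

setValidity("CandidateSet", function(object) {
    cd <- object@candidates
    need <- c("regulator", "agg_rank", "lag")
    if (!all(need %in% names(cd)))
        return("candidates must have columns regulator, agg_rank, lag")
    if (object@targetIndex %in% cd$regulator)
        return("target gene cannot be its own candidate regulator")
    if (nrow(cd) > 1L && is.unsorted(cd$agg_rank))
        return("aggregated ranks must be non-decreasing down the shortlist")
    TRUE
})

#' Lag-aligned design matrix for one target gene
#'
#' Regulator series shifted by their per-pair lags onto the common output
#' window of length \code{m_eff = m - max(lags)}, paired with the target
#' vector on the same window. Row \code{i} of \code{inputs} holds regulator
#' \code{i} at time \code{t - lags[i]} for each output time \code{t}.
#'
#' @slot targetIndex target gene index; \code{regulatorIndices} and
#'   \code{lags} are parallel vectors over the candidate regulators.
#' @slot inputs numeric matrix, regulators in rows, output window in columns.
#' @slot target numeric vector over the same window.
#' @export
setClass("DelayedDesign", representation(
    targetIndex = "integer", regulatorIndices = "integer", lags = "integer",
    inputs = "matrix", target = "numeric"))

setValidity("DelayedDesign", function(object) {
    if (length(object@regulatorIndices) != length(object@lags))
        return("regulatorIndices and lags must have equal length")
    if (nrow(object@inputs) != length(object@regulatorIndices))
        return("inputs must have one row per regulator")
    if (ncol(object@inputs) != length(object@target))
        return("inputs and target must share the output window length")
    if (any(!is.finite(object@inputs)) || any(!is.finite(object@target)))
        return("design matrix must be finite")
    TRUE
})

#' Complex-valued flexible neural tree
#'
#' A typed expression tree. Internal (function) nodes are flexible neurons
#' \code{+n}: they weight their \code{n} children by complex weights, add a
#' complex threshold, and pass the total excitation through the complex
#' Elliot activation \code{net / (a + |net|/r)} with per-node positive real
#' parameters \code{a}, \code{r}. Leaves are terminals \code{z_i} that emit
#' the i-th encoded input series.
#'
#' Nodes are plain lists: function nodes carry \code{kind = "function"},
#' \code{weights} (complex), \code{w0} (complex), \code{a}, \code{r},
#' \code{children}; terminals carry \code{kind = "terminal"} and
#' \code{input} (1-based index into the design's regulator rows).
#'
#' @slot root the root node list.
#' @slot nInputs number of available terminals.
#' @slot maxDepth depth bound (a lone terminal has depth 1).
#' @export
setClass("CVFNTree", representation(
    root = "list", nInputs = "integer", maxDepth = "integer"))

setValidity("CVFNTree", function(object) {
    msg <- .checkNode(object@root, object@nInputs)
    if (!isTRUE(msg)) return(msg)
    if (treeDepth(object) > object@maxDepth)
        return("tree exceeds its depth bound")
    TRUE
})

.checkNode <- function(node, nInputs) {
    if (!is.list(node) || is.null(node$kind))
        return("malformed node")
    if (node$kind == "terminal") {
        if (is.null(node$input) || node$input < 1L || node$input > nInputs)
            return("terminal input index out of range")
        return(TRUE)
    }
    if (node$kind != "function")
        return("node kind must be 'function' or 'terminal'")
    n <- length(node$children)
    if (n < 2L) return("function nodes need at least 2 children")
    if (length(node$weights) != n)
        return("weights length must equal arity")
    if (length(node$w0) != 1L) return("w0 must be a single complex value")
    if (!is.numeric(node$a) || !is.numeric(node$r) ||
        node$a <= 0 || node$r <= 0)
        return("activation parameters a, r must be positive reals")
    for (ch in node$children) {
        msg <- .checkNode(ch, nInputs)
        if (!isTRUE(msg)) return(msg)
    }
    TRUE
}

#' @rdname CVFNTree-class
#' @param root root node list.
#' @param nInputs number of terminals available to the tree.
#' @param maxDepth depth bound.
#' @export
CVFNTree <- function(root, nInputs, maxDepth = 4L) {
    new("CVFNTree", root = root, nInputs = as.integer(nInputs),
        maxDepth = as.integer(maxDepth))
}

#' Inferred directed, lag-annotated network
#'
#' Union over all target genes of the regulators read off the fitted trees.
#' Each edge carries the correlation-optimal lag at which the regulator was
#' aligned and the training RMSE of the target's fitted tree.
#'
#' @slot edges data.frame with columns \code{regulator}, \code{target},
#'   \code{lag}, \code{score}.
#' @export
setClass("InferredNetwork", representation(edges = "data.frame"))

setValidity("InferredNetwork", function(object) {
    e <- object@edges
    need <- c("regulator", "target", "lag", "score")
    if (!all(need %in% names(e)))
        return("edges must have columns regulator, target, lag, score")
    if (nrow(e)) {
        if (anyDuplicated(e[, c("regulator", "target")]))
            return("duplicate (regulator, target) pairs")
        if (any(e$regulator == e$target))
            return("self-loops are never inferred")
        if (any(e$lag < 0))
            return("lags must be non-negative")
    }
    TRUE
})

#' @rdname InferredNetwork-class
#' @param edges data.frame with columns regulator, target, lag, score.
#' @export
InferredNetwork <- function(edges = data.frame(
        regulator = character(), target = character(),
        lag = integer(), score = numeric())) {
    new("InferredNetwork", edges = edges)
}

#' Synthetic network specification
#'
#' Ground truth for the time-course simulator: a directed, lag-annotated,
#' weighted edge set over \code{nGenes} genes. Genes with no incoming edge
#' are drivers and evolve autonomously; all lags are at least 1 so the
#' system can be simulated forward in time.
#'
#' @slot nGenes number of genes; \code{m} emitted time points.
#' @slot edges data.frame with integer \code{regulator}, \code{target},
#'   \code{lag} and numeric \code{weight}.
#' @slot noiseSd observation noise s.d. on regulated genes.
#' @slot link regulatory link function: \code{"elliot"}, \code{"linear"} or
#'   \code{"sigmoid"}.
#' @slot tauMax largest admissible lag; \code{seed} generator seed.
#' @export
setClass("SyntheticSpec", representation(
    nGenes = "integer", edges = "data.frame", noiseSd = "numeric",
    m = "integer", link = "character", tauMax = "integer", seed = "integer"))

setValidity("SyntheticSpec", function(object) {
    e <- object@edges
    if (!all(c("regulator", "target", "lag", "weight") %in% names(e)))
        return("edges must have columns regulator, target, lag, weight")
    if (nrow(e)) {
        if (any(e$regulator == e$target)) return("self-loops not allowed")
        if (any(e$lag < 1L)) return("all lags must be >= 1")
        if (any(e$lag > object@tauMax)) return("lags must not exceed tauMax")
        if (any(e$regulator > object@nGenes | e$target > object@nGenes))
            return("edge endpoints out of gene range")
        if (anyDuplicated(e[, c("regulator", "target")]))
            return("duplicate edges")
    }
    if (object@noiseSd < 0) return("noiseSd must be non-negative")
    if (!object@link %in% c("elliot", "linear", "sigmoid"))
        return("link must be elliot, linear or sigmoid")
    TRUE
})
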