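#' Complex Elliot activation
#'
#' \code{net / (a + |net|/r)} on a complex excitation \code{net}, with
#' \code{|net|} the complex modulus. The denominator is strictly positive for
#' \code{a > 0}, and the output modulus is bounded by \code{r}.
#'
#' @param net complex (or numeric) excitation, vectorised.
#' @param a,r positive real activation parameters.
#' @return complex vector of the same length as \code{net}.
#' @export
complexElliot <- function(net, a, r) {
    stopifnot(a > 0, r > 0)
    net / (a + Mod(net) / r)
}

#' Output of one flexible neuron
#'
#' Weights the child outputs by the node's complex weights, adds the complex
#' threshold \code{w0}, and applies the complex Elliot activation with the
#' node's \code{(a, r)}.
#'
#' @param node a function node (see \code{\link{CVFNTree-class}}).
#' @param childOutputs complex vector, one entry per child.
#' @return a single complex value.
#' @export
evaluateNeuron <- function(node, childOutputs) {
    if (node$kind != "function")
        stop("evaluateNeuron expects a function node")
    if (length(childOutputs) != length(node$weights))
        stop("arity mismatch: node expects ", length(node$weights),
             " children, got ", length(childOutputs))
    complexElliot(node$w0 + sum(node$weights * childOutputs), node$a, node$r)
}

#' Evaluate a tree on encoded inputs
#'
#' Post-order (children before parent, left to right) evaluation of the whole
#' tree; terminals \code{z_i} emit row \code{i} of the input matrix. All time
#' columns are evaluated in one pass through the compiled kernel.
#'
#' @param tree a \code{\link{CVFNTree}}.
#' @param z complex matrix with \code{nInputs} rows (one column per time
#'   point), or a complex vector for a single time point.
#' @return complex vector with one entry per column of \code{z}.
#' @export
evaluateTree <- function(tree, z) {
    if (is.null(dim(z))) z <- matrix(z, ncol = 1L)
    if (nrow(z) != tree@nInputs)
        stop("input matrix must have one row per tree input")
    storage.mode(z) <- "complex"
    fl <- .flattenStructure(tree@root)
    out <- cvfntEvalCpp(fl$kind, fl$arity, fl$input, fl$par, fl$a, fl$r, z)
    if (ncol(z) == 1L) out[[1L]] else out
}

#' Encode a real-valued design as complex tree inputs
#'
#' Real expression data carry no imaginary part, so the default \code{real}
#' scheme embeds them on the real axis (\code{z = x + 0i}). The alternative
#' \code{phase} scheme maps values in [0,1] onto the upper unit half-circle,
#' \code{z = cos(pi x) + i sin(pi x)}, in the spirit of circular
#' complex-valued encodings; it requires min-max-normalised data.
#'
#' @param design a \code{\link{DelayedDesign}}.
#' @param scheme \code{"real"} or \code{"phase"}.
#' @return complex matrix, regulators in rows.
#' @export
encodeInputs <- function(design, scheme = c("real", "phase")) {
    scheme <- match.arg(scheme)
    x <- design@inputs
    if (scheme == "real") {
        z <- x + 0i
    } else {
        if (any(x < 0 | x > 1))
            stop("phase encoding requires values in [0, 1]; ",
                 "normalise with mode 'minmax' first")
        z <- complex(real = cospi(x), imaginary = sinpi(x))
        dim(z) <- dim(x)
    }
    z
}

#' Real-valued predictions of a tree over a design
#'
#' Evaluates the tree on the encoded design inputs, one output per time point
#' of the common window, and reads a real prediction off the complex root
#' output: its real part by default (preserves sign and ordering against the
#' real target), or its modulus.
#'
#' @param tree a \code{\link{CVFNTree}}.
#' @param design a \code{\link{DelayedDesign}}.
#' @param scheme input encoding, see \code{\link{encodeInputs}}.
#' @param readout \code{"real"} or \code{"modulus"}.
#' @return numeric vector of length \code{m_eff}.
#' @export
predictReal <- function(tree, design, scheme = c("real", "phase"),
                        readout = c("real", "modulus")) {
    readout <- match.arg(readout)
    out <- evaluateTree(tree, encodeInputs(design, scheme))
    if (readout == "real") Re(out) else Mod(out)
}

## ---- tree utilities ------------------------------------------------------

#' Tree depth and size
#'
#' Depth counts node levels (a lone terminal has depth 1); size counts nodes.
#'
#' @param tree a \code{\link{CVFNTree}}.
#' @return an integer.
#' @export
treeDepth <- function(tree) .nodeDepth(tree@root)

.nodeDepth <- function(node) {
    if (node$kind == "terminal") return(1L)
    1L + max(vapply(node$children, .nodeDepth, integer(1L)))
}

#' @rdname treeDepth
#' @export
treeSize <- function(tree) .nodeCount(tree@root)

.nodeCount <- function(node) {
    if (node$kind == "terminal") return(1L)
    1L + sum(vapply(node$children, .nodeCount, integer(1L)))
}

#' Terminal input indices used by a tree
#'
#' @param tree a \code{\link{CVFNTree}}.
#' @return sorted unique integer vector of 1-based input indices.
#' @export
treeTerminals <- function(tree) sort(unique(.termIdx(tree@root)))

.termIdx <- function(node) {
    if (node$kind == "terminal") return(node$input)
    unlist(lapply(node$children, .termIdx))
}

formatTree <- function(node) {
    if (node$kind == "terminal") return(paste0("z", node$input))
    paste0("+", length(node$children), "(",
           paste(vapply(node$children, formatTree, ""), collapse = ", "), ")")
}

## Prefix-order flattening for the compiled evaluator: kind (0 terminal,
## 1 function), arity, 0-based input index, and per-function-node parameters
## w1..wn, w0 (complex) with a, r alongside.
.flattenStructure <- function(root) {
    kind <- integer(); arity <- integer(); input <- integer()
    par <- complex(); a <- numeric(); r <- numeric()
    walk <- function(node) {
        if (node$kind == "terminal") {
            kind <<- c(kind, 0L); arity <<- c(arity, 0L)
            input <<- c(input, node$input - 1L)
        } else {
            kind <<- c(kind, 1L)
            arity <<- c(arity, length(node$children))
            input <<- c(input, -1L)
            par <<- c(par, node$weights, node$w0)
            a <<- c(a, node$a); r <<- c(r, node$r)
            for (ch in node$children) walk(ch)
        }
        invisible(NULL)
    }
    walk(root)
    list(kind = kind, arity = arity, input = input, par = par, a = a, r = r)
}

## ---- random tree generation ---------------------------------------------

.randomNodeParams <- function(n) {
    list(weights = complex(real = stats::runif(n, -1, 1),
                           imaginary = stats::runif(n, -1, 1)),
         w0 = complex(real = stats::runif(1, -1, 1),
                      imaginary = stats::runif(1, -1, 1)),
         a = stats::runif(1, 0.1, 2), r = stats::runif(1, 0.1, 2))
}

.growNode <- function(nInputs, depthLeft, functionSet, pFunction) {
    if (depthLeft <= 1L || stats::runif(1) > pFunction)
        return(list(kind = "terminal",
                    input = sample.int(nInputs, 1L)))
    n <- functionSet[sample.int(length(functionSet), 1L)]
    p <- .randomNodeParams(n)
    children <- lapply(seq_len(n), function(i)
        .growNode(nInputs, depthLeft - 1L, functionSet, pFunction))
    list(kind = "function", weights = p$weights, w0 = p$w0,
         a = p$a, r = p$r, children = children)
}

#' Generate a random tree by the grow method
#'
#' Nodes are drawn top-down: below the depth bound a function node is chosen
#' with probability \code{pFunction} (arity uniform over
#' \code{functionSet}), otherwise a terminal with a uniform input index.
#' Weight and threshold components are Uniform(-1, 1); activation parameters
#' are Uniform(0.1, 2). Consumes the current R random stream.
#'
#' @param nInputs number of available terminals.
#' @param maxDepth depth bound.
#' @param functionSet integer vector of admissible arities.
#' @param pFunction probability of growing a function node when allowed.
#' @return a \code{\link{CVFNTree}}.
#' @export
randomTree <- function(nInputs, maxDepth = 4L, functionSet = c(2L, 3L),
                       pFunction = 0.7) {
    CVFNTree(.growNode(nInputs, maxDepth, functionSet, pFunction),
             nInputs = nInputs, maxDepth = maxDepth)
}

## ---- serialization -------------------------------------------------------

.nodeToRecord <- function(node) {
    if (node$kind == "terminal")
        return(list(kind = "terminal", input = node$input))
    list(kind = "function",
         weights = lapply(node$weights, function(w) c(Re(w), Im(w))),
         w0 = c(Re(node$w0), Im(node$w0)),
         a = node$a, r = node$r,
         children = lapply(node$children, .nodeToRecord))
}

.recordToNode <- function(rec) {
    if (rec$kind == "terminal")
        return(list(kind = "terminal", input = as.integer(rec$input)))
    ws <- vapply(rec$weights, function(w)
        complex(real = w[[1L]], imaginary = w[[2L]]), complex(1L))
    list(kind = "function", weights = ws,
         w0 = complex(real = rec$w0[[1L]], imaginary = rec$w0[[2L]]),
         a = as.numeric(rec$a), r = as.numeric(rec$r),
         children = lapply(rec$children, .recordToNode))
}

#' Save / load a tree as JSON text
#'
#' Nodes are stored in prefix order as nested records with complex numbers as
#' \code{[re, im]} pairs; the format carries a version tag. Round-tripping is
#' exact up to double-precision printing (17 significant digits are written).
#'
#' @param tree a \code{\link{CVFNTree}}.
#' @param path file path.
#' @return \code{loadTree} returns the reconstructed \code{CVFNTree};
#'   \code{saveTree} returns \code{path} invisibly.
#' @export
saveTree <- function(tree, path) {
    obj <- list(format = "tdgrn-cvfnt", version = 1L,
                nInputs = tree@nInputs, maxDepth = tree@maxDepth,
                root = .nodeToRecord(tree@root))
    writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA), path)
    invisible(path)
}

#' @rdname saveTree
#' @export
loadTree <- function(path) {
    obj <- tryCatch(jsonlite::fromJSON(readLines(path),
                                       simplifyVector = FALSE),
                    error = function(e)
                        stop("not a tdgrn tree file: ", path, call. = FALSE))
    if (!is.list(obj) || is.null(obj$format) || obj$format != "tdgrn-cvfnt")
        stop("not a tdgrn tree file: ", path)
    CVFNTree(.recordToNode(obj$root), nInputs = as.integer(obj$nInputs),
             maxDepth = as.integer(obj$maxDepth))
}
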