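#' Optimizer settings
#'
#' Constants of the evolutionary structure search and of the embedded
#' bat-algorithm parameter optimisation. Defaults are sized for the short
#' (tens of time points, 2--3 candidate inputs) per-target problems this
#' package addresses, where small populations converge in seconds; every
#' constant is overridable.
#'
#' @param popSize population size (>= 4).
#' @param maxGenerations structure-search generations.
#' @param crossoverProb,mutationProb per-offspring operator probabilities.
#' @param tournamentSize tournament size for selection (lower RMSE wins).
#' @param paramOptEvery generations between parameter-optimisation phases.
#' @param paramOptFraction fraction of the population (best individuals)
#'   sent to the bat optimizer at each phase.
#' @param targetRmse early-stopping threshold on the training RMSE
#'   (the model is declared found below it).
#' @param parsimony selection-fitness penalty per tree node. Selection,
#'   elitism and best-model tracking minimise
#'   \code{RMSE + parsimony * size + inputPenalty * (distinct inputs - 1)},
#'   so a subtree survives only when it buys more training error than it
#'   costs — the usual genetic-programming bloat control. Set both
#'   penalties to 0 to select on raw RMSE alone.
#' @param inputPenalty selection-fitness penalty per distinct input gene
#'   beyond the first. Because every input used by the final tree is
#'   reported as a regulator of the target, this is a regulator-sparsity
#'   pressure: an extra candidate gene enters the model (and hence the
#'   network) only when it explains clearly more of the target than chance
#'   overfitting would.
#' @param maxDepth tree depth bound; \code{functionSet} admissible arities.
#' @param functionSet integer vector of neuron arities.
#' @param seed stream seed used by \code{\link{fitTargetModel}}.
#' @param bat bat-algorithm settings, see \code{\link{batConfig}}.
#' @return a validated named list.
#' @export
optimizerConfig <- function(popSize = 30, maxGenerations = 40,
                            crossoverProb = 0.7, mutationProb = 0.3,
                            tournamentSize = 3, paramOptEvery = 5,
                            paramOptFraction = 0.2, targetRmse = 1e-3,
                            parsimony = 0.002, inputPenalty = 0.01,
                            maxDepth = 4, functionSet = c(2L, 3L),
                            seed = 1L, bat = batConfig()) {
    cfg <- list(popSize = as.integer(popSize),
                maxGenerations = as.integer(maxGenerations),
                crossoverProb = crossoverProb, mutationProb = mutationProb,
                tournamentSize = as.integer(tournamentSize),
                paramOptEvery = as.integer(paramOptEvery),
                paramOptFraction = paramOptFraction,
                targetRmse = targetRmse, parsimony = parsimony,
                inputPenalty = inputPenalty,
                maxDepth = as.integer(maxDepth),
                functionSet = as.integer(functionSet),
                seed = as.integer(seed), bat = bat)
    stopifnot(cfg$popSize >= 4L,
              cfg$maxGenerations >= 1L,
              cfg$crossoverProb >= 0, cfg$crossoverProb <= 1,
              cfg$mutationProb >= 0, cfg$mutationProb <= 1,
              cfg$tournamentSize >= 1L,
              cfg$paramOptEvery >= 1L,
              cfg$paramOptFraction > 0, cfg$paramOptFraction <= 1,
              cfg$targetRmse >= 0, cfg$parsimony >= 0,
              cfg$inputPenalty >= 0,
              all(cfg$functionSet >= 2L))
    cfg
}

#' Bat-algorithm settings
#'
#' Canonical frequency-tuned bat updates: each bat carries a velocity driven
#' by a random frequency in \code{[fMin, fMax]}, a loudness that decays
#' geometrically (factor \code{alpha}) on every accepted move, and a pulse
#' rate that grows as \code{pulse0 * (1 - exp(-gamma * t))}, gating a local
#' random walk around the best-known position.
#'
#' @param nBats number of bats; \code{nIters} iterations.
#' @param nIters number of iterations (0 is a no-op).
#' @param fMin,fMax frequency range.
#' @param loudness0 initial loudness; \code{pulse0} asymptotic pulse rate.
#' @param pulse0 asymptotic pulse rate.
#' @param alpha,gamma decay/growth rates in (0, 1).
#' @return a validated named list.
#' @export
batConfig <- function(nBats = 20, nIters = 40, fMin = 0, fMax = 2,
                      loudness0 = 0.9, pulse0 = 0.5,
                      alpha = 0.9, gamma = 0.9) {
    cfg <- list(nBats = as.integer(nBats), nIters = as.integer(nIters),
                fMin = fMin, fMax = fMax, loudness0 = loudness0,
                pulse0 = pulse0, alpha = alpha, gamma = gamma)
    stopifnot(cfg$nBats >= 1L, cfg$nIters >= 0L, cfg$fMin <= cfg$fMax,
              cfg$alpha > 0, cfg$alpha < 1, cfg$gamma > 0, cfg$gamma < 1)
    cfg
}

#' Root mean squared error
#'
#' @param actual,predicted numeric vectors of equal length.
#' @return non-negative scalar.
#' @export
rmse <- function(actual, predicted) {
    if (length(actual) != length(predicted))
        stop("actual and predicted must have equal length")
    sqrt(mean((actual - predicted)^2))
}

## Fitness of one tree against an encoded design (compiled kernel).
.treeRmse <- function(tree, z, target, useReal = TRUE) {
    fl <- .flattenStructure(tree@root)
    cvfntRmseCpp(fl$kind, fl$arity, fl$input, fl$par, fl$a, fl$r,
                 z, target, useReal)
}

#' Initialise a random population of trees
#'
#' \code{popSize} trees via the grow method within the configured depth
#' bound; weight components Uniform(-1, 1). Consumes the current R random
#' stream, so a preceding \code{set.seed} makes the population reproducible.
#'
#' @param config an \code{\link{optimizerConfig}} list.
#' @param nInputs number of terminals available.
#' @return list of \code{\link{CVFNTree}} objects.
#' @export
initPopulation <- function(config, nInputs) {
    lapply(seq_len(config$popSize), function(i)
        randomTree(nInputs, config$maxDepth, config$functionSet))
}

## ---- structure operators -------------------------------------------------

.nodePaths <- function(node, path = integer()) {
    if (node$kind == "terminal") return(list(path))
    c(list(path), unlist(lapply(seq_along(node$children), function(i)
        .nodePaths(node$children[[i]], c(path, i))), recursive = FALSE))
}

.getSubtree <- function(node, path) {
    for (i in path) node <- node$children[[i]]
    node
}

.setSubtree <- function(node, path, sub) {
    if (!length(path)) return(sub)
    node$children[[path[1L]]] <-
        .setSubtree(node$children[[path[1L]]], path[-1L], sub)
    node
}

## Replace any function node sitting at the depth bound by a random terminal.
.pruneDepth <- function(node, depthLeft, nInputs) {
    if (node$kind == "terminal") return(node)
    if (depthLeft <= 1L)
        return(list(kind = "terminal", input = sample.int(nInputs, 1L)))
    node$children <- lapply(node$children, .pruneDepth,
                            depthLeft = depthLeft - 1L, nInputs = nInputs)
    node
}

.tournament <- function(fitnesses, k) {
    idx <- sample.int(length(fitnesses), min(k, length(fitnesses)))
    idx[which.min(fitnesses[idx])]
}

.mutateTree <- function(tree, config) {
    root <- tree@root
    paths <- .nodePaths(root)
    op <- sample.int(3L, 1L)
    if (op == 1L) {                     # replace a random subtree
        p <- paths[[sample.int(length(paths), 1L)]]
        depthLeft <- tree@maxDepth - length(p)
        sub <- .growNode(tree@nInputs, max(1L, depthLeft), config$functionSet,
                         0.7)
        root <- .setSubtree(root, p, sub)
    } else if (op == 2L) {              # re-point one terminal
        isTerm <- vapply(paths, function(p)
            .getSubtree(root, p)$kind == "terminal", logical(1L))
        p <- paths[isTerm][[sample.int(sum(isTerm), 1L)]]
        node <- .getSubtree(root, p)
        node$input <- sample.int(tree@nInputs, 1L)
        root <- .setSubtree(root, p, node)
    } else {                            # regenerate one node's parameters
        isFun <- vapply(paths, function(p)
            .getSubtree(root, p)$kind == "function", logical(1L))
        if (any(isFun)) {
            p <- paths[isFun][[sample.int(sum(isFun), 1L)]]
            node <- .getSubtree(root, p)
            np <- .randomNodeParams(length(node$children))
            node[c("weights", "w0", "a", "r")] <- np
            root <- .setSubtree(root, p, node)
        } else {                        # lone terminal: re-point it instead
            root$input <- sample.int(tree@nInputs, 1L)
        }
    }
    CVFNTree(.pruneDepth(root, tree@maxDepth, tree@nInputs),
             tree@nInputs, tree@maxDepth)
}

.crossoverTrees <- function(a, b, config) {
    pa <- .nodePaths(a@root)[[sample.int(length(.nodePaths(a@root)), 1L)]]
    pbAll <- .nodePaths(b@root)
    pb <- pbAll[[sample.int(length(pbAll), 1L)]]
    root <- .setSubtree(a@root, pa, .getSubtree(b@root, pb))
    CVFNTree(.pruneDepth(root, a@maxDepth, a@nInputs),
             a@nInputs, a@maxDepth)
}

#' One generation of evolutionary structure search
#'
#' Tournament selection (lower RMSE wins), subtree-exchange crossover with
#' probability \code{crossoverProb}, then mutation with probability
#' \code{mutationProb} choosing uniformly among subtree replacement,
#' terminal re-pointing and single-node parameter regeneration. The best
#' individual is copied unchanged (elitism); offspring that would exceed the
#' depth bound are pruned at the bound by substituting a random terminal.
#'
#' @param population list of \code{\link{CVFNTree}}.
#' @param fitnesses numeric fitness vector parallel to \code{population}
#'   (raw or parsimony-penalised RMSE; lower is better).
#' @param config an \code{\link{optimizerConfig}} list.
#' @return a list of trees of the same length.
#' @export
evolveStructure <- function(population, fitnesses, config) {
    stopifnot(length(population) == length(fitnesses))
    n <- length(population)
    elite <- population[[which.min(fitnesses)]]
    offspring <- vector("list", n)
    offspring[[1L]] <- elite
    for (i in seq.int(2L, n)) {
        child <- population[[.tournament(fitnesses, config$tournamentSize)]]
        if (stats::runif(1) < config$crossoverProb) {
            mate <- population[[.tournament(fitnesses, config$tournamentSize)]]
            child <- .crossoverTrees(child, mate, config)
        }
        if (stats::runif(1) < config$mutationProb)
            child <- .mutateTree(child, config)
        offspring[[i]] <- child
    }
    offspring
}

## ---- parameter vector bridge ---------------------------------------------

#' Pack / unpack tree parameters as a real vector
#'
#' Deterministic prefix-order packing, per function node:
#' \code{Re w1, Im w1, ..., Re wn, Im wn, Re w0, Im w0, a, r} (so a lone
#' \code{+2} node packs to length 8). \code{unflattenParams} is the exact
#' inverse on the vector, except that \code{a} and \code{r} are clamped from
#' below at 1e-3 to keep the activation well defined.
#'
#' @param tree a \code{\link{CVFNTree}}.
#' @return \code{flattenParams}: numeric vector (length 0 for a lone
#'   terminal); \code{unflattenParams}: the tree carrying the new values.
#' @export
flattenParams <- function(tree) {
    fl <- .flattenStructure(tree@root)
    out <- numeric(0)
    p <- 1L
    fn <- which(fl$kind == 1L)
    for (k in seq_along(fn)) {
        n <- fl$arity[fn[k]]
        seg <- fl$par[seq.int(p, p + n)]    # w1..wn, w0
        p <- p + n + 1L
        out <- c(out, as.numeric(rbind(Re(seg), Im(seg))),
                 fl$a[k], fl$r[k])
    }
    out
}

#' @rdname flattenParams
#' @param params numeric vector from \code{flattenParams} (same structure).
#' @export
unflattenParams <- function(tree, params) {
    res <- .consumeParams(tree@root, params, 1L)
    if (res$pos != length(params) + 1L)
        stop("parameter vector has wrong length: expected ",
             res$pos - 1L, ", got ", length(params))
    CVFNTree(res$node, tree@nInputs, tree@maxDepth)
}

.consumeParams <- function(node, v, pos) {
    if (node$kind == "terminal") return(list(node = node, pos = pos))
    n <- length(node$children)
    need <- 2L * (n + 1L) + 2L
    if (pos + need - 1L > length(v))
        stop("parameter vector has wrong length")
    cx <- v[seq.int(pos, pos + 2L * (n + 1L) - 1L)]
    re <- cx[c(TRUE, FALSE)]; im <- cx[c(FALSE, TRUE)]
    node$weights <- complex(real = re[seq_len(n)],
                            imaginary = im[seq_len(n)])
    node$w0 <- complex(real = re[n + 1L], imaginary = im[n + 1L])
    node$a <- max(v[pos + need - 2L], 1e-3)
    node$r <- max(v[pos + need - 1L], 1e-3)
    pos <- pos + need
    for (i in seq_len(n)) {
        res <- .consumeParams(node$children[[i]], v, pos)
        node$children[[i]] <- res$node
        pos <- res$pos
    }
    list(node = node, pos = pos)
}

## Positions of the complex/activation components inside the flat parameter
## vector, precomputed once per tree structure so the bat search maps a
## candidate vector onto the kernel's (par, a, r) arrays with three indexing
## operations (hot path).
.paramIndexMap <- function(fl) {
    reIdx <- integer(); imIdx <- integer()
    aIdx <- integer(); rIdx <- integer()
    q <- 1L
    for (n in fl$arity[fl$kind == 1L]) {
        reIdx <- c(reIdx, seq.int(q, q + 2L * n, by = 2L))
        imIdx <- c(imIdx, seq.int(q + 1L, q + 2L * n + 1L, by = 2L))
        aIdx <- c(aIdx, q + 2L * (n + 1L))
        rIdx <- c(rIdx, q + 2L * (n + 1L) + 1L)
        q <- q + 2L * (n + 1L) + 2L
    }
    list(re = reIdx, im = imIdx, a = aIdx, r = rIdx)
}

.paramsFromVector <- function(fl, v, map = .paramIndexMap(fl)) {
    list(par = complex(real = v[map$re], imaginary = v[map$im]),
         a = pmax(v[map$a], 1e-3), r = pmax(v[map$r], 1e-3))
}

#' Bat-algorithm parameter optimisation of one tree
#'
#' Runs \code{nBats} bats for \code{nIters} iterations over the flattened
#' parameter vector of the tree (structure fixed). Each iteration a bat picks
#' a frequency \code{f = fMin + (fMax - fMin) * beta}, updates its velocity
#' toward the best-known position (clamped to \eqn{\pm}1 per coordinate, the
#' data being normalised), moves, and with probability \code{1 - pulse}
#' substitutes a local walk around the best position scaled by the mean
#' loudness. A candidate replaces the bat's position only when it improves it
#' and a loudness-gated coin accepts; accepted moves decay the bat's loudness
#' and raise its pulse rate. The best-found parameters are returned, so the
#' result is never worse than the input tree. Consumes the R random stream.
#'
#' @param tree a \code{\link{CVFNTree}} (trees without function nodes are
#'   returned unchanged).
#' @param design a \code{\link{DelayedDesign}}.
#' @param scheme input encoding, see \code{\link{encodeInputs}}.
#' @param bat a \code{\link{batConfig}} list.
#' @param readout real readout of the complex output ("real" or "modulus").
#' @return list with elements \code{tree}, \code{rmse} and
#'   \code{evaluations}.
#' @export
batOptimize <- function(tree, design, scheme = "real", bat = batConfig(),
                        readout = "real") {
    z <- encodeInputs(design, scheme)
    target <- design@target
    useReal <- match.arg(readout, c("real", "modulus")) == "real"
    fl <- .flattenStructure(tree@root)
    map <- .paramIndexMap(fl)
    x0 <- flattenParams(tree)
    d <- length(x0)
    evalCount <- 0L
    fit <- function(v) {
        evalCount <<- evalCount + 1L
        cvfntRmseCpp(fl$kind, fl$arity, fl$input,
                     complex(real = v[map$re], imaginary = v[map$im]),
                     pmax(v[map$a], 1e-3), pmax(v[map$r], 1e-3),
                     z, target, useReal)
    }
    f0 <- .treeRmse(tree, z, target, useReal)
    if (bat$nIters == 0L || d == 0L)
        return(list(tree = tree, rmse = f0, evaluations = evalCount))

    nb <- bat$nBats
    X <- matrix(stats::runif(nb * d, -0.5, 0.5), nb, d) + rep(x0, each = nb)
    X[1L, ] <- x0
    V <- matrix(0, nb, d)
    fx <- apply(X, 1L, fit)
    A <- rep(bat$loudness0, nb)
    pulse <- rep(0, nb)
    best <- which.min(fx)
    xStar <- X[best, ]; fStar <- fx[best]
    if (f0 < fStar) { xStar <- x0; fStar <- f0 }

    for (t in seq_len(bat$nIters)) {
        meanA <- mean(A)
        for (i in seq_len(nb)) {
            f <- bat$fMin + (bat$fMax - bat$fMin) * stats::runif(1)
            V[i, ] <- pmin(pmax(V[i, ] + (X[i, ] - xStar) * f, -1), 1)
            cand <- X[i, ] + V[i, ]
            if (stats::runif(1) > pulse[i])
                cand <- xStar + stats::runif(d, -1, 1) * meanA
            fc <- fit(cand)
            if (fc < fx[i] && stats::runif(1) < A[i]) {
                X[i, ] <- cand; fx[i] <- fc
                A[i] <- bat$alpha * A[i]
                pulse[i] <- bat$pulse0 * (1 - exp(-bat$gamma * t))
            }
            if (fc < fStar) { xStar <- cand; fStar <- fc }
        }
    }
    list(tree = unflattenParams(tree, xStar), rmse = fStar,
         evaluations = evalCount)
}

#' Fit a tree model to one target gene's design
#'
#' Alternates evolutionary structure search (one generation of
#' \code{\link{evolveStructure}} per iteration) with bat-algorithm parameter
#' optimisation applied to the best \code{paramOptFraction} of the population
#' every \code{paramOptEvery} generations. Individuals compete on the
#' parsimony-penalised fitness \code{RMSE + parsimony * size} (see
#' \code{\link{optimizerConfig}}); the best-so-far penalised fitness is
#' monotone non-increasing by elitism. Stops when the best model's raw RMSE
#' reaches \code{targetRmse} or after \code{maxGenerations}. Fully
#' reproducible from \code{seed}.
#'
#' @param design a \code{\link{DelayedDesign}}.
#' @param scheme input encoding, see \code{\link{encodeInputs}}.
#' @param config an \code{\link{optimizerConfig}} list.
#' @param seed integer seed for this fit (defaults to \code{config$seed}).
#' @param readout real readout of the complex output.
#' @return list with \code{tree} (best \code{\link{CVFNTree}}), \code{rmse}
#'   (raw training RMSE of that tree), and \code{trace} (data.frame with
#'   generation, best_rmse, best_fitness, evaluations).
#' @export
fitTargetModel <- function(design, scheme = "real",
                           config = optimizerConfig(),
                           seed = config$seed, readout = "real") {
    set.seed(as.integer(seed))
    z <- encodeInputs(design, scheme)
    target <- design@target
    useReal <- match.arg(readout, c("real", "modulus")) == "real"
    nInputs <- nrow(design@inputs)
    evals <- 0L
    evalPop <- function(pop) {
        evals <<- evals + length(pop)
        vapply(pop, .treeRmse, numeric(1L), z = z, target = target,
               useReal = useReal)
    }
    penalty <- function(pop)
        config$parsimony * vapply(pop, treeSize, integer(1L)) +
        config$inputPenalty *
            pmax(vapply(pop, function(tr) length(treeTerminals(tr)),
                        integer(1L)) - 1L, 0L)
    pop <- initPopulation(config, nInputs)
    fx <- evalPop(pop)
    px <- fx + penalty(pop)
    bestIdx <- which.min(px)
    bestTree <- pop[[bestIdx]]
    bestRmse <- fx[bestIdx]; bestFit <- px[bestIdx]
    trace <- data.frame(generation = 0L, best_rmse = bestRmse,
                        best_fitness = bestFit, evaluations = evals)
    for (gen in seq_len(config$maxGenerations)) {
        if (bestRmse <= config$targetRmse) break
        pop <- evolveStructure(pop, px, config)
        fx <- evalPop(pop)
        px <- fx + penalty(pop)
        if (gen %% config$paramOptEvery == 0L) {
            k <- max(1L, ceiling(config$paramOptFraction * length(pop)))
            top <- order(px)[seq_len(k)]
            for (i in top) {
                res <- batOptimize(pop[[i]], design, scheme, config$bat,
                                   readout)
                evals <- evals + res$evaluations
                pop[[i]] <- res$tree
                fx[i] <- res$rmse
                px[i] <- res$rmse +
                    config$parsimony * treeSize(res$tree) +
                    config$inputPenalty *
                        max(length(treeTerminals(res$tree)) - 1L, 0L)
            }
        }
        gi <- which.min(px)
        if (px[gi] < bestFit) {
            bestFit <- px[gi]; bestRmse <- fx[gi]; bestTree <- pop[[gi]]
        }
        trace <- rbind(trace, data.frame(generation = gen,
                                         best_rmse = bestRmse,
                                         best_fitness = bestFit,
                                         evaluations = evals))
    }
    list(tree = bestTree, rmse = bestRmse, trace = trace)
}
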