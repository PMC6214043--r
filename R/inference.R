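## Derived per-target / per-run seed streams: fixed large-prime offsets from
## the root seed, reduced modulo 2^31 - 1 so every derived seed stays a valid
## R integer. Targets (and runs) get independent streams while the whole run
## remains reproducible from the single root seed.
.deriveSeed <- function(seed, index, stream = 1L) {
    p <- c(104729, 15485863, 32452843)[stream]
    as.integer((as.numeric(seed) + p * as.numeric(index)) %% 2147483647)
}

#' Read regulators off a fitted tree
#'
#' Every distinct terminal input index appearing in the tree denotes one
#' regulator of the target (duplicated uses collapse to one edge), annotated
#' with the candidate's correlation-optimal lag.
#'
#' @param tree a fitted \code{\link{CVFNTree}}.
#' @param candidateSet the \code{\link{CandidateSet}} whose rows the tree
#'   terminals index into.
#' @return data.frame with columns \code{regulator} (gene index) and
#'   \code{lag}, one row per distinct terminal.
#' @export
extractRegulators <- function(tree, candidateSet) {
    used <- treeTerminals(tree)
    cd <- candidates(candidateSet)
    if (any(used > nrow(cd)))
        stop("tree terminals index beyond the candidate set")
    data.frame(regulator = cd$regulator[used], lag = cd$lag[used])
}

#' Infer a time-delayed regulatory network
#'
#' Full pipeline, one target gene at a time: normalise, shortlist candidate
#' regulators by hybrid rank aggregation, build the lag-aligned design, fit a
#' complex-valued flexible neural tree, and read the regulators off the
#' fitted tree. The per-target fits use seed streams derived from the root
#' seed, so the whole run is reproducible while targets stay independent.
#'
#' @param es an \code{\link{ExpressionSeries}}.
#' @param config a \code{\link{RunConfig}}.
#' @return an \code{\link{InferredNetwork}}; edge scores are the per-target
#'   training RMSEs.
#' @export
inferNetwork <- function(es, config = RunConfig()) {
    esn <- normalizeExpression(es, config@normalization)
    ids <- geneIds(esn)
    edgeList <- vector("list", nGenes(esn))
    for (k in seq_len(nGenes(esn))) {
        res <- tryCatch({
            cs <- hybridRank(esn, k, config)
            design <- buildDelayedDesign(esn, cs)
            fit <- fitTargetModel(design, scheme = config@encoding,
                                  config = config@optimizer,
                                  seed = .deriveSeed(config@seed, k))
            regs <- extractRegulators(fit$tree, cs)
            data.frame(regulator = ids[regs$regulator], target = ids[k],
                       lag = regs$lag, score = fit$rmse)
        }, error = function(e)
            stop("target gene '", ids[k], "': ", conditionMessage(e),
                 call. = FALSE))
        edgeList[[k]] <- res
    }
    InferredNetwork(do.call(rbind, edgeList))
}

#' Directed-edge confusion counts against a gold standard
#'
#' Over all ordered gene pairs (distinct pairs always; identical pairs only
#' when \code{includeSelf}): TP are inferred-and-gold, FP inferred-only, FN
#' gold-only, TN neither. Matching is direction-sensitive and ignores lags
#' (gold standards are unlagged). With \code{includeSelf = TRUE} a gold
#' self-loop counts as a false negative, since self-loops are never inferred.
#'
#' @param inferred an \code{\link{InferredNetwork}}.
#' @param gold a \code{\link{GoldNetwork}}.
#' @param geneIds character vector of all gene identifiers (the pair
#'   universe).
#' @param includeSelf whether identical pairs enter the universe.
#' @return named integer vector with elements TP, FP, FN, TN.
#' @export
confusionCounts <- function(inferred, gold, geneIds, includeSelf = FALSE) {
    iEdges <- edges(inferred); gEdges <- edges(gold)
    unknown <- setdiff(c(iEdges$regulator, iEdges$target,
                         gEdges$regulator, gEdges$target), geneIds)
    if (length(unknown))
        stop("gene id(s) not in the pair universe: ",
             paste(unknown, collapse = ", "))
    key <- function(r, t) paste(r, t, sep = "\r")
    universe <- expand.grid(regulator = geneIds, target = geneIds,
                            stringsAsFactors = FALSE)
    if (!includeSelf)
        universe <- universe[universe$regulator != universe$target, ]
    uKey <- key(universe$regulator, universe$target)
    inInf <- uKey %in% key(iEdges$regulator, iEdges$target)
    inGold <- uKey %in% key(gEdges$regulator, gEdges$target)
    c(TP = sum(inInf & inGold), FP = sum(inInf & !inGold),
      FN = sum(!inInf & inGold), TN = sum(!inInf & !inGold))
}

#' Network evaluation metrics from confusion counts
#'
#' Sensitivity TP/(TP+FN), precision TP/(TP+FP), specificity TN/(FP+TN), and
#' the F-score as the harmonic mean of sensitivity and precision. Any 0/0
#' denominator yields 0 for that metric, with a warning (the convention only
#' matters for degenerate inputs).
#'
#' @param counts named vector with elements TP, FP, FN, TN (as returned by
#'   \code{\link{confusionCounts}}).
#' @return named numeric vector: sensitivity, precision, specificity,
#'   f_score.
#' @export
networkMetrics <- function(counts) {
    tp <- counts[["TP"]]; fp <- counts[["FP"]]
    fn <- counts[["FN"]]; tn <- counts[["TN"]]
    safe <- function(num, den, what) {
        if (den == 0) {
            warning(what, " undefined (0/0); set to 0")
            return(0)
        }
        num / den
    }
    sens <- safe(tp, tp + fn, "sensitivity")
    prec <- safe(tp, tp + fp, "precision")
    spec <- safe(tn, fp + tn, "specificity")
    f <- if (sens + prec == 0) {
        warning("f_score undefined (0/0); set to 0")
        0
    } else 2 * sens * prec / (sens + prec)
    c(sensitivity = sens, precision = prec, specificity = spec, f_score = f)
}

#' Evaluate an inferred network against a gold standard
#'
#' Convenience wrapper: confusion counts plus metrics in one record.
#'
#' @inheritParams confusionCounts
#' @return list with elements \code{counts} and \code{metrics}.
#' @export
evaluateNetwork <- function(inferred, gold, geneIds, includeSelf = FALSE) {
    counts <- confusionCounts(inferred, gold, geneIds, includeSelf)
    list(counts = counts, metrics = networkMetrics(counts))
}

#' Repeated-run performance summary
#'
#' Runs the full inference \code{nRuns} times with seeds derived from the
#' root seed, evaluates each inferred network against the gold standard, and
#' reports the mean and standard deviation of each metric plus the hit ratio
#' (fraction of runs attaining the best observed F-score).
#'
#' @param es an \code{\link{ExpressionSeries}}.
#' @param gold a \code{\link{GoldNetwork}}.
#' @param config a \code{\link{RunConfig}}; \code{nRuns} controls the number
#'   of repeats.
#' @param includeSelf confusion-universe convention, see
#'   \code{\link{confusionCounts}}.
#' @return list with \code{per_run} (data.frame of metrics by run),
#'   \code{mean}, \code{sd} (named vectors) and \code{hit_ratio}.
#' @export
multiRunSummary <- function(es, gold, config = RunConfig(),
                            includeSelf = FALSE) {
    runs <- lapply(seq_len(config@nRuns), function(r) {
        cfg <- config
        cfg@seed <- .deriveSeed(config@seed, r, stream = 2L)
        net <- inferNetwork(es, cfg)
        m <- networkMetrics(confusionCounts(net, gold, geneIds(es),
                                            includeSelf))
        data.frame(run = r, seed = cfg@seed, t(m))
    })
    perRun <- do.call(rbind, runs)
    met <- c("sensitivity", "precision", "specificity", "f_score")
    mm <- vapply(perRun[met], mean, numeric(1L))
    ss <- vapply(perRun[met], function(v)
        if (length(v) > 1L) stats::sd(v) else 0, numeric(1L))
    hit <- mean(perRun$f_score >= max(perRun$f_score) - 1e-12)
    list(per_run = perRun, mean = mm, sd = ss, hit_ratio = hit)
}
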