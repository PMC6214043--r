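#' Time-delayed mutual information
#'
#' Mutual information (natural log) between the regulator series \code{x} and
#' the target series \code{y} shifted by \code{tau} sampling intervals:
#' \code{x[k]} is paired with \code{y[k + tau]} over the overlapping window of
#' length \code{m - tau}, and MI is estimated from an equal-width 2-D
#' histogram on that window. The regulator leads: lag \code{tau} means the
#' regulator at time \code{t} influences the target at \code{t + tau}. At
#' \code{tau = 0} this is symmetric ordinary MI.
#'
#' @param x,y numeric series of equal length.
#' @param tau non-negative integer lag.
#' @param bins number of equal-width bins per axis; when NULL,
#'   \code{max(2, floor(sqrt(overlap length)))}.
#' @return non-negative MI estimate in nats.
#' @export
tdmi <- function(x, y, tau = 0L, bins = NULL) {
    ov <- .lagOverlap(x, y, tau)
    n <- length(ov$x)
    if (n < 3L)
        stop("overlap after lag shift is shorter than 3 points")
    if (is.null(bins)) bins <- max(2L, floor(sqrt(n)))
    bins <- as.integer(bins)
    if (bins < 2L) stop("bins must be at least 2")
    bx <- .equalWidthBin(ov$x, bins)
    by <- .equalWidthBin(ov$y, bins)
    joint <- table(factor(bx, levels = seq_len(bins)),
                   factor(by, levels = seq_len(bins)))
    .miFromCounts(joint)
}

.lagOverlap <- function(x, y, tau) {
    stopifnot(length(x) == length(y))
    tau <- as.integer(tau)
    if (tau < 0L) stop("tau must be non-negative")
    m <- length(x)
    if (tau >= m) stop("tau must be smaller than the series length")
    list(x = x[seq_len(m - tau)], y = y[seq_len(m - tau) + tau])
}

.equalWidthBin <- function(v, bins) {
    rng <- range(v)
    if (rng[1L] == rng[2L]) return(rep(1L, length(v)))
    brk <- seq(rng[1L], rng[2L], length.out = bins + 1L)
    pmin(pmax(findInterval(v, brk, rightmost.closed = TRUE), 1L), bins)
}

.miFromCounts <- function(joint) {
    n <- sum(joint)
    p <- joint / n
    px <- rowSums(p); py <- colSums(p)
    ok <- p > 0
    sum(p[ok] * log(p[ok] / outer(px, py)[ok]))
}

#' Time-delayed maximal information coefficient
#'
#' MIC of the lag-shifted pair: the regulator leads by \code{tau}, and on the
#' overlap of length \code{N} the normalised mutual information
#' \code{I(G)/log(min(nx, ny))} is maximised over 2-D grids \code{G} with
#' \code{nx * ny <= B(N)} cells, \code{B(N) = max(4, floor(N^0.6))},
#' \code{nx, ny >= 2}. For each grid size one axis gets an equal-frequency
#' partition and the other axis's cut points are chosen optimally by dynamic
#' programming; both orientations are tried and the maximum taken. A
#' noiseless monotone functional relation attains 1; a constant series
#' returns 0.
#'
#' @inheritParams tdmi
#' @return MIC value in [0, 1].
#' @export
tdmic <- function(x, y, tau = 0L) {
    ov <- .lagOverlap(x, y, tau)
    n <- length(ov$x)
    if (n < 4L) stop("overlap after lag shift is shorter than 4 points")
    if (length(unique(ov$x)) < 2L || length(unique(ov$y)) < 2L)
        return(0)
    B <- max(4L, as.integer(floor(n^0.6)))
    micCpp(ov$x, ov$y, B)
}

#' Time-delayed Pearson correlation
#'
#' Pearson correlation between \code{x[k]} and \code{y[k + tau]}, with means
#' and variances computed on the same overlapping window. A zero-variance
#' overlap returns 0 with a warning.
#'
#' @inheritParams tdmi
#' @return correlation in [-1, 1].
#' @export
tdcc <- function(x, y, tau = 0L) {
    ov <- .lagOverlap(x, y, tau)
    if (length(ov$x) < 3L)
        stop("overlap after lag shift is shorter than 3 points")
    if (stats::sd(ov$x) == 0 || stats::sd(ov$y) == 0) {
        warning("zero variance on the lag overlap; correlation set to 0")
        return(0)
    }
    stats::cor(ov$x, ov$y)
}

#' Correlation-optimal lag between a regulator and a target
#'
#' Scans \code{tau} over \code{[minLag, tauMax]} and returns the lag
#' maximising the absolute time-delayed correlation, ties broken toward the
#' smallest lag.
#'
#' @param x regulator series; \code{y} target series.
#' @param y numeric series.
#' @param minLag,tauMax inclusive lag bounds (sampling intervals).
#' @return list with elements \code{lag} and \code{value} (the signed
#'   correlation at that lag).
#' @export
bestLag <- function(x, y, minLag = 0L, tauMax = 6L) {
    taus <- seq.int(as.integer(minLag), as.integer(tauMax))
    vals <- vapply(taus, function(tau)
        suppressWarnings(tdcc(x, y, tau)), numeric(1L))
    i <- which.max(abs(vals))
    list(lag = taus[i], value = vals[i])
}

## Lag-maximised scores of every non-target gene against one target.
.pairScores <- function(values, targetIndex, config) {
    taus <- seq.int(config@minLag, config@tauMax)
    regs <- setdiff(seq_len(nrow(values)), targetIndex)
    yt <- values[targetIndex, ]
    res <- lapply(regs, function(i) {
        xr <- values[i, ]
        mi <- max(vapply(taus, function(tau) tdmi(xr, yt, tau), numeric(1L)))
        mic <- max(vapply(taus, function(tau) tdmic(xr, yt, tau), numeric(1L)))
        bl <- bestLag(xr, yt, config@minLag, config@tauMax)
        data.frame(regulator = i, tdmi = mi, tdmic = mic,
                   tdcc = abs(bl$value), lag = bl$lag)
    })
    do.call(rbind, res)
}

.rankDesc <- function(v) {
    ## rank 1 = strongest; ties share the smallest rank
    rank(-v, ties.method = "min")
}

#' Hybrid rank-aggregated candidate selection for one target gene
#'
#' For every non-target gene the three association measures are maximised
#' over the lag window; genes are ranked per measure (rank 1 = strongest,
#' ties share the smallest rank) and the three ranks are summed. The \code{L}
#' genes with the smallest aggregated rank form the candidate set, each
#' annotated with its correlation-optimal lag. Ties on the aggregated rank
#' are broken by larger MIC, then larger MI, then smaller gene index; the
#' chain is fixed so runs are deterministic. A gene never selects itself.
#'
#' @param es an \code{\link{ExpressionSeries}} (normalise first; see
#'   \code{\link{normalizeExpression}}).
#' @param targetIndex index of the target gene.
#' @param config a \code{\link{RunConfig}}; uses \code{minLag},
#'   \code{tauMax} and \code{L}.
#' @return a \code{\link{CandidateSet}}.
#' @export
hybridRank <- function(es, targetIndex, config = RunConfig()) {
    values <- exprValues(es)
    targetIndex <- as.integer(targetIndex)
    stopifnot(targetIndex >= 1L, targetIndex <= nrow(values))
    if (config@L > nrow(values) - 1L)
        stop("L must not exceed the number of non-target genes")
    sc <- .pairScores(values, targetIndex, config)
    agg <- .rankDesc(sc$tdmi) + .rankDesc(sc$tdmic) + .rankDesc(sc$tdcc)
    sc$agg_rank <- agg
    ord <- order(agg, -sc$tdmic, -sc$tdmi, sc$regulator)
    sel <- sc[ord[seq_len(config@L)],
              c("regulator", "agg_rank", "lag", "tdmi", "tdmic", "tdcc")]
    rownames(sel) <- NULL
    new("CandidateSet", targetIndex = targetIndex, candidates = sel)
}

#' Full association score table
#'
#' Lag-maximised TDMI, MIC and |correlation| plus per-measure and aggregated
#' ranks for every ordered (regulator, target) pair; the table behind the
#' candidate selection, suitable for export.
#'
#' @inheritParams hybridRank
#' @return data.frame with one row per ordered gene pair.
#' @export
scoreTable <- function(es, config = RunConfig()) {
    values <- exprValues(es)
    ids <- geneIds(es)
    out <- lapply(seq_len(nrow(values)), function(k) {
        sc <- .pairScores(values, k, config)
        data.frame(target = ids[k], regulator = ids[sc$regulator],
                   tdmi = sc$tdmi, tdmic = sc$tdmic, tdcc = sc$tdcc,
                   lag = sc$lag,
                   rank_tdmi = .rankDesc(sc$tdmi),
                   rank_tdmic = .rankDesc(sc$tdmic),
                   rank_tdcc = .rankDesc(sc$tdcc),
                   agg_rank = .rankDesc(sc$tdmi) + .rankDesc(sc$tdmic) +
                       .rankDesc(sc$tdcc))
    })
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
}
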