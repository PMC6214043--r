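#' Generate a random ground-truth regulatory network
#'
#' Draws \code{nEdges} distinct directed non-self edges uniformly over the
#' ordered gene pairs, with lags uniform on \code{1..tauMax} and weights
#' uniform on \eqn{[-1, -0.2] \cup [0.2, 1]} — bounded away from zero so
#' every true edge has a detectable effect. Genes with no incoming edge are
#' drivers and evolve autonomously during simulation. Defaults emulate the
#' scale of the short benchmark time courses this tool targets (half a dozen
#' genes, a few dozen equally spaced points).
#'
#' @param nGenes number of genes; \code{nEdges} number of edges.
#' @param nEdges number of directed edges (at most \code{nGenes*(nGenes-1)}).
#' @param tauMax largest lag assigned to an edge.
#' @param m emitted time points per gene.
#' @param noiseSd observation noise s.d. added to regulated genes.
#' @param link regulatory link: \code{"elliot"} (default, the same
#'   saturating activation family the tree model uses, with a = 1, r = 1),
#'   \code{"linear"} (identity) or \code{"sigmoid"} (logistic, slope 4).
#' @param seed generator seed.
#' @return a \code{\link{SyntheticSpec}}.
#' @export
generateNetwork <- function(nGenes, nEdges, tauMax = 6L, m = 50L,
                            noiseSd = 0.05, link = "elliot", seed = 1L) {
    nGenes <- as.integer(nGenes); nEdges <- as.integer(nEdges)
    maxEdges <- nGenes * (nGenes - 1L)
    if (nEdges > maxEdges)
        stop("at most ", maxEdges, " distinct non-self directed edges exist")
    set.seed(as.integer(seed))
    pairs <- expand.grid(regulator = seq_len(nGenes),
                         target = seq_len(nGenes))
    pairs <- pairs[pairs$regulator != pairs$target, ]
    pick <- pairs[sample.int(nrow(pairs), nEdges), , drop = FALSE]
    edges <- data.frame(
        regulator = as.integer(pick$regulator),
        target = as.integer(pick$target),
        lag = if (nEdges) sample.int(as.integer(tauMax), nEdges,
                                     replace = TRUE) else integer(),
        weight = stats::runif(nEdges, 0.2, 1) *
            sample(c(-1, 1), nEdges, replace = TRUE))
    rownames(edges) <- NULL
    new("SyntheticSpec", nGenes = nGenes, edges = edges,
        noiseSd = noiseSd, m = as.integer(m), link = link,
        tauMax = as.integer(tauMax), seed = as.integer(seed))
}

## Centred links: the regulatory drive is u = sum w * (x_reg - 0.5) and the
## regulated level is 0.5 + link(u), so positive and negative weights act
## symmetrically about mid-range and the series stay inside [0,1] instead of
## saturating at the clip boundary. All links are odd with unit slope at 0,
## so a single weight-1 linear edge reproduces its regulator exactly.
.linkFun <- function(link) {
    switch(link,
           linear = identity,
           elliot = function(u) u / (1 + abs(u)),
           sigmoid = function(u) 1 / (1 + exp(-4 * u)) - 0.5)
}

.clip01 <- function(v) pmin(pmax(v, 0), 1)

#' Simulate an expression time course from a synthetic network
#'
#' Driver genes (in-degree 0) evolve as smooth AR(1)-plus-sinusoid processes
#' kept in [0, 1]; each regulated gene at time t is
#' \code{0.5 + link(sum w * (x_reg(t - lag) - 0.5))} plus Gaussian
#' observation noise, clipped to [0, 1] — the regulatory drive is centred at
#' mid-range so positive and negative weights act symmetrically and the
#' series do not saturate at the clip boundary; all links have unit slope at
#' the origin, so a single weight-1 linear edge reproduces its regulator as
#' an exact lagged copy. The first \code{tauMax}
#' points of every gene are seeded from driver-style dynamics and this
#' burn-in segment is discarded, so all lagged influences are strictly in
#' the past and the emitted \code{m} points obey the stated dynamics
#' exactly. Deterministic given the spec's seed.
#'
#' @param spec a \code{\link{SyntheticSpec}}.
#' @return list with elements \code{expression} (an
#'   \code{\link{ExpressionSeries}} with gene ids \code{g1..gN}) and
#'   \code{gold} (the exact \code{\link{GoldNetwork}}; lag annotations are
#'   available in \code{spec@edges}).
#' @export
simulateExpression <- function(spec) {
    set.seed(spec@seed)
    n <- spec@nGenes
    tot <- spec@tauMax + spec@m
    lf <- .linkFun(spec@link)
    ## Driver process: persistent AR(1) pulled toward a slow sinusoidal
    ## trend. Periods are drawn well beyond the lag search window so that
    ## two independent drivers stay distinguishable under lag shifts --
    ## trend periods comparable to the lag window would alias and make
    ## direction unidentifiable even in principle.
    period <- stats::runif(n, 30, 80)
    phase <- stats::runif(n, 0, 2 * pi)
    amp <- stats::runif(n, 0.05, 0.2)
    innov <- matrix(stats::rnorm(n * tot, 0, 0.05), n, tot)
    obs <- matrix(stats::rnorm(n * tot, 0, spec@noiseSd), n, tot)
    sinTrack <- function(g, t) 0.5 + amp[g] * sin(2 * pi * t / period[g] +
                                                  phase[g])
    driver <- matrix(0, n, tot)
    for (g in seq_len(n)) {
        driver[g, 1L] <- .clip01(sinTrack(g, 1) + innov[g, 1L])
        for (t in seq.int(2L, tot))
            driver[g, t] <- .clip01(0.85 * driver[g, t - 1L] +
                                    0.15 * sinTrack(g, t) + innov[g, t])
    }
    regulated <- seq_len(n) %in% spec@edges$target
    x <- driver
    if (any(regulated) && tot > spec@tauMax) {
        byTarget <- split(spec@edges, spec@edges$target)
        for (t in seq.int(spec@tauMax + 1L, tot)) {
            for (tg in names(byTarget)) {
                e <- byTarget[[tg]]
                g <- as.integer(tg)
                u <- sum(e$weight * (x[cbind(e$regulator, t - e$lag)] - 0.5))
                x[g, t] <- .clip01(0.5 + lf(u) + obs[g, t])
            }
        }
    }
    emit <- x[, seq.int(spec@tauMax + 1L, tot), drop = FALSE]
    rownames(emit) <- paste0("g", seq_len(n))
    colnames(emit) <- paste0("t", seq_len(spec@m))
    ids <- rownames(emit)
    list(expression = ExpressionSeries(emit),
         gold = GoldNetwork(regulator = ids[spec@edges$regulator],
                            target = ids[spec@edges$target]))
}
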