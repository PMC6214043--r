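# Independent reference implementations used as oracles. These are written
# against the definitions directly (explicit loops, no shared code with the
# package internals) and are only run at small sizes.

# Joint-histogram mutual information by explicit double loop over bins.
bruteMI <- function(x, y, bins) {
    bin1 <- function(v) {
        rng <- range(v)
        if (rng[1] == rng[2]) return(rep(1L, length(v)))
        b <- floor((v - rng[1]) / (rng[2] - rng[1]) * bins) + 1L
        pmin(b, bins)
    }
    bx <- bin1(x); by <- bin1(y)
    n <- length(x)
    mi <- 0
    for (i in seq_len(bins)) {
        for (j in seq_len(bins)) {
            pij <- sum(bx == i & by == j) / n
            if (pij > 0) {
                pi. <- sum(bx == i) / n
                p.j <- sum(by == j) / n
                mi <- mi + pij * log(pij / (pi. * p.j))
            }
        }
    }
    mi
}

# Equal-frequency class labels with ties sharing the earlier label
# (the convention the MIC estimator documents).
eqFreqLabels <- function(y, ny) {
    n <- length(y)
    ord <- order(y)
    lab <- integer(n)
    for (k in seq_len(n)) {
        b <- floor((k - 1) * ny / n)
        if (k > 1 && y[ord[k]] == y[ord[k - 1]]) b <- lab[ord[k - 1]]
        lab[ord[k]] <- b
    }
    match(lab, sort(unique(lab)))
}

# Exhaustive MIC oracle: enumerates every admissible x-cut combination for
# every grid size (both orientations); feasible only for small N.
oracleMIC <- function(x, y, B) {
    oriented <- function(x, y) {
        n <- length(x)
        ord <- order(x)
        xs <- x[ord]
        validCut <- which(xs[-n] != xs[-1])   # cut after these positions
        best <- 0
        for (ny in 2:floor(B / 2)) {
            q <- eqFreqLabels(y, ny)[ord]
            if (length(unique(q)) < 2) next
            for (nx in 2:floor(B / ny)) {
                if (length(validCut) < nx - 1) next
                for (cuts in asplit(utils::combn(validCut, nx - 1), 2)) {
                    xb <- findInterval(seq_len(n) - 1, cuts) + 1L
                    tab <- table(xb, q)
                    p <- tab / n
                    px <- rowSums(p); py <- colSums(p)
                    mi <- 0
                    for (i in seq_len(nrow(p))) for (j in seq_len(ncol(p)))
                        if (p[i, j] > 0)
                            mi <- mi + p[i, j] *
                                log(p[i, j] / (px[i] * py[j]))
                    best <- max(best, mi / log(min(nx, ny)))
                }
            }
        }
        best
    }
    min(max(oriented(x, y), oriented(y, x)), 1)
}

# Independent recursive tree evaluator for one input column (complex vector
# with one entry per terminal index).
oracleEvalNode <- function(node, zcol) {
    if (node$kind == "terminal") return(zcol[node$input])
    net <- node$w0
    for (i in seq_along(node$children))
        net <- net + node$weights[i] * oracleEvalNode(node$children[[i]], zcol)
    net / (node$a + Mod(net) / node$r)
}

oracleEvalTree <- function(tree, z) {
    if (is.null(dim(z))) z <- matrix(z, ncol = 1)
    vapply(seq_len(ncol(z)), function(t) oracleEvalNode(tree@root, z[, t]),
           complex(1))
}

# Small well-formed expression fixture written to a temp file.
writeToyExpression <- function(path, sep = "\t") {
    lines <- c(paste(c("gene", paste0("t", 1:5)), collapse = sep),
               paste(c("gA", 1, 2, 3, 4, 5), collapse = sep),
               paste(c("gB", 5, 4, 3, 2, 1), collapse = sep),
               paste(c("gC", 2, 2, 2, 2, 2), collapse = sep))
    writeLines(lines, path)
    path
}
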