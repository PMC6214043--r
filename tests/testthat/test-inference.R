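terminalNode <- function(i) list(kind = "terminal", input = as.integer(i))

twoTermTree <- function(i, j, nInputs = 2L)
    CVFNTree(list(kind = "function", weights = c(1 + 0i, 1 + 0i),
                  w0 = 0 + 0i, a = 1, r = 1,
                  children = list(terminalNode(i), terminalNode(j))),
             nInputs)

toyCandidates <- function(target = 4L, regs = c(1L, 2L), lags = c(2L, 0L))
    new("CandidateSet", targetIndex = target,
        candidates = data.frame(regulator = regs,
                                agg_rank = seq_along(regs) + 2L,
                                lag = lags))

test_that("regulators are read off tree terminals with duplicates
           collapsed", {
    cs <- toyCandidates()
    one <- CVFNTree(terminalNode(1L), 2L)
    e1 <- extractRegulators(one, cs)
    expect_equal(nrow(e1), 1L)
    expect_equal(e1$regulator, 1L)
    expect_equal(e1$lag, 2L)
    # z1 used three times, z2 once -> exactly two edges
    deep <- CVFNTree(list(kind = "function",
                          weights = c(1 + 0i, 1 + 0i), w0 = 0 + 0i,
                          a = 1, r = 1,
                          children = list(twoTermTree(1L, 1L)@root,
                                          twoTermTree(1L, 2L)@root)),
                     2L)
    e2 <- extractRegulators(deep, cs)
    expect_equal(nrow(e2), 2L)
    expect_setequal(e2$regulator, c(1L, 2L))
})

test_that("confusion counting reproduces the 6-gene benchmark bookkeeping", {
    ids <- c("uvrD", "lexA", "umuD", "recA", "uvrA", "polB")
    # gold: 7 edges including one self-loop on the hub repressor
    gold <- GoldNetwork(
        regulator = c("lexA", "lexA", "lexA", "lexA", "lexA", "recA", "lexA"),
        target = c("uvrD", "umuD", "recA", "uvrA", "polB", "lexA", "lexA"))
    expect_equal(sum(edges(gold)$self_loop), 1L)
    # inferred: exactly the six non-self gold edges
    g <- edges(gold)[!edges(gold)$self_loop, ]
    inf <- InferredNetwork(data.frame(regulator = g$regulator,
                                      target = g$target,
                                      lag = 1L, score = 0.1))
    cc <- confusionCounts(inf, gold, ids, includeSelf = TRUE)
    expect_equal(cc, c(TP = 6L, FP = 0L, FN = 1L, TN = 29L))
    m <- networkMetrics(cc)
    expect_equal(m[["sensitivity"]], 6 / 7, tolerance = 1e-3)
    expect_equal(m[["precision"]], 1)
    expect_equal(m[["f_score"]], 0.923, tolerance = 1e-3)

    # empty inferred network: all gold edges become false negatives
    cc0 <- confusionCounts(InferredNetwork(), gold, ids, includeSelf = TRUE)
    expect_equal(cc0[["TP"]], 0L)
    expect_equal(cc0[["FP"]], 0L)
    expect_equal(cc0[["FN"]], 7L)

    # saturated inferred network: no FN or TN left (non-self universe)
    all <- expand.grid(regulator = ids, target = ids,
                       stringsAsFactors = FALSE)
    all <- all[all$regulator != all$target, ]
    ccA <- confusionCounts(InferredNetwork(data.frame(all, lag = 0L,
                                                      score = 0)),
                           gold, ids, includeSelf = FALSE)
    expect_equal(ccA[["FN"]], 0L)
    expect_equal(ccA[["TN"]], 0L)
    # counts always sum to the pair universe
    expect_equal(sum(cc), 36L)
    expect_equal(sum(ccA), 30L)

    expect_error(confusionCounts(inf, gold, ids[-2]), "lexA")
})

test_that("metrics match the four defining ratios on random count tuples", {
    set.seed(90)
    for (rep in 1:100) {
        cc <- c(TP = sample(0:20, 1), FP = sample(0:20, 1),
                FN = sample(0:20, 1), TN = sample(0:20, 1))
        m <- suppressWarnings(networkMetrics(cc))
        expWhen <- function(num, den) if (den == 0) 0 else num / den
        expect_equal(m[["sensitivity"]], expWhen(cc[["TP"]],
                                                 cc[["TP"]] + cc[["FN"]]))
        expect_equal(m[["precision"]], expWhen(cc[["TP"]],
                                               cc[["TP"]] + cc[["FP"]]))
        expect_equal(m[["specificity"]], expWhen(cc[["TN"]],
                                                 cc[["FP"]] + cc[["TN"]]))
        sp <- m[["sensitivity"]] + m[["precision"]]
        expect_equal(m[["f_score"]], if (sp == 0) 0 else
            2 * m[["sensitivity"]] * m[["precision"]] / sp)
    }
    w <- capture_warnings(m0 <- networkMetrics(c(TP = 0L, FP = 0L, FN = 0L,
                                                 TN = 5L)))
    expect_true(length(w) >= 1 && all(grepl("0/0", w)))
    expect_equal(unname(m0[c("sensitivity", "precision", "f_score")]),
                 c(0, 0, 0))
})

test_that("network inference is deterministic, capped at n*L edges, and
           recovers a noiseless lagged driver", {
    cfg <- RunConfig(tauMax = 6, L = 2, seed = 77,
                     optimizer = optimizerConfig(
                         popSize = 16, maxGenerations = 12, paramOptEvery = 4,
                         bat = batConfig(nBats = 8, nIters = 10)))
    set.seed(14)
    A <- cumsum(rnorm(30)); A <- (A - min(A)) / diff(range(A))
    B <- c(rep(0.5, 2), Re(complexElliot(A + 0i, 1, 1)))[1:30]
    mat <- rbind(A = A, B = B, C = runif(30), D = runif(30))
    es <- ExpressionSeries(mat)
    net1 <- inferNetwork(es, cfg)
    net2 <- inferNetwork(es, cfg)
    expect_identical(edges(net1), edges(net2))
    expect_lte(nrow(edges(net1)), 4 * 2)
    e <- edges(net1)
    ab <- e[e$regulator == "A" & e$target == "B", ]
    expect_equal(nrow(ab), 1L)
    expect_equal(ab$lag, 2L)
})

test_that("the lagged-driver edge is recovered across almost all seeds", {
    set.seed(300)
    hits <- 0L
    for (s in 1:20) {
        A <- cumsum(rnorm(30)); A <- (A - min(A)) / diff(range(A))
        B <- c(rep(0.5, 2), Re(complexElliot(A + 0i, 1, 1)))[1:30] +
            rnorm(30, sd = 0.01)
        mat <- rbind(A = A, B = B, C = runif(30), D = runif(30))
        cs <- hybridRank(normalizeExpression(ExpressionSeries(mat),
                                             "minmax"), 2L,
                         RunConfig(tauMax = 6, L = 2))
        if (1L %in% candidates(cs)$regulator &&
            candidates(cs)$lag[match(1L, candidates(cs)$regulator)] == 2L)
            hits <- hits + 1L
    }
    expect_gte(hits, 18L)
})

test_that("multi-run summaries degenerate correctly for a single run and
           reproduce bit-for-bit", {
    set.seed(21)
    mat <- matrix(runif(4 * 25), 4, 25,
                  dimnames = list(paste0("g", 1:4), NULL))
    es <- ExpressionSeries(mat)
    gold <- GoldNetwork(regulator = c("g1", "g2"), target = c("g2", "g3"))
    cfg <- RunConfig(seed = 5, nRuns = 1,
                     optimizer = optimizerConfig(
                         popSize = 12, maxGenerations = 6, paramOptEvery = 3,
                         bat = batConfig(nBats = 6, nIters = 6)))
    # random data can yield zero-TP runs; the 0/0 -> 0 convention warns
    s1 <- suppressWarnings(multiRunSummary(es, gold, cfg))
    expect_equal(unname(s1$sd), rep(0, 4))
    expect_equal(s1$hit_ratio, 1)
    cfg@nRuns <- 3L
    s3a <- suppressWarnings(multiRunSummary(es, gold, cfg))
    s3b <- suppressWarnings(multiRunSummary(es, gold, cfg))
    expect_identical(s3a, s3b)
    expect_equal(nrow(s3a$per_run), 3L)
    expect_true(s3a$hit_ratio >= 1 / 3)
})
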