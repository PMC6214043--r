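lightConfig <- function(...) {
    args <- list(popSize = 20, maxGenerations = 25, paramOptEvery = 3,
                 bat = batConfig(nBats = 12, nIters = 20))
    dots <- list(...)
    args[names(dots)] <- dots
    do.call(optimizerConfig, args)
}

# design with a known linear law: target = 0.5 reg1 + 0.5 reg2
linearDesign <- function(m = 30) {
    r1 <- runif(m); r2 <- runif(m)
    new("DelayedDesign", targetIndex = 3L, regulatorIndices = c(1L, 2L),
        lags = c(0L, 0L), inputs = rbind(r1, r2),
        target = 0.5 * r1 + 0.5 * r2)
}

identityDesign <- function(m = 30) {
    x <- runif(m)
    new("DelayedDesign", targetIndex = 2L, regulatorIndices = 1L,
        lags = 0L, inputs = matrix(x, 1), target = x)
}

test_that("rmse follows its closed forms", {
    expect_equal(rmse(c(1, 2, 3), c(1, 2, 3)), 0)
    expect_equal(rmse(c(0, 0), c(1, 1)), 1)
    expect_equal(rmse(c(0, 0, 0), c(3, 0, 0)), sqrt(3))
    expect_error(rmse(1:3, 1:4), "equal length")
})

test_that("population initialisation is valid and seed-reproducible", {
    cfg <- lightConfig()
    set.seed(12); pop1 <- initPopulation(cfg, 3L)
    set.seed(12); pop2 <- initPopulation(cfg, 3L)
    expect_length(pop1, cfg$popSize)
    expect_identical(pop1, pop2)
    for (tr in pop1) {
        expect_true(validObject(tr))
        expect_lte(treeDepth(tr), cfg$maxDepth)
        expect_true(all(treeTerminals(tr) %in% 1:3))
    }
})

test_that("with operators off, offspring are copies of selected parents", {
    cfg <- lightConfig(crossoverProb = 0, mutationProb = 0)
    set.seed(31)
    pop <- initPopulation(cfg, 2L)
    fx <- runif(length(pop))
    nxt <- evolveStructure(pop, fx, cfg)
    expect_length(nxt, length(pop))
    expect_identical(nxt[[1]], pop[[which.min(fx)]])     # elite slot
    for (child in nxt)
        expect_true(any(vapply(pop, identical, logical(1), child)))
})

test_that("offspring satisfy depth and arity invariants across generations", {
    cfg <- lightConfig()
    set.seed(55)
    pop <- initPopulation(cfg, 3L)
    for (gen in 1:40) {
        pop <- evolveStructure(pop, runif(length(pop)), cfg)
        for (tr in pop) {
            expect_true(validObject(tr))
            expect_lte(treeDepth(tr), cfg$maxDepth)
        }
    }
})

test_that("parameter vectors round-trip through flatten/unflatten", {
    set.seed(63)
    # lone +2 node: 2 complex weights + threshold + (a, r) = 8 reals
    tr <- CVFNTree(list(kind = "function",
                        weights = c(0.3 + 1i, -0.2 - 0.5i), w0 = 0.1 + 0.2i,
                        a = 0.7, r = 1.3,
                        children = list(list(kind = "terminal", input = 1L),
                                        list(kind = "terminal", input = 2L))),
                   2L)
    v <- flattenParams(tr)
    expect_length(v, 8L)
    expect_equal(v, c(0.3, 1, -0.2, -0.5, 0.1, 0.2, 0.7, 1.3))
    expect_equal(flattenParams(unflattenParams(tr, v)), v)
    # random trees: round trip is the identity on the vector
    for (rep in 1:10) {
        tr <- randomTree(3L)
        v <- flattenParams(tr)
        expect_equal(flattenParams(unflattenParams(tr, v)), v)
    }
    expect_error(unflattenParams(tr, c(v, 1)), "length")
    # lone terminals carry no parameters
    expect_length(flattenParams(CVFNTree(list(kind = "terminal",
                                              input = 1L), 1L)), 0L)
})

test_that("unflatten clamps activation parameters away from zero", {
    tr <- CVFNTree(list(kind = "function",
                        weights = c(1 + 0i, 1 + 0i), w0 = 0 + 0i,
                        a = 1, r = 1,
                        children = list(list(kind = "terminal", input = 1L),
                                        list(kind = "terminal", input = 2L))),
                   2L)
    v <- flattenParams(tr)
    v[7:8] <- c(-5, 0)
    tr2 <- unflattenParams(tr, v)
    expect_equal(tr2@root$a, 1e-3)
    expect_equal(tr2@root$r, 1e-3)
})

test_that("zero-iteration bat search is a no-op", {
    set.seed(71)
    tr <- randomTree(2L)
    d <- linearDesign()
    res <- batOptimize(tr, d, bat = batConfig(nIters = 0))
    expect_identical(res$tree, tr)
})

test_that("bat search improves a linear-law design in nearly all seeds and
           never returns a worse tree", {
    wins <- 0L
    for (s in 1:20) {
        set.seed(s)
        d <- linearDesign()
        tr <- CVFNTree(list(kind = "function",
                            weights = c(0.2 + 0.1i, -0.3 + 0.2i),
                            w0 = 0.1 - 0.1i, a = 1, r = 5,
                            children = list(list(kind = "terminal",
                                                 input = 1L),
                                            list(kind = "terminal",
                                                 input = 2L))),
                       2L)
        pre <- rmse(d@target, predictReal(tr, d))
        res <- batOptimize(tr, d, bat = batConfig(nBats = 12, nIters = 20))
        post <- rmse(d@target, predictReal(res$tree, d))
        expect_lte(post, pre + 1e-12)
        expect_equal(post, res$rmse, tolerance = 1e-12)
        if (post < pre) wins <- wins + 1L
    }
    expect_gte(wins, 18L)
})

test_that("fitting recovers an identity model and is seed-deterministic", {
    hits <- 0L
    for (s in 1:20) {
        set.seed(1000 + s)
        d <- identityDesign()
        fit <- fitTargetModel(d, config = lightConfig(maxGenerations = 30,
                                                      targetRmse = 1e-3),
                              seed = s)
        if (fit$rmse <= 0.05) hits <- hits + 1L
    }
    expect_gte(hits, 18L)

    set.seed(9); d <- identityDesign()
    f1 <- fitTargetModel(d, config = lightConfig(), seed = 4L)
    f2 <- fitTargetModel(d, config = lightConfig(), seed = 4L)
    expect_identical(f1$tree, f2$tree)
    expect_identical(f1$trace, f2$trace)
    # best-so-far penalised fitness is monotone non-increasing
    expect_true(all(diff(f1$trace$best_fitness) <= 0))
    # without parsimony pressure the raw-RMSE trace itself is monotone
    f0 <- fitTargetModel(d, config = lightConfig(parsimony = 0,
                                                 inputPenalty = 0),
                         seed = 4L)
    expect_true(all(diff(f0$trace$best_rmse) <= 0))
})

test_that("fitted predictions recover a known single-neuron generative
           law in most seeds", {
    hits <- 0L
    nSeeds <- 20L
    for (s in 1:nSeeds) {
        set.seed(2000 + s)
        x <- runif(35)
        net <- 0.05 + 0i + (0.9 + 0i) * x
        target <- Re(net / (0.8 + Mod(net) / 1.5))
        d <- new("DelayedDesign", targetIndex = 2L, regulatorIndices = 1L,
                 lags = 0L, inputs = matrix(x, 1), target = target)
        fit <- fitTargetModel(d, config = lightConfig(maxGenerations = 30,
                                                      targetRmse = 0.015),
                              seed = s)
        if (fit$rmse < 0.02) hits <- hits + 1L
    }
    expect_gt(hits, nSeeds / 2)
})
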