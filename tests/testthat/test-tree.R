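singleTerminalTree <- function(i = 1L, nInputs = 2L)
    CVFNTree(list(kind = "terminal", input = as.integer(i)), nInputs)

plusNode <- function(weights, w0 = 0 + 0i, a = 1, r = 1, children)
    list(kind = "function", weights = as.complex(weights),
         w0 = as.complex(w0), a = a, r = r, children = children)

terminal <- function(i) list(kind = "terminal", input = as.integer(i))

test_that("complex Elliot activation has its closed forms and modulus
           bound", {
    expect_equal(complexElliot(0 + 0i, 1, 1), 0 + 0i)
    expect_equal(complexElliot(1 + 0i, 0.5, 2), 1 + 0i)
    expect_equal(complexElliot(0 + 2i, 1, 1), (2 / 3) * 1i)
    set.seed(3)
    net <- complex(real = rnorm(200, sd = 5), imaginary = rnorm(200, sd = 5))
    for (r in c(0.3, 1, 4))
        expect_true(all(Mod(complexElliot(net, runif(1, 0.1, 2), r)) < r))
})

test_that("a flexible neuron combines children per its excitation formula", {
    n0 <- plusNode(c(0 + 0i, 0 + 0i), children = list(terminal(1),
                                                      terminal(2)))
    expect_equal(evaluateNeuron(n0, c(5 + 1i, 2 - 3i)), 0 + 0i)
    # r -> Inf limit: elliot(net) ~ net / a
    n1 <- plusNode(1 + 0i, a = 1, r = 1e6, children = list(terminal(1)))
    expect_equal(evaluateNeuron(n1, 0.3 + 0i), 0.3 + 0i, tolerance = 1e-6)
    # cancellation through opposite inputs
    n2 <- plusNode(c(1 + 0i, 1 + 0i), children = list(terminal(1),
                                                      terminal(2)))
    expect_equal(evaluateNeuron(n2, c(1 + 0i, -1 + 0i)), 0 + 0i)
    expect_error(evaluateNeuron(n2, c(1 + 0i)), "arity mismatch")
})

test_that("tree evaluation is the identity for a lone terminal and matches
           a hand-composed nesting", {
    tr <- singleTerminalTree(2L, 3L)
    z <- c(0.1 + 0.2i, 0.5 - 0.1i, 0.9 + 0i)
    expect_equal(evaluateTree(tr, z), z[2])

    # two-level tree with unit weights, zero thresholds, fixed (a, r)
    inner <- plusNode(c(1 + 0i, 1 + 0i), a = 1, r = 2,
                      children = list(terminal(1), terminal(2)))
    root <- plusNode(c(1 + 0i, 1 + 0i), a = 1, r = 2,
                     children = list(inner, terminal(3)))
    tr2 <- CVFNTree(root, 3L)
    ell <- function(net, a, r) net / (a + Mod(net) / r)
    byHand <- ell(ell(z[1] + z[2], 1, 2) + z[3], 1, 2)
    expect_equal(evaluateTree(tr2, z), byHand, tolerance = 1e-14)

    # swapping siblings with equal weights and equal child values is a no-op
    rootSwap <- plusNode(c(1 + 0i, 1 + 0i), a = 1, r = 2,
                         children = list(terminal(3), inner))
    expect_equal(evaluateTree(CVFNTree(rootSwap, 3L), z),
                 evaluateTree(tr2, z))
})

test_that("compiled evaluation agrees with the recursive oracle on random
           trees", {
    set.seed(500)
    for (rep in 1:200) {
        nIn <- sample(1:4, 1)
        tr <- randomTree(nIn, maxDepth = 4)
        z <- matrix(complex(real = rnorm(nIn * 5), imaginary = rnorm(nIn * 5)),
                    nIn, 5)
        expect_equal(evaluateTree(tr, z), oracleEvalTree(tr, z),
                     tolerance = 1e-12)
    }
})

test_that("input encodings map reals onto the complex plane as documented", {
    d <- new("DelayedDesign", targetIndex = 1L, regulatorIndices = 1L,
             lags = 0L, inputs = matrix(c(0, 0.5, 0.7, 1), 1),
             target = rep(0, 4))
    expect_equal(encodeInputs(d, "real")[1, ], c(0, 0.5, 0.7, 1) + 0i)
    ph <- encodeInputs(d, "phase")[1, ]
    expect_equal(ph[1], 1 + 0i)
    expect_equal(ph[2], 0 + 1i, tolerance = 1e-15)
    expect_equal(Mod(ph), rep(1, 4))
    d@inputs <- matrix(c(-0.2, 0.5, 0.7, 1), 1)
    expect_error(encodeInputs(d, "phase"), "minmax")
})

test_that("predictions are real vectors over the output window and
           deterministic", {
    set.seed(61)
    x <- runif(12)
    d <- new("DelayedDesign", targetIndex = 2L, regulatorIndices = 1L,
             lags = 0L, inputs = matrix(x, 1), target = x)
    idTree <- singleTerminalTree(1L, 1L)
    expect_equal(predictReal(idTree, d), x)
    expect_equal(rmse(d@target, predictReal(idTree, d)), 0)
    tr <- randomTree(1L)
    p1 <- predictReal(tr, d); p2 <- predictReal(tr, d)
    expect_identical(p1, p2)
    expect_length(p1, 12L)
    expect_true(is.numeric(p1))
})

test_that("trees serialize to JSON and back with identical evaluations", {
    set.seed(71)
    for (rep in 1:5) {
        tr <- randomTree(3L)
        f <- withr::local_tempfile(fileext = ".json")
        saveTree(tr, f)
        tr2 <- loadTree(f)
        z <- complex(real = runif(3), imaginary = runif(3))
        expect_equal(evaluateTree(tr2, z), evaluateTree(tr, z))
        expect_equal(treeDepth(tr2), treeDepth(tr))
        expect_equal(treeTerminals(tr2), treeTerminals(tr))
    }
    expect_error(loadTree(writeToyExpression(
        withr::local_tempfile(fileext = ".tsv"))), "tree file")
})

test_that("structural invariants are enforced at construction", {
    expect_error(CVFNTree(terminal(5), nInputs = 2L), "out of range")
    bad <- plusNode(c(1 + 0i), a = 1, r = 1, children = list(terminal(1)))
    expect_error(CVFNTree(bad, 2L), "at least 2 children")
    deep <- plusNode(c(1 + 0i, 1 + 0i), children = list(
        plusNode(c(1 + 0i, 1 + 0i), children = list(terminal(1),
                                                    terminal(2))),
        terminal(1)))
    expect_error(CVFNTree(deep, 2L, maxDepth = 2L), "depth")
})
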