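test_that("acceptance probability follows the Boltzmann rule", {
  expect_equal(acceptProbability(-5, -4, 10), 1)   # improving: always
  expect_equal(acceptProbability(-5, -5, 10), 1)   # equal: always
  expect_equal(acceptProbability(-4, -6, 2), exp(-1))  # deficit = T
  expect_lt(acceptProbability(-4, -1e6, 0.5), 1e-300)  # hopeless move
  expect_error(acceptProbability(-4, -5, 0), "positive")
  expect_error(acceptProbability(-4, -5, -1), "positive")
})

test_that("exchange swaps a child with a grandchild", {
  tree <- toyTreeABC()  # (a,(b,c))
  # swap a with b: b is hoisted, a joins c
  moved <- exchangeMove(tree, 5L, grandchild = 1L)
  expect_equal(hrgnet:::shapeKey(moved), "((a,c),b)")
  # swap a with c
  moved2 <- exchangeMove(tree, 5L, grandchild = 2L)
  expect_equal(hrgnet:::shapeKey(moved2), "((a,b),c)")
  # a node with two leaf children signals a no-op
  expect_null(exchangeMove(tree, 4L))
})

test_that("rotate regroups the three-subtree configuration", {
  tree <- toyTreeABC()
  expect_equal(hrgnet:::shapeKey(rotateMove(tree, 5L, variant = 1L)),
               "((a,b),c)")
  expect_equal(hrgnet:::shapeKey(rotateMove(tree, 5L, variant = 2L)),
               "((a,c),b)")
  expect_null(rotateMove(tree, 4L))
  # an inverse rotate restores the shape (enumerated at N = 3)
  for (v in 1:2) {
    once <- rotateMove(tree, 5L, variant = v)
    back <- c(hrgnet:::shapeKey(rotateMove(once, 5L, variant = 1L)),
              hrgnet:::shapeKey(rotateMove(once, 5L, variant = 2L)))
    expect_true(hrgnet:::shapeKey(tree) %in% back)
  }
})

test_that("undoing an exchange restores the shape and moves preserve leaves", {
  set.seed(81)
  for (rep in 1:10) {
    tree <- randomDendrogram(paste0("g", 1:8))
    s <- sample(9:15, 1)
    # replicate the move's pivot selection so the inverse targets the same
    # three-subtree configuration
    ch <- c(tree@leftChild[s - 8L], tree@rightChild[s - 8L])
    internal <- ch[ch > 8L]
    if (!length(internal)) {
      expect_null(exchangeMove(tree, s))
      next
    }
    ic <- sample(seq_along(internal), 1)
    t <- internal[ic]
    once <- exchangeMove(tree, s, grandchild = sample(1:2, 1),
                         internalChild = ic)
    expect_true(validObject(once))
    expect_setequal(genes(once), genes(tree))
    counts <- subtreeLeafCounts(once)
    expect_equal(sum(counts$L * counts$R), 28)  # shape-independent invariant
    # the swapped subtree always lands at the pivot's left slot, so the
    # inverse is the exchange of the hoisted child with that grandchild
    ch2 <- c(once@leftChild[s - 8L], once@rightChild[s - 8L])
    internal2 <- ch2[ch2 > 8L]
    twice <- exchangeMove(once, s, grandchild = 1L,
                          internalChild = which(internal2 == t))
    expect_equal(hrgnet:::shapeKey(twice), hrgnet:::shapeKey(tree))
  }
})

test_that("exchange and rotate connect the whole shape space", {
  set.seed(91)
  expect_equal(closureShapes(randomDendrogram(letters[1:4])), 15L)
  expect_equal(closureShapes(randomDendrogram(letters[1:5])), 105L)
})

test_that("exhaustive search enumerates (2N-3)!! shapes", {
  ens3 <- toyEnsemble()
  ex3 <- exhaustiveSearch(ens3)
  expect_equal(nrow(ex3$table), 3L)

  set.seed(92)
  ens4 <- randomEnsemble(letters[1:4], ng = 3, p = 0.5)
  ex4 <- exhaustiveSearch(ens4)
  expect_equal(nrow(ex4$table), 15L)
  expect_equal(length(unique(ex4$table$shape)), 15L)

  ens9 <- randomEnsemble(letters[1:9], ng = 2, p = 0.5)
  expect_error(exhaustiveSearch(ens9), "N <= 8")
})

test_that("annealing finds the worked-example optimum with a 2-way tie", {
  ens <- toyEnsemble()
  ex <- exhaustiveSearch(ens)
  target <- log(1 / 4) + 3 * log(3 / 4)
  expect_equal(ex$optimum, target, tolerance = 1e-12)
  expect_length(ex$ties, 2L)
  expect_setequal(vapply(ex$ties, hrgnet:::shapeKey, ""),
                  c("((a,c),b)", "((a,b),c)"))

  fit <- annealHRG(ens, AnnealSchedule(3, tStart = 10, tEnd = 0.1,
                                       nMaxFactor = 200, gamma = 0.9,
                                       seed = 17L))
  expect_equal(fit$objective, target, tolerance = 1e-10)
  expect_true(hrgnet:::shapeKey(hrgTree(fit$model)) %in%
                c("((a,c),b)", "((a,b),c)"))
})

test_that("the best objective in the trace is monotone non-decreasing", {
  set.seed(93)
  ens <- randomEnsemble(paste0("g", 1:6), ng = 10, p = 0.3)
  fit <- annealHRG(ens, AnnealSchedule(6, tStart = 10, tEnd = 0.1,
                                       nMaxFactor = 100, gamma = 0.9,
                                       seed = 5L))
  expect_true(all(diff(fit$trace$objBest) >= 0))
  expect_named(fit$trace, c("epoch", "temperature", "objCurrent", "objBest",
                            "accepted", "noop"))
  expect_true(all(diff(fit$trace$temperature) < 0))
})

test_that("the incremental annealer objective matches a full recompute", {
  set.seed(94)
  for (rep in 1:5) {
    N <- sample(5:9, 1)
    ens <- randomEnsemble(paste0("g", seq_len(N)), ng = 12, p = 0.4)
    fit <- annealHRG(ens, AnnealSchedule(N, tStart = 5, tEnd = 0.5,
                                         nMaxFactor = 100, gamma = 0.8,
                                         seed = rep))
    expect_true(validObject(hrgTree(fit$model)))
    expect_equal(fit$objective, logLikelihood(hrgTree(fit$model), ens),
                 tolerance = 1e-8)
    expect_equal(theta(fit$model), fitTheta(hrgTree(fit$model), ens))
  }
})

test_that("annealing is deterministic given the schedule seed", {
  set.seed(95)
  ens <- randomEnsemble(paste0("g", 1:7), ng = 8, p = 0.3)
  sched <- AnnealSchedule(7, tStart = 10, tEnd = 0.1, nMaxFactor = 100,
                          gamma = 0.9, seed = 123L)
  a <- annealHRG(ens, sched)
  b <- annealHRG(ens, sched)
  expect_identical(writeNewickHRG(a$model), writeNewickHRG(b$model))
  expect_identical(a$trace, b$trace)
})

test_that("degenerate gene sets are handled without search", {
  ensPair <- buildEnsemble(list(
    DirectedNetwork(c("a", "b"), rbind(c("a", "b"))),
    DirectedNetwork(c("a", "b"))))
  fit <- annealHRG(ensPair)
  expect_equal(hrgnet:::shapeKey(hrgTree(fit$model)), "(a,b)")
  expect_equal(theta(fit$model), 0.5)
})
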