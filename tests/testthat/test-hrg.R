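test_that("edge counts aggregate member edges by lowest common ancestor", {
  ens <- toyEnsemble()
  counts <- edgeCounts(toyTreeABC(), ens)
  expect_equal(counts$E[counts$node == 5L], 2)  # pairs {a,b}, {a,c} at the root
  expect_equal(counts$E[counts$node == 4L], 1)  # pair {b,c} at the cherry

  emptyEns <- buildEnsemble(replicate(3, DirectedNetwork(c("a", "b", "c")),
                                      simplify = FALSE))
  expect_true(all(edgeCounts(toyTreeABC(), emptyEns)$E == 0))

  full <- DirectedNetwork(c("a", "b", "c"),
                          rbind(c("a", "b"), c("a", "c"), c("b", "c")))
  fullEns <- buildEnsemble(list(full, full))
  counts <- edgeCounts(toyTreeABC(), fullEns)
  expect_equal(counts$E, 2 * counts$L * counts$R)  # saturation
})

test_that("per-network counts conserve member edge totals", {
  set.seed(31)
  ens <- randomEnsemble(letters[1:6], ng = 8, p = 0.4)
  tree <- randomDendrogram(letters[1:6])
  counts <- edgeCounts(tree, ens, perNetwork = TRUE)
  Eij <- attr(counts, "perNetwork")
  expect_equal(rowSums(Eij), setNames(counts$E, rownames(Eij)))
  memberEdges <- vapply(memberNetworks(ens), function(m) nrow(edges(m)), 1L)
  expect_equal(unname(colSums(Eij)), as.numeric(memberEdges))
})

test_that("theta is the closed-form edge fraction per node", {
  ens <- toyEnsemble()
  th <- fitTheta(toyTreeABC(), ens)
  expect_equal(th, c(0.5, 0.5))  # cherry: 1/(2*1*1), root: 2/(2*1*2)

  emptyEns <- buildEnsemble(replicate(4, DirectedNetwork(c("a", "b", "c")),
                                      simplify = FALSE))
  expect_equal(fitTheta(toyTreeABC(), emptyEns), c(0, 0))

  full <- DirectedNetwork(c("a", "b", "c"),
                          rbind(c("a", "b"), c("a", "c"), c("b", "c")))
  expect_equal(fitTheta(toyTreeABC(), buildEnsemble(list(full, full))), c(1, 1))
})

test_that("log-likelihood matches hand evaluation on the worked ensemble", {
  ens <- toyEnsemble()
  expect_equal(logLikelihood(toyTreeABC(), ens), 6 * log(0.5),
               tolerance = 1e-12)
  expect_equal(logLikelihood(toyTreeBAC(), ens), log(1 / 4) + 3 * log(3 / 4),
               tolerance = 1e-12)

  # perfectly consistent ensemble: every theta in {0, 1}, likelihood 0
  full <- DirectedNetwork(c("a", "b", "c"), rbind(c("b", "c")))
  ensC <- buildEnsemble(list(full, full, full))
  expect_equal(logLikelihood(toyTreeABC(), ensC), 0)
})

test_that("aggregated likelihood equals the per-network double sum", {
  set.seed(41)
  for (rep in 1:5) {
    N <- sample(4:8, 1)
    ens <- randomEnsemble(paste0("g", seq_len(N)), ng = 6, p = 0.4)
    tree <- randomDendrogram(paste0("g", seq_len(N)))
    expect_equal(logLikelihood(tree, ens), bruteLogLik(tree, ens),
                 tolerance = 1e-10)
    expect_lte(logLikelihood(tree, ens), 0)
  }
})

test_that("compiled and R likelihood computations agree", {
  set.seed(43)
  for (rep in 1:5) {
    N <- sample(4:9, 1)
    g <- paste0("g", seq_len(N))
    ens <- randomEnsemble(g, ng = 5, p = 0.3)
    tree <- randomDendrogram(g)
    expect_equal(
      hrgnet:::.hrgLogLikCpp(tree@leftChild, tree@rightChild, tree@root,
                             edgeWeights(ens), nNetworks(ens)),
      logLikelihood(tree, ens), tolerance = 1e-10)
  }
})

test_that("the closed-form theta is a likelihood maximum", {
  set.seed(51)
  eps <- 1e-3
  for (rep in 1:5) {
    ens <- randomEnsemble(paste0("g", 1:6), ng = 10, p = 0.5)
    tree <- randomDendrogram(paste0("g", 1:6))
    th <- fitTheta(tree, ens)
    ll0 <- logLikAtTheta(tree, ens, th)
    expect_equal(ll0, logLikelihood(tree, ens), tolerance = 1e-10)
    for (i in seq_along(th)) {
      for (dir in c(-eps, eps)) {
        th2 <- th
        th2[i] <- min(1 - 1e-9, max(1e-9, th[i] + dir))
        expect_lte(logLikAtTheta(tree, ens, th2), ll0 + 1e-12)
      }
    }
  }
})

test_that("edge probabilities are theta at the LCA and symmetric", {
  model <- HRGModel(toyTreeABC(), c(0.8, 0.5))  # cherry 0.8, root 0.5
  expect_equal(edgeProbability(model, "a", "b"), 0.5)
  expect_equal(edgeProbability(model, "b", "a"), 0.5)
  expect_equal(edgeProbability(model, "b", "c"), 0.8)
  expect_error(edgeProbability(model, "a", "a"), "undefined")

  allOne <- HRGModel(toyTreeABC(), c(1, 1))
  for (pair in list(c("a", "b"), c("a", "c"), c("b", "c"))) {
    expect_equal(edgeProbability(allOne, pair[1], pair[2]), 1)
  }

  set.seed(61)
  tr <- randomDendrogram(paste0("g", 1:7))
  m <- HRGModel(tr, runif(6))
  P <- hierarchyProbabilities(m)
  expect_equal(unname(P), unname(t(P)))
  expect_true(all(is.na(diag(P))))
})

test_that("generative sampling has the model's expected edge count", {
  set.seed(71)
  zero <- HRGModel(toyTreeABC(), c(0, 0))
  expect_equal(nrow(edges(sampleNetwork(zero))), 0L)
  one <- HRGModel(toyTreeABC(), c(1, 1))
  expect_equal(nrow(edges(sampleNetwork(one))), 3L)

  model <- plantedModel16()
  counts <- subtreeLeafCounts(hrgTree(model))
  expected <- sum(counts$L * counts$R * theta(model))
  draws <- 10000L
  tot <- 0L
  for (k in seq_len(draws)) tot <- tot + nrow(edges(sampleNetwork(model)))
  se <- sqrt(sum(counts$L * counts$R * theta(model) * (1 - theta(model))) / draws)
  expect_lt(abs(tot / draws - expected), 3 * se + 1e-9)
})
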