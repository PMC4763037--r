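test_that("undirect symmetrizes and strips self-regulations", {
  net <- DirectedNetwork(c("m", "n"), rbind(c("m", "n")))
  expect_equal(unname(edges(undirect(net))), rbind(c("m", "n")))

  empty <- DirectedNetwork(c("a", "b"))
  expect_equal(nrow(edges(undirect(empty))), 0L)

  net3 <- DirectedNetwork(c("a", "b"),
                          rbind(c("a", "a"), c("a", "b"), c("b", "a")))
  e <- edges(undirect(net3))
  expect_equal(nrow(e), 1L)
  expect_setequal(c(e), c("a", "b"))
})

test_that("symmetrization is direction-blind and idempotent in effect", {
  g <- letters[1:5]
  set.seed(11)
  for (rep in 1:10) {
    pairs <- expand.grid(g, g, stringsAsFactors = FALSE)
    pairs <- pairs[runif(nrow(pairs)) < 0.3, , drop = FALSE]
    net <- DirectedNetwork(g, as.matrix(pairs))
    und <- undirect(net)
    # adding all reversed regulations changes nothing
    rev <- DirectedNetwork(g, rbind(regulations(net),
                                    regulations(net)[, 2:1, drop = FALSE]))
    expect_equal(edges(undirect(rev)), edges(und))
  }
})

test_that("buildEnsemble counts direction-blind edge weights", {
  ab <- DirectedNetwork(c("a", "b"), rbind(c("a", "b")))
  ens <- buildEnsemble(list(ab, ab))
  expect_equal(edgeWeights(ens)["a", "b"], 2)

  ba <- DirectedNetwork(c("a", "b"), rbind(c("b", "a")))
  ens2 <- buildEnsemble(list(ab, ba))
  expect_equal(edgeWeights(ens2)["a", "b"], 2)

  ens3 <- buildEnsemble(replicate(100, DirectedNetwork(c("a", "b")),
                                  simplify = FALSE))
  expect_equal(nNetworks(ens3), 100L)
  expect_true(all(edgeWeights(ens3) == 0))
})

test_that("mismatched gene lists are rejected with the offending index", {
  a <- DirectedNetwork(c("a", "b"))
  b <- DirectedNetwork(c("a", "c"))
  expect_error(buildEnsemble(list(a, b)), "network 2")
})

test_that("total ensemble weight equals the total member edge count", {
  set.seed(21)
  for (rep in 1:5) {
    ens <- randomEnsemble(letters[1:8], ng = 10, p = 0.4)
    total <- sum(vapply(memberNetworks(ens),
                        function(m) nrow(edges(m)), 1L))
    expect_equal(sum(edgeWeights(ens)) / 2, total)
  }
})

test_that("bootstrap probabilities are member fractions on the 1/Ng grid", {
  g <- c("m", "n")
  with_edge <- DirectedNetwork(g, rbind(c("m", "n")))
  without <- DirectedNetwork(g)
  nets <- c(replicate(29, with_edge, simplify = FALSE),
            replicate(71, without, simplify = FALSE))
  pB <- bootstrapProbabilities(nets)
  expect_equal(pB["n", "m"], 0.29)  # target row, regulator column
  expect_equal(pB["m", "n"], 0)

  expect_equal(bootstrapProbabilities(replicate(5, with_edge,
                                                simplify = FALSE))["n", "m"], 1)
  expect_error(bootstrapProbabilities(list()), "at least one")

  set.seed(3)
  nets <- replicate(7, {
    keep <- runif(4) < 0.5
    pairs <- rbind(c("m", "n"), c("n", "m"), c("m", "m"), c("n", "n"))
    DirectedNetwork(g, pairs[keep, , drop = FALSE])
  }, simplify = FALSE)
  pB <- bootstrapProbabilities(nets)
  expect_true(all(abs(pB * 7 - round(pB * 7)) < 1e-12))
  # self-regulation probabilities are computed (diagonal present)
  expect_true(all(diag(pB) >= 0))
})

test_that("edge-list, adjacency and gold-standard files round-trip", {
  g <- c("G1", "G2", "G3")
  net <- DirectedNetwork(g, rbind(c("G1", "G2"), c("G2", "G3"), c("G3", "G3")))

  f <- tempfile(fileext = ".tsv")
  writeEdgeList(net, f)
  back <- readEdgeList(f, genes = g)
  expect_setequal(hrgnet:::.pairKey(regulations(back)[, 1], regulations(back)[, 2]),
                  hrgnet:::.pairKey(regulations(net)[, 1], regulations(net)[, 2]))

  fa <- tempfile(fileext = ".tsv")
  writeAdjacencyMatrix(net, fa)
  backA <- readAdjacencyMatrix(fa)
  expect_setequal(hrgnet:::.pairKey(regulations(backA)[, 1], regulations(backA)[, 2]),
                  hrgnet:::.pairKey(regulations(net)[, 1], regulations(net)[, 2]))

  fg <- tempfile(fileext = ".tsv")
  writeGoldStandard(net, fg, allPairs = TRUE)
  backG <- readGoldStandard(fg, genes = g)
  expect_setequal(hrgnet:::.pairKey(regulations(backG)[, 1], regulations(backG)[, 2]),
                  setdiff(hrgnet:::.pairKey(regulations(net)[, 1], regulations(net)[, 2]),
                          "G3\rG3"))  # allPairs drops self-pairs by design
})

test_that("ensemble directories round-trip", {
  g <- c("a", "b", "c")
  nets <- list(DirectedNetwork(g, rbind(c("a", "b"))),
               DirectedNetwork(g, rbind(c("b", "c"), c("c", "a"))),
               DirectedNetwork(g))
  d <- tempfile()
  writeEnsemble(nets, d)
  back <- readEnsemble(d, genes = g)
  expect_length(back, 3L)
  for (k in 1:3) {
    expect_equal(sort(hrgnet:::.pairKey(regulations(back[[k]])[, 1],
                                        regulations(back[[k]])[, 2])),
                 sort(hrgnet:::.pairKey(regulations(nets[[k]])[, 1],
                                        regulations(nets[[k]])[, 2])))
  }
})
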