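test_that("the S-system right-hand side matches direct substitution", {
  m <- SSystemModel(c("x", "y"))  # g = 0, h = I, alpha = beta = 1
  expect_equal(unname(ssystemDerivative(m, c(2, 0.5))), c(1 - 2, 1 - 0.5))

  set.seed(7)
  g <- matrix(runif(9, -1, 1), 3, 3)
  m3 <- SSystemModel(c("a", "b", "c"), alpha = c(1, 2, 3), beta = c(2, 1, 1),
                     g = g, h = diag(3))
  X <- c(1, 1, 1)
  expect_equal(unname(ssystemDerivative(m3, X)), m3@alpha - m3@beta)  # powers of one

  m3b <- SSystemModel(c("a", "b", "c"), alpha = 2 * c(1, 2, 3),
                      beta = c(2, 1, 1), g = g, h = diag(3))
  X <- c(0.7, 1.3, 2.1)
  prod1 <- ssystemDerivative(m3, X) + m3@beta * X
  prod2 <- ssystemDerivative(m3b, X) + m3b@beta * X
  expect_equal(prod2, 2 * prod1)  # production is linear in alpha

  expect_error(ssystemDerivative(m, c(1, 0)), "gene y")
})

test_that("the decoupled system matches its closed-form solution", {
  m <- SSystemModel("x")  # dX/dt = 1 - X
  times <- seq(0, 4, by = 0.4)
  traj <- simulateSSystem(m, 2, times)
  expect_equal(nrow(traj), 11L)
  expect_equal(unname(traj[2, 1]), 1 + exp(-0.4), tolerance = 1e-6)
  expect_equal(unname(traj[, 1]), 1 + (2 - 1) * exp(-times), tolerance = 1e-6)

  # from below, and multi-gene
  m5 <- SSystemModel(paste0("g", 1:5))
  x0 <- c(0.2, 0.5, 1.5, 1.9, 1)
  traj5 <- simulateSSystem(m5, x0, times)
  expect_equal(unname(traj5),
               sapply(seq_along(x0), function(j) 1 + (x0[j] - 1) * exp(-times)),
               tolerance = 1e-6)
  # monotone approach to the fixed point
  expect_true(all(diff(traj5[, 1]) > 0))
  expect_true(all(diff(traj5[, 4]) < 0))

  # steady state stays put
  flat <- simulateSSystem(m, 1, times)
  expect_equal(unname(flat[, 1]), rep(1, 11), tolerance = 1e-8)
})

test_that("tightening the solver tolerance does not move the solution", {
  m <- SSystemModel(paste0("g", 1:3))
  times <- seq(0, 4, by = 0.4)
  a <- simulateSSystem(m, c(0.3, 1.2, 1.9), times, rtol = 1e-8)
  b <- simulateSSystem(m, c(0.3, 1.2, 1.9), times, rtol = 1e-10, atol = 1e-12)
  expect_lt(max(abs(a - b) / pmax(abs(b), 1)), 1e-6)
})

test_that("simulation guards its preconditions", {
  m <- SSystemModel("x")
  expect_error(simulateSSystem(m, 0, c(0, 1)), "positive")
  expect_error(simulateSSystem(m, 1, c(0, 1, 1)), "increasing")
})

test_that("kinetic orders are drawn on the topology with the stated law", {
  g <- paste0("g", seq_len(60))
  empty <- sampleModelFromTopology(DirectedNetwork(g))
  expect_true(all(empty@g == 0))

  set.seed(13)
  pairs <- expand.grid(g, g, stringsAsFactors = FALSE)
  pairs <- as.matrix(pairs[pairs[, 1] != pairs[, 2], ])
  topo <- DirectedNetwork(g, pairs)  # 3540 regulations
  model <- sampleModelFromTopology(topo)
  offdiag <- model@g[row(model@g) != col(model@g)]
  expect_true(all(abs(offdiag) >= 0.5 & abs(offdiag) <= 1))
  expect_equal(model@h, diag(60), ignore_attr = TRUE)
  expect_equal(model@alpha, rep(1, 60))
  # sign is a fair coin: 3 binomial SEs around one half
  frac <- mean(offdiag > 0)
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / length(offdiag)))
  # g is non-zero exactly on the topology (here: everywhere off-diagonal)
  M <- matrix(FALSE, 60, 60)
  M[cbind(match(pairs[, 2], g), match(pairs[, 1], g))] <- TRUE
  expect_equal(unname(model@g != 0), M)
})

test_that("dataset generation follows the sampling protocol", {
  m <- SSystemModel(paste0("g", 1:10))
  set.seed(23)
  data <- generateDataset(m)  # defaults: 100 sets x 11 obs at 0.4
  expect_equal(dim(cleanValues(data)), c(100L, 11L, 10L))
  expect_equal(timePoints(data), seq(0, 4, by = 0.4))
  d <- dim(cleanValues(data))
  expect_equal(d[1] * d[2], 1100)  # K measurements per gene

  # noise is multiplicative with the requested relative sd
  ratio <- noisyValues(data) / cleanValues(data) - 1
  expect_lt(abs(sd(ratio) - 0.1), 3 * 0.1 / sqrt(2 * length(ratio)))
  expect_true(all(noisyValues(data) >= 1e-6))

  set.seed(29)
  clean <- generateDataset(m, nSets = 3L, noiseFraction = 0)
  expect_identical(noisyValues(clean), cleanValues(clean))
  # initial states in [0, 2], never below the resampling floor
  expect_true(all(cleanValues(clean)[, 1, ] >= 1e-3 &
                    cleanValues(clean)[, 1, ] <= 2))
  # with g = 0 every trajectory approaches 1 monotonically
  for (s in 1:3) {
    for (j in 1:10) {
      x <- cleanValues(clean)[s, , j]
      expect_true(all(diff(abs(x - 1)) <= 1e-8))
    }
  }
})

test_that("dataset generation is reproducible from the seed", {
  m <- SSystemModel(paste0("g", 1:4))
  set.seed(31)
  a <- generateDataset(m, nSets = 4L)
  set.seed(31)
  b <- generateDataset(m, nSets = 4L)
  expect_identical(noisyValues(a), noisyValues(b))
})

test_that("modular topologies are sparse, self-loop-free and modular", {
  set.seed(37)
  g <- sprintf("G%02d", 1:10)
  topo <- randomModularTopology(g)
  r <- regulations(topo)
  expect_true(all(r[, 1] != r[, 2]))
  expect_true(all(r %in% g))
  # module structure: within-module density dominates on average
  dens <- replicate(200, {
    t2 <- randomModularTopology(g)
    nrow(regulations(t2))
  })
  expect_gt(mean(dens), 5)   # ~ 10 within + 1 between expected
  expect_lt(mean(dens), 20)
})
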