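# S-system power-law kinetics and the synthetic time-series protocol:
# random kinetic orders on a given topology, many short time series from
# random initial states, multiplicative Gaussian measurement noise.

#' Construct an S-system model
#'
#' @param genes gene labels.
#' @param alpha,beta positive rate vectors (recycled to length N).
#' @param g,h N x N kinetic-order matrices, oriented [target, regulator].
#' @return an \linkS4class{SSystemModel}
#' @export
SSystemModel <- function(genes, alpha = 1, beta = 1, g = NULL, h = NULL) {
  genes <- as.character(genes)
  N <- length(genes)
  if (is.null(g)) g <- matrix(0, N, N)
  if (is.null(h)) h <- diag(N)
  dimnames(g) <- dimnames(h) <- list(genes, genes)
  obj <- new("SSystemModel", genes = genes, alpha = rep_len(alpha, N),
             beta = rep_len(beta, N), g = g, h = h)
  validObject(obj)
  obj
}

#' S-system right-hand side
#'
#' dX_n/dt = alpha_n prod_m X_m^{g[n,m]} - beta_n prod_m X_m^{h[n,m]}.
#' The state must be strictly positive (power laws with negative kinetic
#' orders are singular at zero).
#'
#' @param model an \linkS4class{SSystemModel}
#' @param X positive state vector of length N
#' @return rate vector dX/dt
#' @export
ssystemDerivative <- function(model, X) {
  if (any(X <= 0)) {
    bad <- model@genes[which(X <= 0)[1L]]
    stop("non-positive state for gene ", bad,
         ": the S-system right-hand side is undefined")
  }
  lx <- log(X)
  drop(model@alpha * exp(model@g %*% lx) - model@beta * exp(model@h %*% lx))
}

#' Integrate an S-system model
#'
#' Adaptive integration (deSolve, lsoda) at relative tolerance 1e-8. A
#' trajectory that leaves the positive orthant or fails to integrate
#' raises an error with a diagnostic rather than being silently floored.
#'
#' @param model an \linkS4class{SSystemModel}
#' @param x0 positive initial state
#' @param times strictly increasing observation times (the first is the
#'   initial time)
#' @param rtol,atol solver tolerances
#' @return matrix of dim length(times) x N (the trajectory; first row = x0)
#' @export
simulateSSystem <- function(model, x0, times, rtol = 1e-8, atol = 1e-10) {
  N <- length(model@genes)
  stopifnot(length(x0) == N)
  if (any(x0 <= 0)) stop("initial state must be strictly positive")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  rhs <- function(t, X, parms) {
    if (any(X <= 0)) {
      bad <- model@genes[which(X <= 0)[1L]]
      stop("state of gene ", bad, " reached a non-positive value at t = ",
           signif(t, 6))
    }
    lx <- log(X)
    list(drop(model@alpha * exp(model@g %*% lx) -
              model@beta * exp(model@h %*% lx)))
  }
  out <- deSolve::lsoda(y = unname(x0), times = times, func = rhs,
                        parms = NULL, rtol = rtol, atol = atol)
  if (nrow(out) < length(times) || any(!is.finite(out[, -1L])))
    stop("S-system integration failed (trajectory diverged or solver error)")
  traj <- out[, -1L, drop = FALSE]
  dimnames(traj) <- list(NULL, model@genes)
  traj
}

#' Draw random S-system kinetics on a fixed topology
#'
#' For every regulation m -> n in the topology, the production kinetic
#' order g[n, m] is drawn uniformly from [-1, -0.5] U [0.5, 1] (magnitude
#' uniform in [0.5, 1], sign uniform); all other g entries are 0. The
#' degradation term is pure auto-degradation (h = identity) and
#' alpha = beta = 1. Uses the R RNG.
#'
#' @param topology a \linkS4class{DirectedNetwork}
#' @return an \linkS4class{SSystemModel}
#' @export
sampleModelFromTopology <- function(topology) {
  stopifnot(is(topology, "DirectedNetwork"))
  gl <- topology@genes
  N <- length(gl)
  g <- matrix(0, N, N, dimnames = list(gl, gl))
  r <- topology@regulations
  if (nrow(r)) {
    n <- match(r[, 2L], gl)  # target row
    m <- match(r[, 1L], gl)  # regulator column
    mag <- runif(nrow(r), 0.5, 1)
    sgn <- ifelse(runif(nrow(r)) < 0.5, -1, 1)
    g[cbind(n, m)] <- sgn * mag
  }
  SSystemModel(gl, alpha = 1, beta = 1, g = g, h = diag(N))
}

#' Generate a synthetic time-series dataset
#'
#' The study protocol: \code{nSets} independent time series, each started
#' from initial values drawn uniformly in [0, 2] (redrawn while any
#' coordinate is below 1e-3, where negative kinetic orders make the system
#' singular), observed \code{nObs} times at interval \code{dt}, with
#' multiplicative Gaussian measurement noise
#' noisy = clean * (1 + eps), eps ~ N(0, noiseFraction^2), floored at 1e-6.
#' Defaults give 100 x 11 = 1100 measurements per gene. Set
#' \code{absoluteNoise = TRUE} for additive noise with sd = noiseFraction
#' instead. Uses the R RNG.
#'
#' @param model an \linkS4class{SSystemModel}
#' @param nSets number of experiment sets
#' @param nObs observations per set
#' @param dt observation interval
#' @param noiseFraction relative noise level (0 disables noise)
#' @param absoluteNoise use additive instead of multiplicative noise
#' @return a \linkS4class{TimeSeriesSet}
#' @export
generateDataset <- function(model, nSets = 100L, nObs = 11L, dt = 0.4,
                            noiseFraction = 0.1, absoluteNoise = FALSE) {
  N <- length(model@genes)
  times <- (seq_len(nObs) - 1L) * dt
  clean <- array(NA_real_, dim = c(nSets, nObs, N),
                 dimnames = list(NULL, NULL, model@genes))
  for (s in seq_len(nSets)) {
    repeat {
      x0 <- runif(N, 0, 2)
      if (all(x0 >= 1e-3)) break
    }
    clean[s, , ] <- simulateSSystem(model, x0, times)
  }
  if (noiseFraction > 0) {
    eps <- array(rnorm(length(clean), 0, noiseFraction), dim = dim(clean))
    noisy <- if (absoluteNoise) clean + eps else clean * (1 + eps)
    noisy <- pmax(noisy, 1e-6)
  } else {
    noisy <- clean
  }
  new("TimeSeriesSet", genes = model@genes, times = times, clean = clean,
      noisy = noisy)
}

#' Random sparse modular topology
#'
#' Synthetic stand-in for curated benchmark topologies at small N: genes
#' are split into modules and directed regulations are drawn independently
#' with a higher probability within modules than between them, yielding the
#' sparse, clustered structure in which a hierarchy is meaningful.
#' Self-regulations are never drawn (auto-degradation is part of the
#' S-system kinetics instead). Uses the R RNG.
#'
#' @param genes gene labels
#' @param nModules number of modules (genes split as evenly as possible)
#' @param pWithin probability of a directed regulation within a module
#' @param pBetween probability between modules
#' @return a \linkS4class{DirectedNetwork}
#' @export
randomModularTopology <- function(genes, nModules = 2L, pWithin = 0.25,
                                  pBetween = 0.02) {
  genes <- as.character(genes)
  N <- length(genes)
  module <- rep(seq_len(nModules), length.out = N)[order(runif(N))]
  prob <- ifelse(outer(module, module, "=="), pWithin, pBetween)
  diag(prob) <- 0
  draw <- matrix(runif(N * N), N, N) < prob
  idx <- which(draw, arr.ind = TRUE)
  # orientation: entry [i, j] drawn means regulator genes[i] -> target genes[j]
  DirectedNetwork(genes, cbind(genes[idx[, 1L]], genes[idx[, 2L]]))
}

#' Random Erdos-Renyi-style ensemble of undirected networks
#'
#' Each of \code{ng} member networks contains every unordered gene pair
#' independently with probability \code{p}. Used to exercise the hierarchy
#' search on unstructured inputs. Uses the R RNG.
#'
#' @param genes gene labels
#' @param ng number of member networks
#' @param p per-pair edge probability
#' @return a \linkS4class{NetworkEnsemble}
#' @export
randomEnsemble <- function(genes, ng, p = 0.3) {
  genes <- as.character(genes)
  pairs <- t(combn(genes, 2L))
  members <- replicate(ng, {
    keep <- runif(nrow(pairs)) < p
    UndirectedNetwork(genes, pairs[keep, , drop = FALSE])
  }, simplify = FALSE)
  buildEnsemble(members)
}
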