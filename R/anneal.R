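# Simulated-annealing maximization of the dendrogram log-likelihood, the
# Exchange / Rotate proposal moves, and an exhaustive-search oracle for
# small gene sets.

#' Construct an annealing schedule
#'
#' Defaults are the published constants T_start = 1000, T_end = 0.1,
#' N_max = 1000 N and gamma = 0.99, giving ~916 geometric cooling epochs.
#'
#' @param N number of genes (used for the default N_max = nMaxFactor * N).
#' @param tStart,tEnd initial and final temperature.
#' @param nMax proposals per temperature epoch; default nMaxFactor * N.
#' @param nMaxFactor multiplier for the default nMax.
#' @param gamma geometric cooling factor in (0, 1).
#' @param seed RNG seed (NA leaves the RNG state untouched).
#' @param restartFromBest copy the best tree into the current tree at the
#'   start of every epoch, as in the printed algorithm (default TRUE).
#' @return an \linkS4class{AnnealSchedule}
#' @export
AnnealSchedule <- function(N = NULL, tStart = 1000, tEnd = 0.1, nMax = NULL,
                           nMaxFactor = 1000L, gamma = 0.99,
                           seed = NA_integer_, restartFromBest = TRUE) {
  if (is.null(nMax)) {
    if (is.null(N)) stop("give either N or nMax")
    nMax <- as.integer(nMaxFactor) * as.integer(N)
  }
  obj <- new("AnnealSchedule", tStart = tStart, tEnd = tEnd,
             nMax = as.integer(nMax), gamma = gamma,
             seed = as.integer(seed), restartFromBest = restartFromBest)
  validObject(obj)
  obj
}

#' Acceptance probability of a proposed tree
#'
#' min(1, exp(-(objCurrent - objTest) / T)): improving or equal proposals
#' are always accepted, worse ones with Boltzmann probability.
#'
#' @param objCurrent,objTest objective values of the current and proposed
#'   trees (log-likelihoods)
#' @param temperature T > 0
#' @return acceptance probability (vectorized)
#' @export
acceptProbability <- function(objCurrent, objTest, temperature) {
  if (any(temperature <= 0)) stop("temperature must be positive")
  pmin(1, exp((objTest - objCurrent) / temperature))
}

# shared geometry of both proposal moves: at internal node s with subtrees
# (A, (B, C)) (A the child, B and C the grandchildren under internal child
# t), the result keeps A grouped with `partner` under t and hoists `other`
# to be s's direct child.
.regroup <- function(tree, s, t, A, partner, other) {
  N <- length(tree@genes)
  lc <- tree@leftChild; rc <- tree@rightChild; par <- tree@parent
  lc[t - N] <- A;  rc[t - N] <- partner
  lc[s - N] <- t;  rc[s - N] <- other
  par[A] <- t; par[partner] <- t; par[other] <- s
  new("Dendrogram", genes = tree@genes, leftChild = lc, rightChild = rc,
      parent = par, root = tree@root)
}

.moveConfig <- function(tree, s, internalChild = NULL) {
  N <- length(tree@genes)
  if (s <= N || s > 2L * N - 1L) stop("s must be an internal node id")
  ch <- .children(tree, s)
  internal <- ch[ch > N]
  if (!length(internal)) return(NULL)  # two leaf children: no-op
  t <- if (length(internal) == 2L && !is.null(internalChild)) {
    internal[internalChild]
  } else if (length(internal) == 2L) {
    internal[floor(runif(1L) * 2) + 1L]
  } else internal[1L]
  A <- setdiff(ch, t)
  list(t = t, A = A, B = tree@leftChild[t - N], C = tree@rightChild[t - N])
}

#' Exchange move
#'
#' Swaps one child subtree of s with one grandchild subtree under s's
#' internal child: (A,(B,C)) becomes (B,(A,C)) or (C,(A,B)). When choices
#' are not supplied they are drawn uniformly with the R RNG. Returns NULL
#' (a no-op signal) when both children of s are leaves; the caller
#' re-proposes.
#'
#' @param tree a \linkS4class{Dendrogram}
#' @param s internal node id
#' @param grandchild which grandchild to swap with: 1 (left, B) or 2
#'   (right, C); NULL for random
#' @param internalChild when both children of s are internal: 1 or 2
#'   selects which becomes the pivot; NULL for random
#' @return the rearranged \linkS4class{Dendrogram}, or NULL
#' @export
exchangeMove <- function(tree, s, grandchild = NULL, internalChild = NULL) {
  cfg <- .moveConfig(tree, s, internalChild)
  if (is.null(cfg)) return(NULL)
  if (is.null(grandchild)) grandchild <- floor(runif(1L) * 2) + 1L
  if (grandchild == 1L) {  # swap A with B: t keeps {A, C}
    .regroup(tree, s, cfg$t, cfg$A, cfg$C, cfg$B)
  } else {                 # swap A with C: t keeps {A, B}
    .regroup(tree, s, cfg$t, cfg$A, cfg$B, cfg$C)
  }
}

#' Rotate move
#'
#' Re-roots the three-subtree configuration under s: (A,(B,C)) becomes
#' ((A,B),C) (variant 1) or ((A,C),B) (variant 2), uniformly at random
#' when the variant is not supplied. Returns NULL when both children of s
#' are leaves.
#'
#' @param tree a \linkS4class{Dendrogram}
#' @param s internal node id
#' @param variant 1 or 2; NULL for random
#' @param internalChild see \code{\link{exchangeMove}}
#' @return the rearranged \linkS4class{Dendrogram}, or NULL
#' @export
rotateMove <- function(tree, s, variant = NULL, internalChild = NULL) {
  cfg <- .moveConfig(tree, s, internalChild)
  if (is.null(cfg)) return(NULL)
  if (is.null(variant)) variant <- floor(runif(1L) * 2) + 1L
  if (variant == 1L) .regroup(tree, s, cfg$t, cfg$A, cfg$B, cfg$C)
  else               .regroup(tree, s, cfg$t, cfg$A, cfg$C, cfg$B)
}

#' All trees one Exchange/Rotate move away
#'
#' Deterministic enumeration of every distinct rearrangement reachable by
#' a single move; used by the ergodicity (move-closure) checks.
#'
#' @param tree a \linkS4class{Dendrogram}
#' @return list of \linkS4class{Dendrogram}
#' @export
neighborTrees <- function(tree) {
  N <- length(tree@genes)
  out <- list()
  for (s in (N + 1L):(2L * N - 1L)) {
    ch <- .children(tree, s)
    for (which in 1:2) {
      t <- ch[which]
      if (t <= N) next
      A <- ch[3L - which]
      B <- tree@leftChild[t - N]; C <- tree@rightChild[t - N]
      out <- c(out,
               list(.regroup(tree, s, t, A, B, C),
                    .regroup(tree, s, t, A, C, B)))
    }
  }
  out
}

#' Maximum-likelihood dendrogram by simulated annealing
#'
#' Implements the printed algorithm: start from a random tree, propose
#' Exchange/Rotate rearrangements at uniformly chosen internal nodes,
#' accept with probability min(1, exp(-(Obj_c - Obj_t)/T)), replace the
#' best tree only on strict improvement, copy the best tree into the
#' current tree at the start of every temperature epoch, and cool
#' geometrically from tStart to tEnd. Theta is always at its closed-form
#' maximum-likelihood value, never a free search variable. Proposals at a
#' node with two leaf children are counted but have no effect.
#'
#' @param ens a non-empty \linkS4class{NetworkEnsemble}
#' @param schedule an \linkS4class{AnnealSchedule}; default the published
#'   full schedule for N genes
#' @return list with elements \code{model} (\linkS4class{HRGModel}),
#'   \code{objective} (best log-likelihood) and \code{trace} (one row per
#'   epoch: epoch, temperature, objCurrent, objBest, accepted, noop)
#' @export
annealHRG <- function(ens, schedule = NULL) {
  stopifnot(is(ens, "NetworkEnsemble"))
  N <- length(ens@genes)
  if (N < 2L) stop("hierarchy detection needs at least 2 genes")
  if (is.null(schedule)) schedule <- AnnealSchedule(N)
  if (!is.na(schedule@seed)) set.seed(schedule@seed)
  emptyTrace <- data.frame(epoch = integer(), temperature = numeric(),
                           objCurrent = numeric(), objBest = numeric(),
                           accepted = numeric(), noop = numeric())
  if (N == 2L) {  # the unique single-cherry tree; nothing to search
    tree <- Dendrogram(ens@genes, 1L, 2L, 3L)
    model <- fitHRGModel(tree, ens)
    return(list(model = model, objective = logLikelihood(tree, ens),
                trace = emptyTrace))
  }
  init <- randomDendrogram(ens@genes)
  res <- .annealCpp(ens@weights, ens@ng, init@leftChild, init@rightChild,
                    init@root, schedule@tStart, schedule@tEnd, schedule@nMax,
                    schedule@gamma, schedule@restartFromBest)
  tree <- Dendrogram(ens@genes, res$leftChild, res$rightChild, res$root)
  trace <- as.data.frame(res$trace)
  colnames(trace) <- c("epoch", "temperature", "objCurrent", "objBest",
                       "accepted", "noop")
  list(model = fitHRGModel(tree, ens), objective = res$objBest,
       trace = trace)
}

#' Exhaustive dendrogram search (test oracle)
#'
#' Enumerates every leaf-labeled rooted binary shape - there are (2N-3)!!
#' of them - and evaluates the log-likelihood of each, returning the global
#' optimum, the set of tied optima and the full objective table. Refuses
#' N > 8.
#'
#' @param ens a \linkS4class{NetworkEnsemble} with at most 8 genes
#' @param tol tie tolerance on the log-likelihood
#' @return list with elements \code{model}, \code{optimum}, \code{ties}
#'   (list of tied \linkS4class{Dendrogram}s) and \code{table}
#'   (data.frame shape, loglik)
#' @export
exhaustiveSearch <- function(ens, tol = 1e-9) {
  stopifnot(is(ens, "NetworkEnsemble"))
  g <- ens@genes
  N <- length(g)
  if (N < 2L) stop("need at least 2 genes")
  if (N > 8L) stop("exhaustive search is limited to N <= 8 ((2N-3)!! shapes)")
  W <- ens@weights
  Ng <- ens@ng
  total <- prod(seq(1, max(1, 2 * N - 3), by = 2))
  lc <- rc <- integer(N - 1L)
  par <- integer(2L * N - 1L)
  shapes <- character(total)
  lls <- numeric(total)
  idx <- 0L
  bestLL <- -Inf
  bestSet <- list()

  keyOf <- function(x) {
    if (x <= N) return(g[x])
    a <- keyOf(lc[x - N]); b <- keyOf(rc[x - N])
    if (a > b) paste0("(", b, ",", a, ")") else paste0("(", a, ",", b, ")")
  }
  record <- function(root) {
    idx <<- idx + 1L
    ll <- .hrgLogLikCpp(lc, rc, root, W, Ng)
    lls[idx] <<- ll
    shapes[idx] <<- keyOf(root)
    if (ll > bestLL + tol) {
      bestLL <<- ll
      bestSet <<- list(list(lc = lc, rc = rc, root = root))
    } else if (ll >= bestLL - tol) {
      bestSet <<- c(bestSet, list(list(lc = lc, rc = rc, root = root)))
    }
  }
  rec <- function(k, nodes, root) {
    if (k > N) { record(root); return(invisible()) }
    newInt <- N + k - 1L
    for (x in nodes) {
      if (x == root) {
        lc[newInt - N] <<- x; rc[newInt - N] <<- k
        par[x] <<- newInt; par[k] <<- newInt; par[newInt] <<- 0L
        rec(k + 1L, c(nodes, k, newInt), newInt)
        par[x] <<- 0L
      } else {
        p <- par[x]
        wasLeft <- lc[p - N] == x
        if (wasLeft) lc[p - N] <<- newInt else rc[p - N] <<- newInt
        lc[newInt - N] <<- x; rc[newInt - N] <<- k
        par[newInt] <<- p; par[x] <<- newInt; par[k] <<- newInt
        rec(k + 1L, c(nodes, k, newInt), root)
        if (wasLeft) lc[p - N] <<- x else rc[p - N] <<- x
        par[x] <<- p
      }
    }
  }

  lc[1L] <- 1L; rc[1L] <- 2L
  par[1L] <- par[2L] <- N + 1L
  if (N == 2L) record(N + 1L) else rec(3L, c(1L, 2L, N + 1L), N + 1L)

  ties <- lapply(bestSet, function(b) Dendrogram(g, b$lc, b$rc, b$root))
  list(model = fitHRGModel(ties[[1L]], ens), optimum = bestLL, ties = ties,
       table = data.frame(shape = shapes, loglik = lls))
}
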