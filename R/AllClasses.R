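#' @import methods
#' @importFrom stats runif rnorm rbinom setNames sd
#' @importFrom utils read.table write.table head combn
#' @useDynLib hrgnet, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

# ---------------------------------------------------------------------------
# Network containers
# ---------------------------------------------------------------------------

#' Directed gene regulatory network
#'
#' A directed graph over a fixed, ordered gene list. A regulation is an
#' ordered pair (regulator m, target n), read "gene n is regulated by gene m".
#' Self-regulations (auto-regulation / auto-degradation) are permitted at
#' this layer; they are stripped when the network is symmetrized for
#' hierarchy detection and excluded from evaluation.
#'
#' @slot genes character vector of unique gene identifiers (length N).
#' @slot regulations two-column character matrix, columns
#'   \code{regulator}, \code{target}; set semantics (no duplicates).
#' @export
setClass("DirectedNetwork",
         representation(genes = "character", regulations = "matrix"))

setValidity("DirectedNetwork", function(object) {
  msg <- character()
  g <- object@genes
  r <- object@regulations
  if (length(g) < 1L) msg <- c(msg, "gene list is empty")
  if (anyDuplicated(g)) msg <- c(msg, "gene identifiers must be unique")
  if (!is.character(r) || ncol(r) != 2L) {
    msg <- c(msg, "regulations must be a two-column character matrix")
  } else if (nrow(r) > 0L) {
    if (!all(r %in% g)) msg <- c(msg, "regulations refer to genes outside the gene list")
    if (anyDuplicated(paste(r[, 1L], r[, 2L], sep = "\r")))
      msg <- c(msg, "duplicate regulations")
  }
  if (length(msg)) msg else TRUE
})

#' Undirected network
#'
#' Symmetrized view of a regulatory network: an edge joins two genes if
#' either regulates the other. Self-edges are forbidden.
#'
#' @slot genes character vector of unique gene identifiers.
#' @slot edges two-column character matrix of unordered pairs, stored in
#'   canonical order (first endpoint earlier in the gene list).
#' @export
setClass("UndirectedNetwork",
         representation(genes = "character", edges = "matrix"))

setValidity("UndirectedNetwork", function(object) {
  msg <- character()
  g <- object@genes
  e <- object@edges
  if (anyDuplicated(g)) msg <- c(msg, "gene identifiers must be unique")
  if (!is.character(e) || ncol(e) != 2L) {
    msg <- c(msg, "edges must be a two-column character matrix")
  } else if (nrow(e) > 0L) {
    if (!all(e %in% g)) msg <- c(msg, "edges refer to genes outside the gene list")
    if (any(e[, 1L] == e[, 2L])) msg <- c(msg, "self-edges are not allowed")
    i1 <- match(e[, 1L], g); i2 <- match(e[, 2L], g)
    if (any(i1 >= i2)) msg <- c(msg, "edges must be stored in canonical gene-list order")
    if (anyDuplicated(paste(e[, 1L], e[, 2L], sep = "\r")))
      msg <- c(msg, "duplicate edges")
  }
  if (length(msg)) msg else TRUE
})

#' Ensemble of undirected networks over a common gene list
#'
#' Holds the N_g symmetrized member networks together with the aggregated
#' edge-weight matrix W, where W[u, v] counts the members containing the
#' edge {u, v}.
#'
#' @slot genes shared gene list.
#' @slot members list of \linkS4class{UndirectedNetwork}.
#' @slot weights symmetric N x N numeric matrix of member counts per
#'   unordered pair (zero diagonal).
#' @slot ng number of member networks.
#' @export
setClass("NetworkEnsemble",
         representation(genes = "character", members = "list",
                        weights = "matrix", ng = "integer"))

setValidity("NetworkEnsemble", function(object) {
  msg <- character()
  g <- object@genes
  N <- length(g)
  if (object@ng != length(object@members))
    msg <- c(msg, "ng does not match the number of member networks")
  if (!all(dim(object@weights) == c(N, N)))
    msg <- c(msg, "weights matrix dimension does not match the gene list")
  for (k in seq_along(object@members)) {
    m <- object@members[[k]]
    if (!is(m, "UndirectedNetwork") || !identical(m@genes, g)) {
      msg <- c(msg, sprintf("member %d does not share the ensemble gene list", k))
      break
    }
  }
  if (!length(msg) && N > 0L) {
    W <- matrix(0, N, N)
    for (m in object@members) {
      e <- m@edges
      if (nrow(e)) {
        i <- match(e[, 1L], g); j <- match(e[, 2L], g)
        W[cbind(i, j)] <- W[cbind(i, j)] + 1
      }
    }
    W <- W + t(W)
    if (!isTRUE(all.equal(unname(W), unname(object@weights))))
      msg <- c(msg, "weights do not equal the recount over member networks")
    if (any(object@weights < 0) || any(object@weights > object@ng))
      msg <- c(msg, "weights must lie in [0, ng]")
  }
  if (length(msg)) msg else TRUE
})

# ---------------------------------------------------------------------------
# Dendrogram / HRG model
# ---------------------------------------------------------------------------

#' Rooted binary dendrogram over a gene set
#'
#' N leaves in bijection with the gene list and N - 1 internal nodes, each
#' with exactly two children. Nodes are numbered 1..2N-1: leaves 1..N (in
#' gene-list order), internal nodes N+1..2N-1. Internal node i is addressed
#' in the child/theta vectors at position i - N.
#'
#' @slot genes leaf labels, in leaf-id order.
#' @slot leftChild,rightChild integer vectors of length N - 1: children of
#'   internal nodes N+1..2N-1.
#' @slot parent integer vector of length 2N - 1; 0 at the root.
#' @slot root id of the root internal node.
#' @export
setClass("Dendrogram",
         representation(genes = "character", leftChild = "integer",
                        rightChild = "integer", parent = "integer",
                        root = "integer"))

setValidity("Dendrogram", function(object) {
  g <- object@genes
  N <- length(g)
  if (N < 2L) return("a dendrogram needs at least two leaves")
  if (anyDuplicated(g)) return("leaf labels must be unique")
  M <- 2L * N - 1L
  if (length(object@leftChild) != N - 1L || length(object@rightChild) != N - 1L)
    return("child vectors must have length N - 1")
  if (length(object@parent) != M) return("parent vector must have length 2N - 1")
  ch <- c(object@leftChild, object@rightChild)
  if (any(ch < 1L) || any(ch > M)) return("child ids out of range")
  if (anyDuplicated(ch)) return("a node cannot have two parents")
  r <- object@root
  if (r < N + 1L || r > M) return("root must be an internal node")
  if (object@parent[r] != 0L) return("root must have parent 0")
  nonroot <- setdiff(seq_len(M), r)
  if (!setequal(ch, nonroot)) return("every node except the root must have exactly one parent")
  for (i in seq_len(N - 1L)) {
    node <- N + i
    if (object@parent[object@leftChild[i]] != node ||
        object@parent[object@rightChild[i]] != node)
      return("parent vector inconsistent with child vectors")
  }
  # reachability from the root covers all nodes (no cycles)
  seen <- logical(M)
  stack <- r
  while (length(stack)) {
    x <- stack[length(stack)]; stack <- stack[-length(stack)]
    if (seen[x]) return("cycle detected in dendrogram")
    seen[x] <- TRUE
    if (x > N) stack <- c(stack, object@leftChild[x - N], object@rightChild[x - N])
  }
  if (!all(seen)) return("dendrogram is not connected")
  TRUE
})

#' Hierarchical random graph model H(D, theta)
#'
#' A dendrogram D together with one probability theta_i per internal node:
#' an unordered gene pair {u, v} is an edge with probability theta at the
#' pair's lowest common ancestor.
#'
#' @slot tree a \linkS4class{Dendrogram}.
#' @slot theta numeric vector of length N - 1, indexed like the internal
#'   nodes (position i for node N + i), each in [0, 1].
#' @slot ng number of networks the model was fitted to (NA if not fitted).
#' @export
setClass("HRGModel",
         representation(tree = "Dendrogram", theta = "numeric", ng = "integer"))

setValidity("HRGModel", function(object) {
  N <- length(object@tree@genes)
  if (length(object@theta) != N - 1L)
    return("theta must have one entry per internal node")
  if (any(!is.finite(object@theta)) || any(object@theta < 0) || any(object@theta > 1))
    return("theta entries must lie in [0, 1]")
  TRUE
})

# ---------------------------------------------------------------------------
# Confidence matrices
# ---------------------------------------------------------------------------

#' Combined regulation confidences
#'
#' Matrices are oriented target-by-regulator: entry [n, m] refers to the
#' regulation of gene n (row) by gene m (column). pB is the directed
#' bootstrap probability, pH the direction-blind hierarchy probability
#' (theta at the pair's LCA; NA on the diagonal), and
#' combined = eta * pB + (1 - eta) * pH off the diagonal. Diagonal entries
#' (self-regulation) carry pB only and are excluded from ranking and
#' evaluation.
#'
#' @slot genes gene list (rows = targets, columns = regulators).
#' @slot pB,pH,combined N x N numeric matrices.
#' @slot eta mixing weight in [0, 1].
#' @export
setClass("ConfidenceMatrix",
         representation(genes = "character", pB = "matrix", pH = "matrix",
                        eta = "numeric", combined = "matrix"))

setValidity("ConfidenceMatrix", function(object) {
  N <- length(object@genes)
  msg <- character()
  for (nm in c("pB", "pH", "combined")) {
    M <- slot(object, nm)
    if (!all(dim(M) == c(N, N))) msg <- c(msg, sprintf("%s has wrong dimensions", nm))
    off <- M[row(M) != col(M)]
    if (any(!is.finite(off)) || any(off < 0) || any(off > 1))
      msg <- c(msg, sprintf("%s off-diagonal entries must lie in [0, 1]", nm))
  }
  if (length(object@eta) != 1L || object@eta < 0 || object@eta > 1)
    msg <- c(msg, "eta must be a single value in [0, 1]")
  if (!isTRUE(all.equal(unname(object@pH), unname(t(object@pH)),
                        check.attributes = FALSE)))
    msg <- c(msg, "pH must be symmetric")
  if (length(msg)) msg else TRUE
})

# ---------------------------------------------------------------------------
# S-system model and simulated data
# ---------------------------------------------------------------------------

#' S-system kinetic model
#'
#' Power-law ODE system
#' dX_n/dt = alpha_n prod_m X_m^{g[n,m]} - beta_n prod_m X_m^{h[n,m]}.
#' The kinetic-order matrices are oriented target-by-regulator like the
#' confidence matrices: g[n, m] != 0 means gene m appears in the production
#' term of gene n.
#'
#' @slot genes gene labels.
#' @slot alpha,beta positive rate vectors of length N.
#' @slot g,h N x N kinetic-order matrices.
#' @export
setClass("SSystemModel",
         representation(genes = "character", alpha = "numeric", beta = "numeric",
                        g = "matrix", h = "matrix"))

setValidity("SSystemModel", function(object) {
  N <- length(object@genes)
  msg <- character()
  if (length(object@alpha) != N || length(object@beta) != N)
    msg <- c(msg, "alpha and beta must have length N")
  if (any(object@alpha <= 0) || any(object@beta <= 0))
    msg <- c(msg, "alpha and beta must be strictly positive")
  if (!all(dim(object@g) == c(N, N)) || !all(dim(object@h) == c(N, N)))
    msg <- c(msg, "g and h must be N x N")
  if (length(msg)) msg else TRUE
})

#' Simulated time-series expression data
#'
#' S experiment sets of T observations of N genes, stored as S x T x N
#' arrays in both noise-free (\code{clean}) and noise-corrupted
#' (\code{noisy}) form, sharing one observation grid.
#'
#' @slot genes gene labels.
#' @slot times strictly increasing observation times (length T).
#' @slot clean,noisy numeric arrays of dimension S x T x N.
#' @export
setClass("TimeSeriesSet",
         representation(genes = "character", times = "numeric",
                        clean = "array", noisy = "array"))

setValidity("TimeSeriesSet", function(object) {
  msg <- character()
  d <- dim(object@clean)
  if (length(d) != 3L) msg <- c(msg, "clean must be a 3-d array (sets x times x genes)")
  else {
    if (d[2L] != length(object@times)) msg <- c(msg, "time dimension mismatch")
    if (d[3L] != length(object@genes)) msg <- c(msg, "gene dimension mismatch")
    if (!identical(dim(object@noisy), d)) msg <- c(msg, "noisy and clean shapes differ")
    if (any(!is.finite(object@clean)) || any(object@clean < 0))
      msg <- c(msg, "noise-free values must be finite and non-negative")
  }
  if (length(object@times) > 1L && any(diff(object@times) <= 0))
    msg <- c(msg, "times must be strictly increasing")
  if (length(msg)) msg else TRUE
})

# ---------------------------------------------------------------------------
# Annealing schedule
# ---------------------------------------------------------------------------

#' Simulated-annealing cooling schedule
#'
#' Defaults are the published constants: T_start = 1000, T_end = 0.1,
#' N_max = 1000 N proposals per temperature, geometric cooling factor
#' gamma = 0.99. \code{restartFromBest} reproduces the printed algorithm's
#' copy of the best tree into the current tree at the start of every
#' temperature epoch.
#'
#' @slot tStart,tEnd temperatures, tStart > tEnd > 0.
#' @slot nMax proposals per temperature epoch.
#' @slot gamma cooling factor in (0, 1).
#' @slot seed RNG seed (NA to leave the RNG state untouched).
#' @slot restartFromBest logical.
#' @export
setClass("AnnealSchedule",
         representation(tStart = "numeric", tEnd = "numeric", nMax = "integer",
                        gamma = "numeric", seed = "integer",
                        restartFromBest = "logical"))

setValidity("AnnealSchedule", function(object) {
  msg <- character()
  if (!(object@tStart > object@tEnd && object@tEnd > 0))
    msg <- c(msg, "need tStart > tEnd > 0")
  if (!(object@gamma > 0 && object@gamma < 1))
    msg <- c(msg, "gamma must lie in (0, 1)")
  if (object@nMax < 1L) msg <- c(msg, "nMax must be at least 1")
  if (length(msg)) msg else TRUE
})

# ---------------------------------------------------------------------------
# Inference configuration / prior knowledge
# ---------------------------------------------------------------------------

#' Prior-knowledge edge mask
#'
#' Ordered pairs that may never be inferred (\code{forbidden}) or are always
#' present (\code{forced}). Both are two-column character matrices with
#' columns regulator, target; the two sets must be disjoint.
#' @export
setClass("PriorKnowledgeMask",
         representation(forbidden = "matrix", forced = "matrix"))

setValidity("PriorKnowledgeMask", function(object) {
  key <- function(m) if (nrow(m)) paste(m[, 1L], m[, 2L], sep = "\r") else character()
  if (length(intersect(key(object@forbidden), key(object@forced))))
    return("forbidden and forced pairs must be disjoint")
  TRUE
})

#' Configuration of the bootstrap ensemble-inference stage
#'
#' @slot ng number of bootstrap networks to produce.
#' @slot method registered inference method name (default "baseline").
#' @slot threshold standardized-coefficient magnitude above which the
#'   baseline method includes a regulation.
#' @slot seed RNG seed (NA to leave the RNG state untouched).
#' @export
setClass("InferenceConfig",
         representation(ng = "integer", method = "character",
                        threshold = "numeric", seed = "integer"))

setValidity("InferenceConfig", function(object) {
  if (object@ng < 1L) return("ng must be at least 1")
  TRUE
})

# ---------------------------------------------------------------------------
# Evaluation result
# ---------------------------------------------------------------------------

#' Recall-precision evaluation of a scored network
#'
#' One curve point per distinct confidence value (edges enter in whole
#' tie-blocks), directed comparison, self-regulations disregarded.
#'
#' @slot curve data.frame with columns threshold, tp, fp, fn, recall,
#'   precision.
#' @slot aurpc area under the recall-precision curve.
#' @slot nTrue number of true regulations (constant TP + FN).
#' @export
setClass("EvaluationResult",
         representation(curve = "data.frame", aurpc = "numeric",
                        nTrue = "integer"))

#' Run configuration for the command-line workflow
#'
#' Round-trips unchanged through a YAML file; one master seed determines
#' every stage seed (simulate = seed + 1000, infer = seed + 2000,
#' hierarchy = seed + 3000).
#' @export
setClass("RunConfig",
         representation(seed = "integer", ng = "integer", eta = "numeric",
                        nSets = "integer", nObs = "integer", dt = "numeric",
                        noiseFraction = "numeric", threshold = "numeric",
                        tStart = "numeric", tEnd = "numeric",
                        nMaxFactor = "integer", gamma = "numeric",
                        logLevel = "character"))
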