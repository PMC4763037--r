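# The hierarchical random graph model H(D, theta): per-node edge counts
# over an ensemble, closed-form maximum-likelihood theta, the
# log-likelihood of a dendrogram given an ensemble, edge probabilities and
# generative sampling.

#' Construct an HRG model
#'
#' @param tree a \linkS4class{Dendrogram}
#' @param theta numeric vector of per-internal-node probabilities (position
#'   i for internal node N + i), each in [0, 1]
#' @param ng number of networks the model was fitted to (optional)
#' @return an \linkS4class{HRGModel}
#' @export
HRGModel <- function(tree, theta, ng = NA_integer_) {
  obj <- new("HRGModel", tree = tree, theta = as.numeric(theta),
             ng = as.integer(ng))
  validObject(obj)
  obj
}

.checkTreeEnsemble <- function(tree, ens) {
  if (!setequal(tree@genes, ens@genes))
    stop("ensemble gene list does not match the dendrogram leaf set")
}

#' Aggregated edge counts per internal node
#'
#' E_i is the total number of edges, summed over the ensemble members,
#' between leaf pairs whose lowest common ancestor is internal node i.
#' With \code{perNetwork = TRUE} the per-member counts E_ij are returned as
#' well; their row sums equal E_i and their column sums equal the member
#' edge counts.
#'
#' @param tree a \linkS4class{Dendrogram}
#' @param ens a \linkS4class{NetworkEnsemble} over the same genes
#' @param perNetwork also return the (N-1) x N_g matrix of per-member counts
#' @return data.frame with columns node, L, R, E (and attribute
#'   \code{"perNetwork"} if requested)
#' @export
edgeCounts <- function(tree, ens, perNetwork = FALSE) {
  .checkTreeEnsemble(tree, ens)
  N <- length(tree@genes)
  sets <- nodeLeafSets(tree)
  # align ensemble weight matrix to the leaf order of the tree
  ord <- match(tree@genes, ens@genes)
  W <- ens@weights[ord, ord, drop = FALSE]
  counts <- subtreeLeafCounts(tree)
  counts$E <- vapply(counts$node, function(x) {
    sum(W[sets[[tree@leftChild[x - N]]], sets[[tree@rightChild[x - N]]]])
  }, 0)
  if (perNetwork) {
    lcaM <- pairLCAMatrix(tree)
    Eij <- matrix(0, N - 1L, ens@ng,
                  dimnames = list(node = counts$node, network = NULL))
    for (j in seq_len(ens@ng)) {
      e <- ens@members[[j]]@edges
      if (nrow(e)) {
        iu <- match(e[, 1L], tree@genes)
        iv <- match(e[, 2L], tree@genes)
        nodes <- lcaM[cbind(iu, iv)]
        tab <- table(nodes)
        Eij[as.character(names(tab)), j] <- as.numeric(tab)
      }
    }
    attr(counts, "perNetwork") <- Eij
  }
  counts
}

#' Maximum-likelihood theta for a fixed dendrogram
#'
#' The likelihood of the ensemble factorizes over internal nodes, and the
#' optimum is attained in closed form at
#' theta_i = E_i / (N_g L_i R_i): the observed edge fraction among the
#' L_i R_i pairs governed by node i, across the N_g networks.
#'
#' @param tree a \linkS4class{Dendrogram}
#' @param ens a \linkS4class{NetworkEnsemble} over the same genes
#' @return numeric vector of length N - 1 (position i for node N + i)
#' @export
fitTheta <- function(tree, ens) {
  counts <- edgeCounts(tree, ens)
  counts$E / (ens@ng * counts$L * counts$R)
}

.nodeLogLik <- function(E, M) {
  # E edges observed out of M = Ng * L * R slots; theta = E / M;
  # 0 * log 0 := 0 so a perfectly consistent node contributes 0
  th <- E / M
  out <- numeric(length(E))
  pos <- E > 0
  out[pos] <- out[pos] + E[pos] * log(th[pos])
  rem <- (M - E) > 0
  out[rem] <- out[rem] + (M - E)[rem] * log1p(-th[rem])
  out
}

#' Log-likelihood of a dendrogram given a network ensemble
#'
#' log L(D, theta) = sum_j sum_i [E_ij log theta_i +
#' (L_i R_i - E_ij) log(1 - theta_i)] with theta at its closed-form
#' maximum-likelihood value and the convention 0 log 0 = 0. Computed from
#' the aggregated counts E_i (algebraically identical, O(N^2) instead of
#' O(N^2 N_g)); always <= 0, and 0 exactly when every theta_i is 0 or 1.
#'
#' @param tree a \linkS4class{Dendrogram}
#' @param ens a \linkS4class{NetworkEnsemble} over the same genes
#' @return the maximized log-likelihood (a single non-positive number)
#' @examples
#' nets <- list(
#'   DirectedNetwork(c("a", "b", "c"), rbind(c("a", "b"), c("b", "c"))),
#'   DirectedNetwork(c("a", "b", "c"), rbind(c("a", "b"))))
#' ens <- buildEnsemble(nets)
#' tree <- Dendrogram(c("a", "b", "c"), c(2L, 1L), c(3L, 4L), 5L)
#' logLikelihood(tree, ens)  # 6 log(1/2)
#' @export
logLikelihood <- function(tree, ens) {
  counts <- edgeCounts(tree, ens)
  sum(.nodeLogLik(counts$E, ens@ng * counts$L * counts$R))
}

#' Fit an HRG model at a fixed dendrogram
#'
#' @param tree a \linkS4class{Dendrogram}
#' @param ens a \linkS4class{NetworkEnsemble}
#' @return an \linkS4class{HRGModel} with theta from \code{\link{fitTheta}}
#' @export
fitHRGModel <- function(tree, ens) {
  HRGModel(tree, fitTheta(tree, ens), ng = ens@ng)
}

#' Edge probability of a gene pair under an HRG model
#'
#' Theta at the pair's lowest common ancestor; symmetric in its arguments,
#' undefined for a gene with itself.
#'
#' @param model an \linkS4class{HRGModel}
#' @param u,v distinct gene labels
#' @return a probability
#' @export
edgeProbability <- function(model, u, v) {
  if (identical(u, v)) stop("edge probability is undefined for self-regulation")
  node <- lca(model@tree, u, v)
  model@theta[node - length(model@tree@genes)]
}

#' Hierarchy probability matrix p^H
#'
#' Symmetric matrix of theta at each pair's LCA, indexed like the
#' bootstrap-probability matrix ([target, regulator]; the hierarchy is
#' direction-blind so the orientation is immaterial). Diagonal entries are
#' NA: the hierarchy assigns no probability to self-regulation.
#'
#' @param model an \linkS4class{HRGModel}
#' @param genes optional gene order for rows/columns (default: tree leaf order)
#' @return N x N numeric matrix
#' @export
hierarchyProbabilities <- function(model, genes = NULL) {
  tree <- model@tree
  if (is.null(genes)) genes <- tree@genes
  lcaM <- pairLCAMatrix(tree)
  N <- length(tree@genes)
  P <- matrix(model@theta[lcaM - N], N, N,
              dimnames = list(target = tree@genes, regulator = tree@genes))
  diag(P) <- NA_real_
  ord <- match(genes, tree@genes)
  if (anyNA(ord)) stop("requested genes are not leaves of the model")
  P[ord, ord, drop = FALSE]
}

#' Sample a network from an HRG model
#'
#' Generative use of H(D, theta): each unordered gene pair becomes an edge
#' independently with probability theta at its lowest common ancestor.
#' Uses the R random number generator.
#'
#' @param model an \linkS4class{HRGModel}
#' @return an \linkS4class{UndirectedNetwork}
#' @export
sampleNetwork <- function(model) {
  tree <- model@tree
  g <- tree@genes
  N <- length(g)
  lcaM <- pairLCAMatrix(tree)
  ut <- which(upper.tri(lcaM), arr.ind = TRUE)
  p <- model@theta[lcaM[ut] - N]
  keep <- runif(nrow(ut)) < p
  UndirectedNetwork(g, cbind(g[ut[keep, 1L]], g[ut[keep, 2L]]))
}

#' Sample an ensemble from an HRG model
#'
#' @param model an \linkS4class{HRGModel}
#' @param ng number of independent networks to draw
#' @return a \linkS4class{NetworkEnsemble}
#' @export
sampleEnsemble <- function(model, ng) {
  buildEnsemble(replicate(ng, sampleNetwork(model), simplify = FALSE))
}
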