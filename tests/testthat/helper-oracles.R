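# Fixtures and independent oracles used across the suite. Oracles are
# deliberately written as naive, direct computations so they share no code
# path with the package implementation they check.

# the three-gene worked ensemble: G1 = {a-b, b-c}, G2 = {a-b}
toyEnsemble <- function() {
  buildEnsemble(list(
    DirectedNetwork(c("a", "b", "c"), rbind(c("a", "b"), c("b", "c"))),
    DirectedNetwork(c("a", "b", "c"), rbind(c("a", "b")))))
}

# tree (a,(b,c)) over genes a, b, c: node 4 = cherry (b,c), node 5 = root
toyTreeABC <- function() Dendrogram(c("a", "b", "c"), c(2L, 1L), c(3L, 4L), 5L)
# tree (b,(a,c)): cherry (a,c)
toyTreeBAC <- function() Dendrogram(c("a", "b", "c"), c(1L, 4L), c(3L, 2L), 5L)

# brute-force LCA: deepest node among the intersection of full ancestor
# paths
bruteLCA <- function(tree, u, v) {
  path <- function(leaf) {
    x <- match(leaf, genes(tree))
    out <- integer()
    while (x != 0L) { out <- c(out, x); x <- tree@parent[x] }
    out
  }
  depth <- function(x) {
    d <- 0L
    while (tree@parent[x] != 0L) { d <- d + 1L; x <- tree@parent[x] }
    d
  }
  common <- intersect(path(u), path(v))
  common[which.max(vapply(common, depth, 1L))]
}

# per-network double-sum log-likelihood (the definition, O(N^2 Ng)),
# independent of the package's aggregated computation
bruteLogLik <- function(tree, ens) {
  N <- length(genes(tree))
  lcaM <- pairLCAMatrix(tree)
  counts <- subtreeLeafCounts(tree)
  # theta per the closed form, from scratch
  Etot <- setNames(numeric(N - 1L), counts$node)
  perNet <- matrix(0, N - 1L, nNetworks(ens), dimnames = list(counts$node, NULL))
  for (j in seq_len(nNetworks(ens))) {
    e <- edges(memberNetworks(ens)[[j]])
    if (nrow(e)) {
      iu <- match(e[, 1L], genes(tree))
      iv <- match(e[, 2L], genes(tree))
      for (k in seq_len(nrow(e))) {
        node <- as.character(lcaM[iu[k], iv[k]])
        perNet[node, j] <- perNet[node, j] + 1
        Etot[node] <- Etot[node] + 1
      }
    }
  }
  th <- Etot / (nNetworks(ens) * counts$L * counts$R)
  ll <- 0
  for (j in seq_len(nNetworks(ens))) {
    for (i in seq_len(N - 1L)) {
      LR <- counts$L[i] * counts$R[i]
      Eij <- perNet[i, j]
      if (Eij > 0) ll <- ll + Eij * log(th[i])
      if (LR - Eij > 0) ll <- ll + (LR - Eij) * log(1 - th[i])
    }
  }
  unname(ll)
}

# log-likelihood at an arbitrary theta vector (not the MLE), used by the
# optimality grid test
logLikAtTheta <- function(tree, ens, th) {
  counts <- edgeCounts(tree, ens)
  M <- nNetworks(ens) * counts$L * counts$R
  E <- counts$E
  term <- function(cnt, p) ifelse(cnt > 0, cnt * log(p), 0)
  sum(term(E, th) + term(M - E, 1 - th))
}

# naive recall-precision area: explicit re-count at every distinct
# threshold, best precision per achieved positive recall, horizontal
# extension from the smallest positive recall down to zero, trapezoids
brutePR <- function(score, isTrue) {
  nTrue <- sum(isTrue)
  pts <- lapply(sort(unique(score), decreasing = TRUE), function(thr) {
    pred <- score >= thr
    tp <- sum(pred & isTrue)
    c(recall = tp / nTrue, precision = if (sum(pred)) tp / sum(pred) else 1)
  })
  pts <- do.call(rbind, pts)
  recalls <- sort(unique(pts[pts[, "recall"] > 0, "recall"]))
  if (!length(recalls)) return(0)
  best <- vapply(recalls,
                 function(r) max(pts[pts[, "recall"] == r, "precision"]), 0)
  area <- recalls[1L] * best[1L]  # horizontal extension to recall 0
  for (k in seq_along(recalls)[-1L]) {
    area <- area +
      (recalls[k] - recalls[k - 1L]) * (best[k] + best[k - 1L]) / 2
  }
  unname(area)
}

# BFS closure of the move set over canonical shapes
closureShapes <- function(start) {
  seen <- new.env(parent = emptyenv())
  key0 <- hrgnet:::shapeKey(start)
  assign(key0, TRUE, envir = seen)
  queue <- list(start)
  while (length(queue)) {
    tree <- queue[[1L]]
    queue <- queue[-1L]
    for (nb in neighborTrees(tree)) {
      k <- hrgnet:::shapeKey(nb)
      if (!exists(k, envir = seen, inherits = FALSE)) {
        assign(k, TRUE, envir = seen)
        queue <- c(queue, list(nb))
      }
    }
  }
  length(ls(seen))
}

# perfectly balanced 16-leaf dendrogram with two theta levels: tight
# modules (subtrees of <= 4 leaves, theta 0.9) joined loosely (theta 0.05)
plantedModel16 <- function() {
  genes <- sprintf("g%02d", 1:16)
  lc <- rc <- integer(15L)
  # leaves 1..16; internal 17..31; build bottom-up level by level
  nodes <- 1:16
  nextId <- 17L
  while (length(nodes) > 1L) {
    upper <- integer(0)
    for (k in seq(1L, length(nodes), by = 2L)) {
      lc[nextId - 16L] <- nodes[k]
      rc[nextId - 16L] <- nodes[k + 1L]
      upper <- c(upper, nextId)
      nextId <- nextId + 1L
    }
    nodes <- upper
  }
  tree <- Dendrogram(genes, lc, rc, 31L)
  counts <- subtreeLeafCounts(tree)
  th <- ifelse(counts$L + counts$R <= 4L, 0.9, 0.05)
  HRGModel(tree, th)
}
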