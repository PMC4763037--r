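# Rooted binary dendrograms: construction, traversal, LCA, random
# generation and annotated-Newick IO.
#
# Node numbering: leaves 1..N in gene-list order, internal nodes
# N+1..2N-1. Child and theta vectors are indexed by (internal id - N).

.newDendrogram <- function(genes, leftChild, rightChild, root) {
  N <- length(genes)
  parent <- integer(2L * N - 1L)
  for (i in seq_len(N - 1L)) {
    parent[leftChild[i]] <- N + i
    parent[rightChild[i]] <- N + i
  }
  parent[root] <- 0L
  new("Dendrogram", genes = genes, leftChild = as.integer(leftChild),
      rightChild = as.integer(rightChild), parent = parent,
      root = as.integer(root))
}

#' Build a dendrogram from child vectors
#'
#' @param genes leaf labels (leaf ids 1..N follow this order).
#' @param leftChild,rightChild integer vectors of length N - 1 giving the
#'   children of internal nodes N+1..2N-1.
#' @param root id of the root internal node.
#' @return a validated \linkS4class{Dendrogram}
#' @export
Dendrogram <- function(genes, leftChild, rightChild, root) {
  obj <- .newDendrogram(as.character(genes), leftChild, rightChild, root)
  validObject(obj)
  obj
}

#' Generate a random dendrogram
#'
#' Leaves are attached one at a time, each grafted onto a branch chosen
#' uniformly among all current branches (including above the root). Every
#' one of the (2N-3)!! leaf-labeled rooted binary shapes is produced with
#' equal probability. Uses the R random number generator.
#'
#' @param genes at least two leaf labels.
#' @return a \linkS4class{Dendrogram}
#' @examples
#' set.seed(1)
#' randomDendrogram(letters[1:5])
#' @export
randomDendrogram <- function(genes) {
  genes <- as.character(genes)
  N <- length(genes)
  if (N < 2L) stop("a dendrogram needs at least 2 leaves")
  leftChild <- rightChild <- integer(N - 1L)
  parent <- integer(2L * N - 1L)
  # start with the cherry (1, 2) at internal node N + 1
  leftChild[1L] <- 1L; rightChild[1L] <- 2L
  parent[1L] <- parent[2L] <- N + 1L
  root <- N + 1L
  if (N > 2L) {
    nodes <- c(1L, 2L, N + 1L)  # nodes of the current subtree
    for (k in 3:N) {
      x <- nodes[floor(runif(1L) * length(nodes)) + 1L]
      newInt <- N + k - 1L
      if (x == root) {
        root <- newInt
      } else {
        p <- parent[x]
        if (leftChild[p - N] == x) leftChild[p - N] <- newInt
        else rightChild[p - N] <- newInt
        parent[newInt] <- p
      }
      leftChild[newInt - N] <- x
      rightChild[newInt - N] <- k
      parent[x] <- newInt
      parent[k] <- newInt
      nodes <- c(nodes, k, newInt)
    }
  }
  .newDendrogram(genes, leftChild, rightChild, root)
}

.children <- function(tree, node) {
  N <- length(tree@genes)
  c(tree@leftChild[node - N], tree@rightChild[node - N])
}

#' Leaf ids under each node
#'
#' @param tree a \linkS4class{Dendrogram}
#' @return list of integer vectors, one per node id 1..2N-1
#' @keywords internal
nodeLeafSets <- function(tree) {
  N <- length(tree@genes)
  M <- 2L * N - 1L
  out <- vector("list", M)
  for (i in seq_len(N)) out[[i]] <- i
  # process internal nodes children-first (post-order via DFS from the root)
  order <- integer(N - 1L)
  stack <- tree@root
  k <- 0L
  while (length(stack)) {
    x <- stack[length(stack)]; stack <- stack[-length(stack)]
    k <- k + 1L
    order[k] <- x
    ch <- .children(tree, x)
    stack <- c(stack, ch[ch > N])
  }
  for (x in rev(order)) {
    ch <- .children(tree, x)
    out[[x]] <- c(out[[ch[1L]]], out[[ch[2L]]])
  }
  out
}

#' Lowest common ancestor of two leaves
#'
#' @param tree a \linkS4class{Dendrogram}
#' @param u,v distinct gene labels (leaves of the tree)
#' @return the internal node id of the deepest common ancestor
#' @export
lca <- function(tree, u, v) {
  stopifnot(is(tree, "Dendrogram"))
  if (identical(u, v)) stop("lca is undefined for a leaf with itself")
  iu <- match(u, tree@genes)
  iv <- match(v, tree@genes)
  if (is.na(iu)) stop("unknown gene: ", u)
  if (is.na(iv)) stop("unknown gene: ", v)
  anc <- integer()
  x <- iu
  while (x != 0L) { anc <- c(anc, x); x <- tree@parent[x] }
  x <- iv
  while (!(x %in% anc)) x <- tree@parent[x]
  x
}

#' Per-pair lowest common ancestors
#'
#' @param tree a \linkS4class{Dendrogram}
#' @return N x N integer matrix of internal node ids (NA on the diagonal)
#' @export
pairLCAMatrix <- function(tree) {
  N <- length(tree@genes)
  sets <- nodeLeafSets(tree)
  M <- matrix(NA_integer_, N, N, dimnames = list(tree@genes, tree@genes))
  for (node in (N + 1L):(2L * N - 1L)) {
    L <- sets[[tree@leftChild[node - N]]]
    R <- sets[[tree@rightChild[node - N]]]
    M[L, R] <- node
    M[R, L] <- node
  }
  M
}

#' Left/right subtree leaf counts per internal node
#'
#' @param tree a \linkS4class{Dendrogram}
#' @return data.frame with columns node, L, R; sum(L * R) = N(N-1)/2
#' @export
subtreeLeafCounts <- function(tree) {
  N <- length(tree@genes)
  sets <- nodeLeafSets(tree)
  nodes <- (N + 1L):(2L * N - 1L)
  data.frame(node = nodes,
             L = vapply(nodes, function(x) length(sets[[tree@leftChild[x - N]]]), 1L),
             R = vapply(nodes, function(x) length(sets[[tree@rightChild[x - N]]]), 1L))
}

# ---------------------------------------------------------------------------
# Newick
# ---------------------------------------------------------------------------

.quoteLabel <- function(x) {
  needs <- grepl("[][ \t(),:;']", x)
  x[needs] <- paste0("'", gsub("'", "''", x[needs]), "'")
  x
}

#' Plain Newick string of a dendrogram (no annotations)
#' @param tree a \linkS4class{Dendrogram}
#' @export
dendrogramNewick <- function(tree) {
  N <- length(tree@genes)
  rec <- function(x) {
    if (x <= N) return(.quoteLabel(tree@genes[x]))
    paste0("(", rec(tree@leftChild[x - N]), ",", rec(tree@rightChild[x - N]), ")")
  }
  paste0(rec(tree@root), ";")
}

#' Write an HRG model as annotated Newick
#'
#' Internal nodes carry their edge probability as an NHX-style comment,
#' e.g. \code{(a,(b,c)[&&NHX:theta=0.5])[&&NHX:theta=0.25];}. Theta values
#' are printed with 12 significant digits so the round trip is exact to
#' that precision.
#'
#' @param model an \linkS4class{HRGModel}
#' @param path optional output file; if NULL the string is returned
#' @return the Newick string (invisibly when written to a file)
#' @export
writeNewickHRG <- function(model, path = NULL) {
  tree <- model@tree
  N <- length(tree@genes)
  rec <- function(x) {
    if (x <= N) return(.quoteLabel(tree@genes[x]))
    paste0("(", rec(tree@leftChild[x - N]), ",", rec(tree@rightChild[x - N]),
           ")[&&NHX:theta=", sprintf("%.12g", model@theta[x - N]), "]")
  }
  s <- paste0(rec(tree@root), ";")
  if (is.null(path)) return(s)
  writeLines(s, path)
  invisible(s)
}

#' Parse an annotated Newick string or file into an HRG model
#'
#' Accepts the format written by \code{\link{writeNewickHRG}}: rooted,
#' strictly binary, leaf labels (optionally single-quoted), internal nodes
#' annotated with \code{[&&NHX:theta=...]}. Internal nodes lacking a theta
#' annotation get theta = 0. Malformed input raises an error naming the
#' character position.
#'
#' @param text Newick string (used if \code{path} is NULL)
#' @param path file to read
#' @param genes optional gene order for the leaf ids; defaults to the order
#'   of appearance in the string
#' @return an \linkS4class{HRGModel}
#' @export
readNewickHRG <- function(text = NULL, path = NULL, genes = NULL) {
  if (!is.null(path)) text <- paste(readLines(path, warn = FALSE), collapse = "")
  if (is.null(text)) stop("either text or path must be given")
  s <- text
  pos <- 1L
  n <- nchar(s)
  peek <- function() if (pos > n) "" else substr(s, pos, pos)
  advance <- function() pos <<- pos + 1L
  fail <- function(what) stop(sprintf("Newick parse error at position %d: %s", pos, what))
  skipWS <- function() while (peek() %in% c(" ", "\t", "\n", "\r")) advance()

  readLabel <- function() {
    skipWS()
    if (peek() == "'") {
      advance()
      out <- character()
      repeat {
        if (pos > n) fail("unterminated quoted label")
        ch <- peek(); advance()
        if (ch == "'") {
          if (peek() == "'") { out <- c(out, "'"); advance() } else break
        } else out <- c(out, ch)
      }
      paste(out, collapse = "")
    } else {
      start <- pos
      while (pos <= n && !(peek() %in% c("(", ")", ",", ";", "[", ":"))) advance()
      lab <- trimws(substr(s, start, pos - 1L))
      if (!nchar(lab)) fail("expected a leaf label")
      lab
    }
  }
  readAnnotation <- function() {
    skipWS()
    if (peek() != "[") return(NA_real_)
    start <- pos
    while (pos <= n && peek() != "]") advance()
    if (pos > n) fail("unterminated [ annotation")
    ann <- substr(s, start + 1L, pos - 1L)
    advance()
    m <- regmatches(ann, regexec("theta=([-+0-9.eE]+)", ann))[[1L]]
    if (length(m) == 2L) as.numeric(m[2L]) else NA_real_
  }

  skipBranchLength <- function() {
    skipWS()
    if (peek() == ":") {
      advance()
      start <- pos
      while (pos <= n && grepl("[-+0-9.eE]", peek())) advance()
      if (pos == start) fail("expected a branch length after ':'")
    }
  }

  # recursive descent; nodes collected as nested lists. Branch lengths are
  # tolerated (and ignored: the model carries no lengths).
  parseClade <- function() {
    skipWS()
    if (peek() == "(") {
      advance()
      left <- parseClade()
      skipWS()
      if (peek() != ",") fail("expected ',' (dendrograms are strictly binary)")
      advance()
      right <- parseClade()
      skipWS()
      if (peek() != ")") fail("expected ')'")
      advance()
      skipWS()
      if (!(peek() %in% c("[", ":", ",", ")", ";", ""))) readLabel()  # internal label, ignored
      th <- readAnnotation()
      skipBranchLength()
      list(kind = "internal", left = left, right = right, theta = th)
    } else {
      lab <- readLabel()
      readAnnotation()  # tolerated, ignored on leaves
      skipBranchLength()
      list(kind = "leaf", label = lab)
    }
  }

  node <- parseClade()
  skipWS()
  if (peek() != ";") fail("expected terminating ';'")
  advance()
  skipWS()
  if (pos <= n) fail("trailing characters after ';'")
  if (node$kind != "internal") fail("a dendrogram must have at least two leaves")

  labs <- character()
  collect <- function(nd) {
    if (nd$kind == "leaf") labs <<- c(labs, nd$label)
    else { collect(nd$left); collect(nd$right) }
  }
  collect(node)
  if (anyDuplicated(labs)) stop("duplicate leaf labels in Newick input")
  if (is.null(genes)) genes <- labs
  if (!setequal(genes, labs)) stop("Newick leaves do not match the given gene list")

  N <- length(genes)
  leftChild <- rightChild <- integer(N - 1L)
  thetaVec <- numeric(N - 1L)
  nextInt <- 0L
  build <- function(nd) {
    if (nd$kind == "leaf") return(match(nd$label, genes))
    nextInt <<- nextInt + 1L
    me <- N + nextInt
    lc <- build(nd$left)
    rc <- build(nd$right)
    leftChild[me - N] <<- lc
    rightChild[me - N] <<- rc
    thetaVec[me - N] <<- if (is.na(nd$theta)) 0 else nd$theta
    me
  }
  root <- build(node)
  tree <- Dendrogram(genes, leftChild, rightChild, root)
  new("HRGModel", tree = tree, theta = thetaVec, ng = NA_integer_)
}

# canonical shape key: label-sorted nested parentheses, used by the move
# closure tests and the exhaustive enumeration table
shapeKey <- function(tree) {
  N <- length(tree@genes)
  rec <- function(x) {
    if (x <= N) return(tree@genes[x])
    a <- rec(tree@leftChild[x - N])
    b <- rec(tree@rightChild[x - N])
    if (a > b) { tmp <- a; a <- b; b <- tmp }
    paste0("(", a, ",", b, ")")
  }
  rec(tree@root)
}
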