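# Directed/undirected network constructors, the symmetrizing transformations
# that prepare inferred networks for hierarchy detection, and plain-text IO.
#
# Orientation convention used throughout the package: a regulation is the
# ordered pair (regulator m, target n); matrices over ordered pairs are
# indexed [target, regulator], so entry [n, m] is "regulation of gene n by
# gene m". Adjacency-matrix files follow the same convention (row = target,
# column = regulator).

.pairKey <- function(a, b) paste(a, b, sep = "\r")

.asPairMatrix <- function(x, what = "regulations") {
  if (is.null(x) || (is.matrix(x) && nrow(x) == 0L) ||
      (is.data.frame(x) && nrow(x) == 0L) || length(x) == 0L) {
    m <- matrix(character(), 0L, 2L)
  } else if (is.data.frame(x)) {
    m <- as.matrix(x[, 1:2])
  } else if (is.matrix(x)) {
    m <- x[, 1:2, drop = FALSE]
  } else {
    stop(what, " must be a two-column matrix or data.frame")
  }
  mode(m) <- "character"
  dimnames(m) <- NULL
  m
}

#' Construct a directed gene regulatory network
#'
#' @param genes character vector of unique gene identifiers.
#' @param regulations two-column matrix or data.frame of (regulator, target)
#'   pairs; duplicates are dropped (set semantics). Self-regulations are
#'   allowed here.
#' @return a \linkS4class{DirectedNetwork}
#' @examples
#' net <- DirectedNetwork(c("a", "b", "c"), rbind(c("a", "b"), c("b", "c")))
#' regulations(net)
#' @export
DirectedNetwork <- function(genes, regulations = NULL) {
  reg <- unique(.asPairMatrix(regulations))
  colnames(reg) <- c("regulator", "target")
  new("DirectedNetwork", genes = as.character(genes), regulations = reg)
}

#' Construct an undirected network
#'
#' Pairs are canonicalized to gene-list order; duplicates (in either
#' orientation) collapse. Self-pairs are an error.
#'
#' @param genes character vector of unique gene identifiers.
#' @param edges two-column matrix or data.frame of unordered pairs.
#' @return an \linkS4class{UndirectedNetwork}
#' @export
UndirectedNetwork <- function(genes, edges = NULL) {
  genes <- as.character(genes)
  e <- .asPairMatrix(edges, "edges")
  if (nrow(e)) {
    i1 <- match(e[, 1L], genes)
    i2 <- match(e[, 2L], genes)
    if (anyNA(i1) || anyNA(i2)) stop("edges refer to genes outside the gene list")
    if (any(i1 == i2)) stop("self-edges are not allowed in an undirected network")
    swap <- i1 > i2
    e[swap, ] <- e[swap, c(2L, 1L), drop = FALSE]
    e <- unique(e)
  }
  colnames(e) <- c("gene1", "gene2")
  new("UndirectedNetwork", genes = genes, edges = e)
}

#' Symmetrize a directed network for hierarchy detection
#'
#' An undirected edge {n, m} is present iff the directed network contains
#' m -> n, n -> m, or both; self-regulations are removed, because the
#' hierarchy detection cannot represent them.
#'
#' @param net a \linkS4class{DirectedNetwork}
#' @return an \linkS4class{UndirectedNetwork} over the same gene list
#' @examples
#' net <- DirectedNetwork(c("a", "b"), rbind(c("a", "b"), c("b", "a"), c("a", "a")))
#' edges(undirect(net))  # the single edge {a, b}
#' @export
undirect <- function(net) {
  stopifnot(is(net, "DirectedNetwork"))
  r <- net@regulations
  r <- r[r[, 1L] != r[, 2L], , drop = FALSE]
  UndirectedNetwork(net@genes, r)
}

#' Aggregate directed networks into an ensemble
#'
#' Each input is symmetrized with \code{\link{undirect}}; the ensemble
#' records all members plus the per-pair count of members containing each
#' edge.
#'
#' @param nets list of \linkS4class{DirectedNetwork} (or already
#'   \linkS4class{UndirectedNetwork}) objects sharing one gene list.
#' @return a \linkS4class{NetworkEnsemble}
#' @export
buildEnsemble <- function(nets) {
  if (!length(nets)) stop("cannot build an ensemble from zero networks")
  g <- genes(nets[[1L]])
  members <- vector("list", length(nets))
  for (k in seq_along(nets)) {
    if (!identical(genes(nets[[k]]), g))
      stop(sprintf("network %d does not share the common gene list", k))
    members[[k]] <- if (is(nets[[k]], "DirectedNetwork")) undirect(nets[[k]]) else nets[[k]]
  }
  N <- length(g)
  W <- matrix(0, N, N, dimnames = list(g, g))
  for (m in members) {
    e <- m@edges
    if (nrow(e)) {
      i <- match(e[, 1L], g); j <- match(e[, 2L], g)
      W[cbind(i, j)] <- W[cbind(i, j)] + 1
      W[cbind(j, i)] <- W[cbind(j, i)] + 1
    }
  }
  new("NetworkEnsemble", genes = g, members = members, weights = W,
      ng = length(members))
}

#' Bootstrap regulation probabilities p^B
#'
#' For every ordered pair, the fraction of networks containing the
#' regulation m -> n. The result is indexed [target, regulator]: entry
#' [n, m] is the bootstrap probability of the regulation of gene n by gene
#' m. Values lie on the grid {0, 1/N_g, ..., 1}. Diagonal entries
#' (self-regulation) are computed but excluded from hierarchy detection and
#' evaluation downstream.
#'
#' @param nets non-empty list of \linkS4class{DirectedNetwork} sharing one
#'   gene list.
#' @return N x N numeric matrix with dimnames (targets, regulators)
#' @export
bootstrapProbabilities <- function(nets) {
  if (!length(nets)) stop("need at least one network to compute bootstrap probabilities")
  g <- genes(nets[[1L]])
  N <- length(g)
  P <- matrix(0, N, N, dimnames = list(target = g, regulator = g))
  for (k in seq_along(nets)) {
    net <- nets[[k]]
    if (!identical(genes(net), g))
      stop(sprintf("network %d does not share the common gene list", k))
    r <- net@regulations
    if (nrow(r)) {
      m <- match(r[, 1L], g)  # regulator
      n <- match(r[, 2L], g)  # target
      P[cbind(n, m)] <- P[cbind(n, m)] + 1
    }
  }
  P / length(nets)
}

# ---------------------------------------------------------------------------
# Plain-text readers and writers
# ---------------------------------------------------------------------------

.hasHeader <- function(path) {
  first <- strsplit(trimws(readLines(path, n = 1L)), "[ \t]+")[[1L]]
  length(first) >= 2L &&
    tolower(first[1L]) %in% c("regulator", "source", "from", "gene1")
}

#' Read a directed network from a whitespace/tab-separated edge list
#'
#' Lines are "regulator target [weight]"; an optional header line starting
#' with "regulator"/"source"/"from" is skipped, as are comments (#) and
#' blank lines. A third numeric column, if present, is ignored (binary
#' presence semantics). Genes default to the union of endpoints, in order
#' of first appearance.
#'
#' @param path file path.
#' @param genes optional gene list (required to represent isolated genes).
#' @return a \linkS4class{DirectedNetwork}
#' @export
readEdgeList <- function(path, genes = NULL) {
  if (!file.exists(path)) stop("edge-list file not found: ", path)
  tab <- tryCatch(
    read.table(path, header = .hasHeader(path), colClasses = "character",
               comment.char = "#", blank.lines.skip = TRUE),
    error = function(e) data.frame())
  if (!nrow(tab)) {
    if (is.null(genes)) stop("empty edge list and no gene list given: ", path)
    return(DirectedNetwork(genes))
  }
  if (ncol(tab) < 2L) stop("edge list must have at least two columns: ", path)
  reg <- as.matrix(tab[, 1:2])
  if (is.null(genes)) genes <- unique(c(t(reg)))
  DirectedNetwork(genes, reg)
}

#' Write a directed network as a TSV edge list
#' @param net a \linkS4class{DirectedNetwork}
#' @param path output file
#' @export
writeEdgeList <- function(net, path) {
  stopifnot(is(net, "DirectedNetwork"))
  df <- as.data.frame(net@regulations, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an adjacency matrix (row = target, column = regulator)
#'
#' The file is a TSV with row and column names; entry [n, m] non-zero means
#' gene n (row) is regulated by gene m (column).
#'
#' @param path file path
#' @return a \linkS4class{DirectedNetwork}
#' @export
readAdjacencyMatrix <- function(path) {
  if (!file.exists(path)) stop("adjacency file not found: ", path)
  M <- as.matrix(read.table(path, header = TRUE, row.names = 1L,
                            check.names = FALSE))
  if (nrow(M) != ncol(M) || !identical(rownames(M), colnames(M)))
    stop("adjacency matrix must be square with matching row/column names")
  g <- rownames(M)
  idx <- which(M != 0, arr.ind = TRUE)
  reg <- cbind(regulator = g[idx[, "col"]], target = g[idx[, "row"]])
  DirectedNetwork(g, reg)
}

#' Write a directed network as an adjacency matrix (row = target,
#' column = regulator)
#' @param net a \linkS4class{DirectedNetwork}
#' @param path output file
#' @export
writeAdjacencyMatrix <- function(net, path) {
  g <- net@genes
  N <- length(g)
  M <- matrix(0L, N, N, dimnames = list(g, g))
  r <- net@regulations
  if (nrow(r)) M[cbind(match(r[, 2L], g), match(r[, 1L], g))] <- 1L
  write.table(M, path, sep = "\t", quote = FALSE, col.names = NA)
  invisible(path)
}

#' Read a DREAM-style gold standard ("regulator target 1" triples)
#'
#' Lines whose third field is 1 are regulations; 0 lines are explicit
#' non-edges and only contribute their genes to the gene list.
#'
#' @param path file path
#' @param genes optional gene list
#' @return a \linkS4class{DirectedNetwork}
#' @export
readGoldStandard <- function(path, genes = NULL) {
  if (!file.exists(path)) stop("gold-standard file not found: ", path)
  tab <- read.table(path, colClasses = c("character", "character", "numeric"),
                    col.names = c("regulator", "target", "present"))
  if (is.null(genes)) genes <- unique(c(tab$regulator, tab$target))
  DirectedNetwork(genes, tab[tab$present != 0, 1:2])
}

#' Write a directed network as DREAM-style triples
#' @param net a \linkS4class{DirectedNetwork}
#' @param path output file
#' @param allPairs also write 0-lines for absent ordered pairs
#' @export
writeGoldStandard <- function(net, path, allPairs = FALSE) {
  r <- net@regulations
  if (allPairs) {
    g <- net@genes
    grid <- expand.grid(regulator = g, target = g, stringsAsFactors = FALSE)
    grid <- grid[grid$regulator != grid$target, ]
    present <- .pairKey(grid$regulator, grid$target) %in% .pairKey(r[, 1L], r[, 2L])
    out <- data.frame(grid, present = as.integer(present))
  } else {
    out <- data.frame(regulator = r[, 1L], target = r[, 2L],
                      present = rep(1L, nrow(r)))
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read an ensemble of directed networks
#'
#' Either a directory of edge-list files (one network per file, sorted by
#' file name) or a single concatenated TSV with columns
#' network, regulator, target.
#'
#' @param path directory or file path
#' @param genes gene list shared by all members (recommended; otherwise the
#'   union over all files is used)
#' @return list of \linkS4class{DirectedNetwork}
#' @export
readEnsemble <- function(path, genes = NULL) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.(tsv|txt)$", full.names = TRUE))
    if (!length(files)) stop("no network files found in ", path)
    if (is.null(genes)) {
      genes <- unique(unlist(lapply(files, function(f) {
        tab <- tryCatch(
          read.table(f, header = .hasHeader(f), colClasses = "character",
                     comment.char = "#"),
          error = function(e) data.frame())
        if (nrow(tab)) c(t(as.matrix(tab[, 1:2]))) else character()
      })))
    }
    lapply(files, readEdgeList, genes = genes)
  } else {
    if (!file.exists(path)) stop("ensemble path not found: ", path)
    tab <- read.table(path, header = .hasHeaderEnsemble(path),
                      colClasses = "character", comment.char = "#")
    if (ncol(tab) < 3L) stop("concatenated ensemble file needs columns network, regulator, target")
    if (is.null(genes)) genes <- unique(c(tab[[2L]], tab[[3L]]))
    lapply(split(tab, factor(tab[[1L]], levels = unique(tab[[1L]]))),
           function(d) DirectedNetwork(genes, as.matrix(d[, 2:3])))
  }
}

.hasHeaderEnsemble <- function(path) {
  first <- strsplit(trimws(readLines(path, n = 1L)), "[ \t]+")[[1L]]
  length(first) >= 3L && tolower(first[1L]) %in% c("network", "net", "index")
}

#' Write an ensemble of directed networks to a directory of edge lists
#' @param nets list of \linkS4class{DirectedNetwork}
#' @param dir output directory (created if needed)
#' @return the directory path
#' @export
writeEnsemble <- function(nets, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  width <- max(4L, nchar(length(nets)))
  for (k in seq_along(nets)) {
    writeEdgeList(nets[[k]],
                  file.path(dir, sprintf(paste0("network_%0", width, "d.tsv"), k)))
  }
  invisible(dir)
}
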