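# Generics, accessors and show methods.

#' Gene identifiers of an object
#' @param x an object carrying a gene list
#' @return character vector of gene labels
#' @export
setGeneric("genes", function(x) standardGeneric("genes"))

#' Number of genes
#' @param x an object carrying a gene list
#' @export
setGeneric("nGenes", function(x) standardGeneric("nGenes"))

setMethod("genes", "DirectedNetwork", function(x) x@genes)
setMethod("genes", "UndirectedNetwork", function(x) x@genes)
setMethod("genes", "NetworkEnsemble", function(x) x@genes)
setMethod("genes", "Dendrogram", function(x) x@genes)
setMethod("genes", "HRGModel", function(x) x@tree@genes)
setMethod("genes", "ConfidenceMatrix", function(x) x@genes)
setMethod("genes", "SSystemModel", function(x) x@genes)
setMethod("genes", "TimeSeriesSet", function(x) x@genes)

setMethod("nGenes", "ANY", function(x) length(genes(x)))

#' Regulations of a directed network
#' @param x a \linkS4class{DirectedNetwork}
#' @return two-column character matrix (regulator, target)
#' @export
setGeneric("regulations", function(x) standardGeneric("regulations"))
setMethod("regulations", "DirectedNetwork", function(x) x@regulations)

#' Edges of an undirected network
#' @param x an \linkS4class{UndirectedNetwork}
#' @return two-column character matrix of unordered pairs
#' @export
setGeneric("edges", function(x) standardGeneric("edges"))
setMethod("edges", "UndirectedNetwork", function(x) x@edges)

#' Number of member networks in an ensemble
#' @param x a \linkS4class{NetworkEnsemble}
#' @export
setGeneric("nNetworks", function(x) standardGeneric("nNetworks"))
setMethod("nNetworks", "NetworkEnsemble", function(x) x@ng)

#' Aggregated edge-weight matrix of an ensemble
#'
#' Symmetric matrix counting, for every unordered gene pair, how many
#' member networks contain the edge.
#' @param x a \linkS4class{NetworkEnsemble}
#' @export
setGeneric("edgeWeights", function(x) standardGeneric("edgeWeights"))
setMethod("edgeWeights", "NetworkEnsemble", function(x) x@weights)

#' Member networks of an ensemble
#' @param x a \linkS4class{NetworkEnsemble}
#' @export
setGeneric("memberNetworks", function(x) standardGeneric("memberNetworks"))
setMethod("memberNetworks", "NetworkEnsemble", function(x) x@members)

#' Dendrogram of a fitted model
#' @param x an \linkS4class{HRGModel}
#' @export
setGeneric("hrgTree", function(x) standardGeneric("hrgTree"))
setMethod("hrgTree", "HRGModel", function(x) x@tree)

#' Internal-node edge probabilities of a model
#' @param x an \linkS4class{HRGModel}
#' @return numeric vector, entry i for internal node N + i
#' @export
setGeneric("theta", function(x) standardGeneric("theta"))
setMethod("theta", "HRGModel", function(x) x@theta)

#' Combined confidence matrix
#' @param x a \linkS4class{ConfidenceMatrix}
#' @export
setGeneric("combinedConfidence", function(x) standardGeneric("combinedConfidence"))
setMethod("combinedConfidence", "ConfidenceMatrix", function(x) x@combined)

#' Observation times
#' @param x a \linkS4class{TimeSeriesSet}
#' @export
setGeneric("timePoints", function(x) standardGeneric("timePoints"))
setMethod("timePoints", "TimeSeriesSet", function(x) x@times)

#' Noise-free expression values
#' @param x a \linkS4class{TimeSeriesSet}
#' @return array of dimension sets x times x genes
#' @export
setGeneric("cleanValues", function(x) standardGeneric("cleanValues"))
setMethod("cleanValues", "TimeSeriesSet", function(x) x@clean)

#' Noise-corrupted expression values
#' @param x a \linkS4class{TimeSeriesSet}
#' @return array of dimension sets x times x genes
#' @export
setGeneric("noisyValues", function(x) standardGeneric("noisyValues"))
setMethod("noisyValues", "TimeSeriesSet", function(x) x@noisy)

#' Recall-precision curve of an evaluation
#' @param x an \linkS4class{EvaluationResult}
#' @export
setGeneric("rpCurve", function(x) standardGeneric("rpCurve"))
setMethod("rpCurve", "EvaluationResult", function(x) x@curve)

#' Area under the recall-precision curve
#' @param x an \linkS4class{EvaluationResult}
#' @export
setGeneric("aurpc", function(x) standardGeneric("aurpc"))
setMethod("aurpc", "EvaluationResult", function(x) x@aurpc)

# ---------------------------------------------------------------------------
# show methods
# ---------------------------------------------------------------------------

setMethod("show", "DirectedNetwork", function(object) {
  cat(sprintf("DirectedNetwork: %d genes, %d regulations\n",
              length(object@genes), nrow(object@regulations)))
})

setMethod("show", "UndirectedNetwork", function(object) {
  cat(sprintf("UndirectedNetwork: %d genes, %d edges\n",
              length(object@genes), nrow(object@edges)))
})

setMethod("show", "NetworkEnsemble", function(object) {
  cat(sprintf("NetworkEnsemble: %d networks over %d genes (total edge weight %g)\n",
              object@ng, length(object@genes), sum(object@weights) / 2))
})

setMethod("show", "Dendrogram", function(object) {
  N <- length(object@genes)
  cat(sprintf("Dendrogram: %d leaves, %d internal nodes\n", N, N - 1L))
  cat("  ", dendrogramNewick(object), "\n", sep = "")
})

setMethod("show", "HRGModel", function(object) {
  N <- length(object@tree@genes)
  cat(sprintf("HRGModel: %d genes, %d internal nodes, theta in [%.3g, %.3g]\n",
              N, N - 1L, min(object@theta), max(object@theta)))
})

setMethod("show", "ConfidenceMatrix", function(object) {
  cat(sprintf("ConfidenceMatrix: %d genes, eta = %.4g\n",
              length(object@genes), object@eta))
})

setMethod("show", "SSystemModel", function(object) {
  cat(sprintf("SSystemModel: %d genes, %d regulations (non-zero g off-diagonal)\n",
              length(object@genes),
              sum(object@g[row(object@g) != col(object@g)] != 0)))
})

setMethod("show", "TimeSeriesSet", function(object) {
  d <- dim(object@clean)
  cat(sprintf("TimeSeriesSet: %d sets x %d timepoints x %d genes (K = %d per gene)\n",
              d[1L], d[2L], d[3L], d[1L] * d[2L]))
})

setMethod("show", "AnnealSchedule", function(object) {
  cat(sprintf("AnnealSchedule: T %g -> %g, gamma %g, %d proposals/epoch\n",
              object@tStart, object@tEnd, object@gamma, object@nMax))
})

setMethod("show", "EvaluationResult", function(object) {
  cat(sprintf("EvaluationResult: %d curve points, %d true regulations, AURPC = %.4f\n",
              nrow(object@curve), object@nTrue, object@aurpc))
})
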