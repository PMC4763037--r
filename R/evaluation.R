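# Directed recall-precision evaluation against a gold-standard topology,
# sweeping the confidence threshold over the distinct confidence values,
# and the area under the recall-precision curve.

.directedPairKeys <- function(net) {
  r <- net@regulations
  r <- r[r[, 1L] != r[, 2L], , drop = FALSE]  # self-regulations disregarded
  .pairKey(r[, 1L], r[, 2L])
}

#' Confusion counts of a predicted edge set
#'
#' Directed comparison (m -> n and n -> m are distinct); self-regulations
#' are removed from both sides before counting.
#'
#' @param predicted two-column matrix/data.frame of (regulator, target)
#'   pairs, or a \linkS4class{DirectedNetwork}
#' @param truth the gold-standard \linkS4class{DirectedNetwork}
#' @return named vector c(tp, fp, fn)
#' @export
confusion <- function(predicted, truth) {
  stopifnot(is(truth, "DirectedNetwork"))
  if (!is(predicted, "DirectedNetwork"))
    predicted <- DirectedNetwork(truth@genes, predicted)
  predKeys <- .directedPairKeys(predicted)
  trueKeys <- .directedPairKeys(truth)
  tp <- sum(predKeys %in% trueKeys)
  c(tp = tp, fp = length(predKeys) - tp, fn = length(trueKeys) - tp)
}

#' Recall-precision curve over confidence thresholds
#'
#' The threshold sweeps over the distinct combined-confidence values in
#' descending order; at each, the predicted network contains every
#' regulation whose confidence reaches that value, so tied regulations
#' enter in one block. Comparison is directed and self-regulations are
#' disregarded. recall = TP/(TP+FN), precision = TP/(TP+FP) with
#' precision defined as 1 when nothing is predicted.
#'
#' @param conf a \linkS4class{ConfidenceMatrix}
#' @param truth gold-standard \linkS4class{DirectedNetwork} with at least
#'   one (non-self) regulation
#' @return an \linkS4class{EvaluationResult}
#' @export
recallPrecisionCurve <- function(conf, truth) {
  stopifnot(is(conf, "ConfidenceMatrix"), is(truth, "DirectedNetwork"))
  if (!setequal(conf@genes, truth@genes))
    stop("confidence matrix and gold standard cover different genes")
  trueKeys <- .directedPairKeys(truth)
  nTrue <- length(trueKeys)
  if (nTrue == 0L) stop("gold standard has no regulations: recall is undefined")
  g <- conf@genes
  off <- which(row(conf@combined) != col(conf@combined), arr.ind = TRUE)
  scores <- conf@combined[off]
  isTrue <- .pairKey(g[off[, "col"]], g[off[, "row"]]) %in% trueKeys
  .curveFromScores(scores, isTrue, nTrue)
}

# shared implementation: one point per distinct score, tie blocks enter
# together
.curveFromScores <- function(scores, isTrue, nTrue) {
  ord <- order(scores, decreasing = TRUE)
  scores <- scores[ord]
  isTrue <- isTrue[ord]
  last <- which(!duplicated(scores, fromLast = TRUE))  # block ends
  cumTP <- cumsum(isTrue)[last]
  n <- last  # predictions made at each block end
  tp <- cumTP
  fp <- n - tp
  fn <- nTrue - tp
  recall <- tp / nTrue
  precision <- ifelse(n > 0, tp / n, 1)
  curve <- data.frame(threshold = scores[last], tp = tp, fp = fp, fn = fn,
                      recall = recall, precision = precision)
  new("EvaluationResult", curve = curve,
      aurpc = .aurpcFromCurve(curve), nTrue = as.integer(nTrue))
}

# trapezoidal area of precision over recall: at each distinct recall the
# best (first-attained) precision is used, the curve is extended
# horizontally from the smallest achieved recall down to 0, and precision
# beyond the largest achieved recall (if < 1) is taken as 0.
.aurpcFromCurve <- function(curve) {
  keep <- !duplicated(curve$recall)  # first = highest precision per recall
  r <- curve$recall[keep]
  p <- curve$precision[keep]
  pos <- r > 0
  r <- r[pos]
  p <- p[pos]
  if (!length(r)) return(0)
  r <- c(0, r)
  p <- c(p[1L], p)
  sum(diff(r) * (head(p, -1L) + p[-1L]) / 2)
}

#' Area under the recall-precision curve
#'
#' Trapezoidal integration of precision over recall on [0, 1]; see
#' \code{\link{recallPrecisionCurve}} for the curve conventions. The
#' result lies in [0, 1] and equals 1 only for a scorer that reaches
#' recall 1 at precision 1.
#'
#' @param result an \linkS4class{EvaluationResult} (or a curve data.frame
#'   with recall and precision columns)
#' @return a scalar in [0, 1]
#' @export
aurpcOf <- function(result) {
  if (is(result, "EvaluationResult")) return(result@aurpc)
  if (!nrow(result)) stop("empty curve")
  .aurpcFromCurve(result)
}

#' Write a recall-precision curve as TSV
#' @param result an \linkS4class{EvaluationResult}
#' @param path output file
#' @export
writeCurve <- function(result, path) {
  write.table(result@curve, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
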