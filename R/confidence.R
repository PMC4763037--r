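# Combination of directed bootstrap probabilities with direction-blind
# hierarchy probabilities, and deterministic ranking of regulations.

#' Default mixing weight eta
#'
#' eta = 1 - 1/N_g, so that the hierarchy term (weight 1/N_g) can reorder
#' regulations within one step of the bootstrap-probability grid but never
#' across two steps: the hierarchy breaks ties rather than overruling the
#' bootstrap.
#'
#' @param ng ensemble size N_g >= 1
#' @return eta in [0, 1)
#' @examples
#' defaultEta(100)  # 0.99
#' @export
defaultEta <- function(ng) {
  if (length(ng) != 1L || is.na(ng) || ng < 1) stop("ng must be at least 1")
  1 - 1 / ng
}

#' Combine bootstrap and hierarchy probabilities
#'
#' combined[n, m] = eta * pB[n, m] + (1 - eta) * pH[n, m] for ordered pairs
#' n != m. Diagonal entries (self-regulation, for which the hierarchy
#' assigns no probability) carry pB only and are excluded from ranking and
#' evaluation.
#'
#' @param pB directed bootstrap-probability matrix [target, regulator]
#' @param pH symmetric hierarchy-probability matrix (diagonal ignored)
#' @param eta mixing weight in [0, 1]
#' @param genes gene labels (default: pB dimnames)
#' @return a \linkS4class{ConfidenceMatrix}
#' @examples
#' # a bootstrap probability of 0.29 with hierarchy probability 0.51 at the
#' # default eta for 100 networks gives 0.2922
#' 0.99 * 0.29 + 0.01 * 0.51
#' @export
combineConfidences <- function(pB, pH, eta, genes = rownames(pB)) {
  if (length(eta) != 1L || is.na(eta) || eta < 0 || eta > 1)
    stop("eta must be a single value in [0, 1]")
  if (!all(dim(pB) == dim(pH))) stop("pB and pH are not conformable")
  if (is.null(genes)) genes <- paste0("G", seq_len(nrow(pB)))
  pH2 <- pH
  diag(pH2) <- NA_real_
  combined <- eta * pB + (1 - eta) * pH2
  diag(combined) <- diag(pB)  # pB only; flagged excluded downstream
  obj <- new("ConfidenceMatrix", genes = as.character(genes), pB = pB,
             pH = pH2, eta = eta, combined = combined)
  validObject(obj)
  obj
}

#' Score regulations with a fitted hierarchy
#'
#' Convenience wrapper: p^H from the model, eta defaulting to 1 - 1/N_g,
#' combined with the supplied bootstrap probabilities.
#'
#' @param pB bootstrap-probability matrix [target, regulator]
#' @param model an \linkS4class{HRGModel}
#' @param ng ensemble size (default: the model's)
#' @param eta mixing weight (default \code{defaultEta(ng)})
#' @return a \linkS4class{ConfidenceMatrix}
#' @export
scoreRegulations <- function(pB, model, ng = model@ng, eta = defaultEta(ng)) {
  pH <- hierarchyProbabilities(model, genes = rownames(pB))
  pH[is.na(pH)] <- 0
  combineConfidences(pB, pH, eta, genes = rownames(pB))
}

#' Rank regulations by combined confidence
#'
#' Descending by combined value; ties broken deterministically by pB
#' (descending), then regulator label, then target label - the
#' lexicographic rule is a repository convention. Self-regulations are
#' excluded.
#'
#' @param conf a \linkS4class{ConfidenceMatrix}
#' @return data.frame with columns regulator, target, pB, pH, combined,
#'   rank
#' @export
rankRegulations <- function(conf) {
  g <- conf@genes
  N <- length(g)
  off <- which(row(conf@combined) != col(conf@combined), arr.ind = TRUE)
  df <- data.frame(regulator = g[off[, "col"]], target = g[off[, "row"]],
                   pB = conf@pB[off], pH = conf@pH[off],
                   combined = conf@combined[off],
                   stringsAsFactors = FALSE)
  ord <- order(-df$combined, -df$pB, df$regulator, df$target)
  df <- df[ord, , drop = FALSE]
  df$rank <- seq_len(nrow(df))
  rownames(df) <- NULL
  df
}

#' Network of regulations above a confidence threshold
#'
#' @param conf a \linkS4class{ConfidenceMatrix}
#' @param threshold regulations with combined confidence strictly
#'   exceeding this value are kept (self-regulations never)
#' @return a \linkS4class{DirectedNetwork}
#' @export
thresholdNetwork <- function(conf, threshold) {
  g <- conf@genes
  M <- conf@combined
  keep <- which(M > threshold & row(M) != col(M), arr.ind = TRUE)
  DirectedNetwork(g, cbind(g[keep[, "col"]], g[keep[, "row"]]))
}

#' Write a ranked confidence table as TSV
#' @param conf a \linkS4class{ConfidenceMatrix}
#' @param path output file
#' @export
writeConfidenceTable <- function(conf, path) {
  write.table(rankRegulations(conf), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read a ranked confidence table back into a ConfidenceMatrix
#'
#' @param path TSV written by \code{\link{writeConfidenceTable}}
#' @param eta the mixing weight recorded with the run
#' @return a \linkS4class{ConfidenceMatrix} (diagonal entries zero)
#' @export
readConfidenceTable <- function(path, eta) {
  tab <- read.table(path, header = TRUE, stringsAsFactors = FALSE)
  g <- sort(unique(c(tab$regulator, tab$target)))
  N <- length(g)
  mk <- function(col) {
    M <- matrix(0, N, N, dimnames = list(target = g, regulator = g))
    M[cbind(match(tab$target, g), match(tab$regulator, g))] <- tab[[col]]
    M
  }
  pH <- mk("pH")
  pH <- (pH + t(pH)) / 2  # symmetric up to the table's rounding
  combineConfidences(mk("pB"), pH, eta, genes = g)
}
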